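# Shared fixtures and independent oracles.

# minimal long-form record builder; censored rows get (censor, 0, 0)
make_records <- function(participant_id, ad_id = "Ad1", aoi_id, category,
                         ttff_ms, fc, fd_ms, censored = NULL,
                         censor_ms = 10000) {
  n <- max(length(participant_id), length(aoi_id), length(ttff_ms))
  tibble::tibble(
    participant_id = rep_len(participant_id, n),
    ad_id = rep_len(ad_id, n),
    aoi_id = rep_len(aoi_id, n),
    category = normalize_category(rep_len(category, n)),
    ttff_ms = rep_len(ttff_ms, n),
    censored = if (is.null(censored)) rep_len(ttff_ms >= censor_ms & fc == 0, n)
               else rep_len(censored, n),
    fc = rep_len(fc, n),
    fd_ms = rep_len(fd_ms, n))
}

# dwell-only study rows: one row per participant x aoi, all uncensored
dwell_records <- function(dwell_matrix, aoi_id = colnames(dwell_matrix),
                          category = "Text", ad_id = "Ad1") {
  df <- expand.grid(p = seq_len(nrow(dwell_matrix)),
                    a = seq_along(aoi_id))
  tibble::tibble(
    participant_id = sprintf("P%02d", df$p),
    ad_id = ad_id,
    aoi_id = aoi_id[df$a],
    category = rep_len(category, length(aoi_id))[df$a],
    ttff_ms = 500 + 10 * df$a,
    censored = is.na(dwell_matrix[cbind(df$p, df$a)]),
    fc = ifelse(is.na(dwell_matrix[cbind(df$p, df$a)]), 0, 1),
    fd_ms = ifelse(is.na(dwell_matrix[cbind(df$p, df$a)]), 0,
                   dwell_matrix[cbind(df$p, df$a)]),
    ttff_ms2 = NULL) |>
    dplyr::mutate(ttff_ms = ifelse(.data$censored, 10000, .data$ttff_ms))
}

# brute-force tie-aware pairwise win counting: independent double loop
oracle_pairwise <- function(dwell_matrix) {
  K <- ncol(dwell_matrix)
  P <- matrix(NA_real_, K, K); diag(P) <- 0.5
  N <- matrix(0, K, K)
  diag(N) <- colSums(!is.na(dwell_matrix))
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (i == j) next
    wins <- 0; ties <- 0; n <- 0
    for (p in seq_len(nrow(dwell_matrix))) {
      di <- dwell_matrix[p, i]; dj <- dwell_matrix[p, j]
      if (is.na(di) || is.na(dj)) next
      n <- n + 1
      if (di > dj) wins <- wins + 1
      if (di == dj) ties <- ties + 1
    }
    N[i, j] <- n
    if (n > 0) P[i, j] <- (wins + 0.5 * ties) / n
  }
  list(P = P, N = N)
}

# brute-force I-VT run segmentation, written as an explicit scan
oracle_ivt <- function(trial, params, ppd) {
  trial <- trial[order(trial$t_ms), ]
  n <- nrow(trial)
  valid <- trial$valid & is.finite(trial$x_px) & is.finite(trial$y_px)
  fixational <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (!valid[i]) next
    v_back <- NA_real_
    if (i > 1 && valid[i - 1]) {
      d <- sqrt((trial$x_px[i] - trial$x_px[i - 1])^2 +
                  (trial$y_px[i] - trial$y_px[i - 1])^2) / ppd
      v_back <- d / ((trial$t_ms[i] - trial$t_ms[i - 1]) / 1000)
    }
    if (!is.na(v_back)) {
      fixational[i] <- v_back < params$velocity_threshold_deg_s
    } else if (i < n && valid[i + 1]) {
      d <- sqrt((trial$x_px[i + 1] - trial$x_px[i])^2 +
                  (trial$y_px[i + 1] - trial$y_px[i])^2) / ppd
      v_fwd <- d / ((trial$t_ms[i + 1] - trial$t_ms[i]) / 1000)
      fixational[i] <- v_fwd < params$velocity_threshold_deg_s
    }
  }
  out <- list()
  i <- 1
  while (i <= n) {
    if (!fixational[i]) { i <- i + 1; next }
    j <- i
    while (j < n && fixational[j + 1]) j <- j + 1
    dur <- trial$t_ms[j] - trial$t_ms[i]
    if (dur >= params$min_fixation_ms) {
      out[[length(out) + 1]] <- data.frame(
        onset_ms = trial$t_ms[i], duration_ms = dur,
        cx_px = mean(trial$x_px[i:j]), cy_px = mean(trial$y_px[i:j]))
    }
    i <- j + 1
  }
  if (length(out) == 0) {
    data.frame(onset_ms = numeric(), duration_ms = numeric(),
               cx_px = numeric(), cy_px = numeric())
  } else do.call(rbind, out)
}

# gaze-sample stream for one trial at a fixed rate
make_samples <- function(x, y, hz = 60, valid = TRUE,
                         participant_id = "P01", ad_id = "Ad1") {
  n <- max(length(x), length(y))
  tibble::tibble(participant_id = participant_id, ad_id = ad_id,
                 t_ms = (seq_len(n) - 1) * 1000 / hz,
                 x_px = rep_len(x, n), y_px = rep_len(y, n),
                 valid = rep_len(valid, n))
}

rect_vertices <- function(x0, y0, w, h) {
  cbind(x = c(x0, x0 + w, x0 + w, x0), y = c(y0, y0, y0 + h, y0 + h))
}

# tiny two-ad AOI set with an engineered overlap on Ad1
tiny_aois <- function(geometry = screen_geometry()) {
  aoi_set(
    ad_id = c("Ad1", "Ad1", "Ad1", "Ad2", "Ad2"),
    aoi_id = c("Cta", "Head", "Pic", "Head", "Logo"),
    category = c("Website/CTA", "Text", "Image/Visual", "Text", "Logo"),
    vertices = list(
      rect_vertices(100, 100, 200, 100),   # overlaps Head on Ad1
      rect_vertices(150, 120, 400, 200),
      rect_vertices(800, 400, 300, 300),
      rect_vertices(100, 100, 400, 200),
      rect_vertices(1500, 50, 200, 100)),
    geometry = geometry)
}

# compact synthetic config for fast tests: one ad, no subgroup modifiers
test_config <- function(n_participants = 10, n_aoi = 4, p_skip = 0.1,
                        modifiers = NULL, ...) {
  ad <- synthetic_ad("Ad1",
                     aoi_id = paste0("A", seq_len(n_aoi)),
                     category = rep_len(c("Text", "Image/Visual", "Symbol",
                                          "Logo", "Website/CTA",
                                          "Source/Authority"), n_aoi),
                     p_skip = p_skip)
  synthetic_study_config(n_participants = n_participants, ads = ad,
                         modifiers = modifiers, ...)
}
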