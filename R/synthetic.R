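#' Default stratum levels and proportions
#'
#' Quota proportions for the three participant strata of a 30-person
#' screening-ad panel: four age bands (40-45 30%, 46-50 16.7%, 51-55
#' 23.3%, 56-60 30%), four household types (married with kids 63.3%,
#' single no kids 16.7%, single with kids 10%, married no kids 10%), and
#' four education levels (primary 13.3%, secondary 43.3%, university
#' 23.3%, postgraduate 20%).
#'
#' @return Named list of named probability vectors (`age_band`,
#'   `household`, `education`).
#' @export
default_strata <- function() {
  list(
    age_band = c("40-45" = 9, "46-50" = 5, "51-55" = 7, "56-60" = 9) / 30,
    household = c("Married with kids" = 19, "Single, no kids" = 5,
                  "Single with kids" = 3, "Married, no kids" = 3) / 30,
    education = c("Primary" = 4, "Secondary" = 13, "University" = 7,
                  "Postgraduate" = 6) / 30)
}

#' Default subgroup modifiers
#'
#' Mild multiplicative shifts encoding the directional audience patterns a
#' screening-ad study would expect: older viewers enter on
#' Source/Authority more, higher-education viewers on Text and
#' Website/CTA, and single viewers on Symbols and Images. `entry_mult`
#' scales the AOI entry (salience) weight; `dwell_mult` scales the mean
#' dwell.
#'
#' @return Tibble: `stratum`, `level`, `category`, `entry_mult`,
#'   `dwell_mult`.
#' @export
default_modifiers <- function() {
  tibble::tribble(
    ~stratum,     ~level,           ~category,          ~entry_mult, ~dwell_mult,
    "age_band",   "56-60",          "Source/Authority", 1.5,         1.2,
    "education",  "Postgraduate",   "Text",             1.4,         1.15,
    "education",  "Postgraduate",   "Website/CTA",      1.4,         1.0,
    "household",  "Single, no kids", "Symbol",          1.3,         1.0,
    "household",  "Single, no kids", "Image/Visual",    1.2,         1.0)
}

# per-category generative defaults: entry salience, dwell gamma, skip rate,
# and log-normal entry-latency parameters
.category_defaults <- tibble::tribble(
  ~category,          ~entry_weight, ~dwell_shape, ~dwell_scale, ~p_skip, ~ttff_meanlog, ~ttff_sdlog,
  "Image/Visual",     3.0,           3.0,          150,          0.05,    log(800),      0.55,
  "Symbol",           2.0,           2.5,          120,          0.15,    log(1200),     0.55,
  "Text",             1.5,           4.0,          200,          0.10,    log(1500),     0.50,
  "Source/Authority", 0.8,           3.5,          180,          0.25,    log(2500),     0.50,
  "Logo",             0.7,           2.0,          100,          0.30,    log(3000),     0.50,
  "Website/CTA",      0.5,           2.0,          110,          0.35,    log(3500),     0.50)

#' Build one synthetic ad layout
#'
#' Lays AOIs out as non-overlapping axis-aligned rectangles on the screen
#' and attaches per-AOI generative parameters (entry weight, log-normal
#' entry latency, gamma dwell, skip probability), defaulting by semantic
#' category.
#'
#' @param ad_id Ad identifier.
#' @param aoi_id Character vector of AOI names.
#' @param category Raw category labels (normalized).
#' @param entry_weight,dwell_shape,dwell_scale,p_skip,ttff_meanlog,ttff_sdlog
#'   Optional numeric vectors overriding the per-category defaults.
#' @param vertices Optional list of polygon vertex matrices; auto-placed
#'   rectangles when `NULL`.
#' @param geometry A [screen_geometry()] for auto-placement.
#' @return Tibble with one row per AOI.
#' @export
synthetic_ad <- function(ad_id, aoi_id, category,
                         entry_weight = NULL, dwell_shape = NULL,
                         dwell_scale = NULL, p_skip = NULL,
                         ttff_meanlog = NULL, ttff_sdlog = NULL,
                         vertices = NULL, geometry = screen_geometry()) {
  n <- length(aoi_id)
  category <- normalize_category(rep_len(category, n))
  defs <- .category_defaults[match(category, .category_defaults$category), ]
  pick <- function(user, col) if (is.null(user)) defs[[col]] else rep_len(user, n)
  if (is.null(vertices)) {
    # tile rectangles over a 4-column grid with margins
    ncol_grid <- 4
    w <- floor(geometry$width_px / ncol_grid) - 40
    h <- floor(geometry$height_px / ceiling(n / ncol_grid)) - 40
    vertices <- lapply(seq_len(n) - 1, function(k) {
      x0 <- (k %% ncol_grid) * (w + 40) + 20
      y0 <- (k %/% ncol_grid) * (h + 40) + 20
      cbind(x = c(x0, x0 + w, x0 + w, x0),
            y = c(y0, y0, y0 + h, y0 + h))
    })
  }
  tibble::tibble(
    ad_id = as.character(ad_id), aoi_id = as.character(aoi_id),
    category = category,
    entry_weight = pick(entry_weight, "entry_weight"),
    dwell_shape = pick(dwell_shape, "dwell_shape"),
    dwell_scale = pick(dwell_scale, "dwell_scale"),
    p_skip = pick(p_skip, "p_skip"),
    ttff_meanlog = pick(ttff_meanlog, "ttff_meanlog"),
    ttff_sdlog = pick(ttff_sdlog, "ttff_sdlog"),
    vertices = vertices)
}

default_ad_layouts <- function(geometry = screen_geometry()) {
  base_aois <- c(Headline = "Text", BodyText = "Text",
                 MainImage = "Image/Visual", Ribbon = "Symbol",
                 Logo = "Logo", SiteStrip = "Website/CTA",
                 SourceBlock = "Source/Authority")
  ads <- lapply(1:6, function(a) {
    aois <- base_aois
    if (a == 6) aois <- aois[names(aois) != "BodyText"]  # 41 AOIs in total
    synthetic_ad(paste0("Ad", a), names(aois), unname(aois),
                 geometry = geometry)
  })
  dplyr::bind_rows(ads)
}

#' Configuration of a synthetic gaze study
#'
#' Defines the generative ground truth of a simulated study: per-AOI entry
#' (salience) weights driving the first-hit multinomial, log-normal entry
#' latencies ordering later entries, gamma dwell distributions, per-AOI
#' skip (censoring) probabilities, stratum proportions, and multiplicative
#' subgroup modifiers. Defaults emulate a 30-participant panel viewing 6
#' static ads (41 AOIs over the six semantic categories) for 10 s at
#' 60 Hz.
#'
#' @param n_participants Number of participants.
#' @param ads Ad/AOI parameter tibble (see [synthetic_ad()]).
#' @param strata Named list of stratum-level probability vectors.
#' @param modifiers Subgroup modifier tibble (see [default_modifiers()]);
#'   `NULL` for none.
#' @param exposure_ms,censor_ms Exposure and TTFF censoring durations, ms.
#' @param sampling_rate_hz Gaze sampling rate for emitted raw samples.
#' @param saccade_gap_ms Inter-fixation gap in the synthesized scanpath.
#' @param geometry A [screen_geometry()].
#' @return An object of class `synthetic_study_config`.
#' @export
synthetic_study_config <- function(n_participants = 30,
                                   ads = default_ad_layouts(),
                                   strata = default_strata(),
                                   modifiers = default_modifiers(),
                                   exposure_ms = 10000,
                                   censor_ms = 10000,
                                   sampling_rate_hz = 60,
                                   saccade_gap_ms = 80,
                                   geometry = screen_geometry()) {
  ads <- tibble::as_tibble(ads)
  stopifnot(all(c("ad_id", "aoi_id", "category", "entry_weight",
                  "dwell_shape", "dwell_scale", "p_skip",
                  "ttff_meanlog", "ttff_sdlog", "vertices") %in% names(ads)))
  if (n_participants < 1) abort_gd("validation", "Need at least one participant.")
  if (any(ads$entry_weight < 0) || all(ads$entry_weight == 0)) {
    abort_gd("validation", "Entry weights must be non-negative and normalizable.")
  }
  if (any(ads$p_skip < 0 | ads$p_skip >= 1)) {
    abort_gd("validation", "p_skip must lie in [0, 1).")
  }
  if (any(ads$dwell_shape <= 0 | ads$dwell_scale <= 0 | ads$ttff_sdlog <= 0)) {
    abort_gd("validation", "Distribution parameters must be strictly positive.")
  }
  # feasibility: expected dwell mass must fit comfortably in the exposure
  mass <- ads |>
    dplyr::group_by(.data$ad_id) |>
    dplyr::summarise(m = sum((1 - .data$p_skip) * .data$dwell_shape * .data$dwell_scale),
                     .groups = "drop")
  if (any(mass$m > 0.75 * exposure_ms)) {
    abort_gd("validation",
             sprintf("Infeasible config: expected dwell mass of ad %s exceeds 75%% of the exposure.",
                     mass$ad_id[which.max(mass$m)]))
  }
  if (!is.null(modifiers)) {
    modifiers <- tibble::as_tibble(modifiers)
    stopifnot(all(c("stratum", "level", "category",
                    "entry_mult", "dwell_mult") %in% names(modifiers)))
  }
  structure(list(n_participants = n_participants, ads = ads,
                 strata = strata, modifiers = modifiers,
                 exposure_ms = exposure_ms, censor_ms = censor_ms,
                 sampling_rate_hz = sampling_rate_hz,
                 saccade_gap_ms = saccade_gap_ms, geometry = geometry),
            class = "synthetic_study_config")
}

#' @export
print.synthetic_study_config <- function(x, ...) {
  cat(sprintf("<synthetic_study_config> %d participants | %d ads | %d AOIs | %g ms at %g Hz\n",
              x$n_participants, dplyr::n_distinct(x$ads$ad_id),
              nrow(x$ads), x$exposure_ms, x$sampling_rate_hz))
  invisible(x)
}

# multiplicative modifier for one participant's strata on each AOI row
modifier_mults <- function(config, strata_row) {
  ads <- config$ads
  entry <- rep(1, nrow(ads)); dwell <- rep(1, nrow(ads))
  mods <- config$modifiers
  if (is.null(mods) || nrow(mods) == 0) return(list(entry = entry, dwell = dwell))
  for (r in seq_len(nrow(mods))) {
    if (identical(strata_row[[mods$stratum[r]]], mods$level[r])) {
      hit <- ads$category == mods$category[r]
      entry[hit] <- entry[hit] * mods$entry_mult[r]
      dwell[hit] <- dwell[hit] * mods$dwell_mult[r]
    }
  }
  list(entry = entry, dwell = dwell)
}

# random interior point of a polygon: rejection-sample in the bounding box
polygon_point <- function(vertices) {
  for (i in 1:30) {
    px <- stats::runif(1, min(vertices[, 1]), max(vertices[, 1]))
    py <- stats::runif(1, min(vertices[, 2]), max(vertices[, 2]))
    if (point_in_polygon(px, py, vertices)) return(c(px, py))
  }
  c(mean(vertices[, 1]), mean(vertices[, 2]))  # centroid fallback
}

#' Generate a synthetic gaze study
#'
#' Simulates every participant x ad trial of the configured study and
#' emits three mutually consistent representations: raw gaze samples (60 Hz
#' by default, with saccade interpolation and invalid samples outside the
#' scanpath), the fixation table (assigned to AOIs), and the long-form
#' [study_table()] of per-AOI metrics, plus the participant strata map.
#' Per trial, the first-hit AOI is drawn from the (modifier-adjusted)
#' entry weights and is always fixated; other AOIs are skipped with their
#' configured probabilities; remaining entries are ordered by log-normal
#' latency draws; per-AOI dwell is gamma-distributed and split across
#' revisit fixations by a symmetric Dirichlet; trials whose drawn dwell
#' overruns the exposure are scaled down uniformly, which preserves every
#' within-trial dwell comparison. Determinism: each participant uses the
#' substream `seed + participant index`, so adding participants never
#' perturbs earlier ones.
#'
#' @param config A [synthetic_study_config()].
#' @param seed Integer root seed.
#' @param emit_samples Emit the raw gaze-sample table (set `FALSE` to
#'   speed up large simulation studies that only need the metric table).
#' @return A list of class `synthetic_study`: `samples`, `fixations`,
#'   `study` (a [study_table()]), `strata`, `config`, `seed`.
#' @export
generate_study <- function(config, seed = 1, emit_samples = TRUE) {
  stopifnot(inherits(config, "synthetic_study_config"))
  ads_split <- split(config$ads, config$ads$ad_id)
  all_fix <- vector("list", config$n_participants)
  all_samp <- vector("list", config$n_participants)
  strata_rows <- vector("list", config$n_participants)

  for (p in seq_len(config$n_participants)) {
    set.seed((seed + p) %% .Machine$integer.max)
    pid <- sprintf("P%02d", p)
    srow <- tibble::tibble(participant_id = pid)
    for (dim in names(config$strata)) {
      pr <- config$strata[[dim]]
      srow[[dim]] <- sample(names(pr), 1, prob = pr)
    }
    strata_rows[[p]] <- srow
    mults <- modifier_mults(config, srow)

    p_fix <- list(); p_samp <- list()
    for (ad in names(ads_split)) {
      aois <- ads_split[[ad]]
      rows <- match(paste(aois$ad_id, aois$aoi_id),
                    paste(config$ads$ad_id, config$ads$aoi_id))
      trial <- simulate_trial(aois, mults$entry[rows], mults$dwell[rows],
                              config)
      trial$fix$participant_id <- pid
      trial$fix$ad_id <- ad
      p_fix[[ad]] <- trial$fix
      if (emit_samples) {
        samp <- emit_trial_samples(trial$fix, config)
        samp$participant_id <- pid
        samp$ad_id <- ad
        p_samp[[ad]] <- samp
      }
    }
    all_fix[[p]] <- dplyr::bind_rows(p_fix)
    if (emit_samples) all_samp[[p]] <- dplyr::bind_rows(p_samp)
  }

  strata <- dplyr::bind_rows(strata_rows)
  fixations <- dplyr::bind_rows(all_fix) |>
    dplyr::relocate("participant_id", "ad_id")
  samples <- if (emit_samples) {
    dplyr::bind_rows(all_samp) |>
      dplyr::relocate("participant_id", "ad_id")
  } else NULL

  # long-form metric table aggregated directly from the emitted fixations
  grid <- tidyr::expand_grid(participant_id = strata$participant_id,
                             config$ads[, c("ad_id", "aoi_id", "category")])
  hits <- fixations |>
    dplyr::group_by(.data$participant_id, .data$ad_id, .data$aoi_id) |>
    dplyr::summarise(ttff_ms = min(.data$onset_ms),
                     fc = dplyr::n(), fd_ms = sum(.data$duration_ms),
                     .groups = "drop")
  rec <- dplyr::left_join(grid, hits,
                          by = c("participant_id", "ad_id", "aoi_id")) |>
    dplyr::mutate(censored = is.na(.data$ttff_ms),
                  ttff_ms = dplyr::if_else(.data$censored,
                                           config$censor_ms, .data$ttff_ms),
                  fc = dplyr::if_else(.data$censored, 0, as.double(.data$fc)),
                  fd_ms = dplyr::if_else(.data$censored, 0, .data$fd_ms)) |>
    dplyr::left_join(strata, by = "participant_id")
  study <- study_table(rec, geometry = config$geometry,
                       exposure_ms = config$exposure_ms,
                       censor_ms = config$censor_ms)
  structure(list(samples = samples, fixations = fixations, study = study,
                 strata = strata, config = config, seed = seed),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> seed %d | %d participants | %d fixations | %d records\n",
              x$seed, nrow(x$strata), nrow(x$fixations), nrow(x$study)))
  invisible(x)
}

# simulate one trial; returns fixation tibble (aoi_id, category, onset,
# duration, cx, cy)
simulate_trial <- function(aois, entry_mult, dwell_mult, config) {
  K <- nrow(aois)
  w <- aois$entry_weight * entry_mult
  first_idx <- sample.int(K, 1, prob = w)
  fixated <- stats::runif(K) >= aois$p_skip
  fixated[first_idx] <- TRUE
  latency <- stats::rlnorm(K, aois$ttff_meanlog, aois$ttff_sdlog)
  entry_order <- c(first_idx,
                   setdiff(order(latency), first_idx)[
                     setdiff(order(latency), first_idx) %in% which(fixated)])
  entry_order <- entry_order[fixated[entry_order]]

  dwell <- stats::rgamma(K, shape = aois$dwell_shape,
                         scale = aois$dwell_scale * dwell_mult)
  dwell[!fixated] <- 0
  fc <- ifelse(fixated, 1 + stats::rpois(K, dwell / 350), 0)

  # per-fixation durations: symmetric Dirichlet split of the AOI dwell
  slots <- list()
  for (i in entry_order) {
    g <- stats::rgamma(fc[i], 1)
    slots[[as.character(i)]] <- dwell[i] * g / sum(g)
  }
  # visit order: first fixation of each AOI in entry order, then revisits
  first_pass <- entry_order
  revisit <- unlist(lapply(entry_order, function(i) rep(i, fc[i] - 1)))
  if (length(revisit) > 1) revisit <- sample(revisit)
  visit <- c(first_pass, revisit)
  taken <- stats::setNames(rep(0L, K), seq_len(K))
  dur <- numeric(length(visit))
  for (v in seq_along(visit)) {
    i <- visit[v]
    taken[i] <- taken[i] + 1L
    dur[v] <- slots[[as.character(i)]][taken[i]]
  }

  t0 <- min(latency[first_idx], config$exposure_ms * 0.2)
  gaps <- config$saccade_gap_ms * max(length(visit) - 1, 0)
  budget <- config$exposure_ms - t0 - gaps
  if (budget <= 0) {
    abort_gd("validation",
             "Infeasible trial: saccade overhead alone exceeds the exposure.")
  }
  if (sum(dur) > budget) dur <- dur * budget / sum(dur)

  onset <- t0 + cumsum(c(0, utils::head(dur, -1) + config$saccade_gap_ms))
  pts <- t(vapply(visit, function(i) polygon_point(aois$vertices[[i]]),
                  numeric(2)))
  fix <- tibble::tibble(aoi_id = aois$aoi_id[visit],
                        category = aois$category[visit],
                        onset_ms = onset, duration_ms = dur,
                        cx_px = pts[, 1], cy_px = pts[, 2])
  # background fixations outside every AOI fill the rest of the exposure;
  # they contribute to no AOI record but keep the gaze stream realistic
  t_end <- if (nrow(fix) > 0) max(fix$onset_ms + fix$duration_ms) else t0
  filler <- list()
  repeat {
    t_next <- t_end + config$saccade_gap_ms
    remaining <- config$exposure_ms - t_next
    if (remaining < 250) break
    pt <- outside_point(aois, config$geometry)
    if (is.null(pt)) break
    d <- min(stats::rgamma(1, 2, scale = 175) + 60, remaining)
    filler[[length(filler) + 1]] <- tibble::tibble(
      aoi_id = NA_character_, category = NA_character_,
      onset_ms = t_next, duration_ms = d, cx_px = pt[1], cy_px = pt[2])
    t_end <- t_next + d
  }
  if (length(filler) > 0) fix <- dplyr::bind_rows(fix, filler)
  list(fix = fix)
}

# uniform screen point contained in no AOI polygon (NULL if none found)
outside_point <- function(aois, geometry) {
  for (i in 1:40) {
    px <- stats::runif(1, 0, geometry$width_px)
    py <- stats::runif(1, 0, geometry$height_px)
    inside <- any(vapply(aois$vertices,
                         function(v) point_in_polygon(px, py, v),
                         logical(1)))
    if (!inside) return(c(px, py))
  }
  NULL
}

# 60 Hz sample stream for one trial: jittered positions inside fixations,
# linear saccade interpolation between them, invalid before/after scanpath
emit_trial_samples <- function(fix, config) {
  dt <- 1000 / config$sampling_rate_hz
  t <- seq(0, config$exposure_ms - dt / 2, by = dt)
  n <- length(t)
  x <- rep(NA_real_, n); y <- rep(NA_real_, n); valid <- rep(FALSE, n)
  if (nrow(fix) > 0) {
    fix <- fix[order(fix$onset_ms), , drop = FALSE]
    off <- fix$onset_ms + fix$duration_ms
    for (k in seq_len(nrow(fix))) {
      inside <- t >= fix$onset_ms[k] & t <= off[k]
      m <- sum(inside)
      if (m > 0) {
        x[inside] <- fix$cx_px[k] + stats::runif(m, -1.5, 1.5)
        y[inside] <- fix$cy_px[k] + stats::runif(m, -1.5, 1.5)
        valid[inside] <- TRUE
      }
      if (k < nrow(fix)) {  # saccade gap to the next fixation
        gap <- t > off[k] & t < fix$onset_ms[k + 1]
        if (any(gap)) {
          frac <- (t[gap] - off[k]) / (fix$onset_ms[k + 1] - off[k])
          x[gap] <- fix$cx_px[k] + frac * (fix$cx_px[k + 1] - fix$cx_px[k])
          y[gap] <- fix$cy_px[k] + frac * (fix$cy_px[k + 1] - fix$cy_px[k])
          valid[gap] <- TRUE
        }
      }
    }
  }
  tibble::tibble(t_ms = t, x_px = x, y_px = y, valid = valid)
}

#' Ground-truth first-hit distribution of a synthetic config
#'
#' The configured probability that each AOI is entered first: the
#' normalized entry weights, averaged over the stratum mixture when
#' subgroup entry modifiers are configured (strata dimensions are assumed
#' independent, as in generation).
#'
#' @param config A [synthetic_study_config()].
#' @param ad_id Ad identifier.
#' @return Tibble: `ad_id`, `aoi_id`, `category`, `prob`, `pct`.
#' @export
ground_truth_first_hit <- function(config, ad_id) {
  aois <- config$ads[config$ads$ad_id == ad_id, ]
  if (nrow(aois) == 0) abort_gd("validation", sprintf("Unknown ad '%s'.", ad_id))
  combos <- strata_combos(config)
  prob <- rep(0, nrow(aois))
  for (s in seq_len(nrow(combos))) {
    srow <- combos[s, , drop = FALSE]
    rows <- match(paste(aois$ad_id, aois$aoi_id),
                  paste(config$ads$ad_id, config$ads$aoi_id))
    m <- modifier_mults(config, srow)
    w <- aois$entry_weight * m$entry[rows]
    prob <- prob + combos$.w[s] * w / sum(w)
  }
  tibble::tibble(ad_id = ad_id, aoi_id = aois$aoi_id,
                 category = aois$category, prob = prob, pct = 100 * prob)
}

# enumerate strata-level combinations with joint weights (independent dims)
strata_combos <- function(config) {
  dims <- names(config$strata)
  if (length(dims) == 0 ||
      is.null(config$modifiers) || nrow(config$modifiers) == 0) {
    out <- tibble::tibble(.w = 1)
    return(out)
  }
  grids <- lapply(dims, function(d) names(config$strata[[d]]))
  names(grids) <- dims
  combos <- tidyr::expand_grid(!!!grids)
  w <- rep(1, nrow(combos))
  for (d in dims) w <- w * unname(config$strata[[d]][combos[[d]]])
  combos$.w <- w
  combos
}

#' Ground-truth pairwise dwell matrix of a synthetic config
#'
#' The analytic win probability `P[i, j] = Pr(dwell_i > dwell_j)` implied
#' by the configured gamma dwell distributions, conditional on both AOIs
#' being fixated, computed by numerical quadrature and averaged over the
#' stratum mixture when dwell modifiers are configured. The continuous
#' dwell model has no ties, and the within-trial rescaling used by the
#' generator preserves every comparison, so estimates from generated data
#' converge to these values.
#'
#' @param config A [synthetic_study_config()].
#' @param ad_id Ad identifier.
#' @return A `pairwise_matrix` (support `N` holds the expected number of
#'   joint observers per participant, times `n_participants`).
#' @export
ground_truth_matrix <- function(config, ad_id) {
  aois <- config$ads[config$ads$ad_id == ad_id, ]
  if (nrow(aois) == 0) abort_gd("validation", sprintf("Unknown ad '%s'.", ad_id))
  K <- nrow(aois)
  combos <- strata_combos(config)
  rows <- match(paste(aois$ad_id, aois$aoi_id),
                paste(config$ads$ad_id, config$ads$aoi_id))
  P <- matrix(NA_real_, K, K); diag(P) <- 0.5
  N <- matrix(0, K, K)
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      if (i >= j) next
      pij <- 0
      for (s in seq_len(nrow(combos))) {
        m <- modifier_mults(config, combos[s, , drop = FALSE])
        pij <- pij + combos$.w[s] *
          gamma_win_prob(aois$dwell_shape[i],
                         aois$dwell_scale[i] * m$dwell[rows][i],
                         aois$dwell_shape[j],
                         aois$dwell_scale[j] * m$dwell[rows][j])
      }
      P[i, j] <- pij
      P[j, i] <- 1 - pij
      N[i, j] <- N[j, i] <-
        (1 - aois$p_skip[i]) * (1 - aois$p_skip[j]) * config$n_participants
    }
  }
  diag(N) <- (1 - aois$p_skip) * config$n_participants
  new_pairwise_matrix(ad_id, aois$aoi_id, P, N,
                      kind = "dwell", level = "aoi")
}

# Pr(X > Y) for X ~ Gamma(a1, s1), Y ~ Gamma(a2, s2); equal scales reduce
# to a beta tail, otherwise quadrature over the density of X
gamma_win_prob <- function(a1, s1, a2, s2) {
  if (isTRUE(all.equal(s1, s2))) {
    return(stats::pbeta(0.5, a2, a1))
  }
  f <- function(x) stats::dgamma(x, a1, scale = s1) *
    stats::pgamma(x, a2, scale = s2)
  stats::integrate(f, 0, Inf, rel.tol = 1e-9)$value
}

#' Ground-truth category dominance ordering
#'
#' Categories of an ad ordered by the expected per-participant total dwell
#' implied by the config (sum over the category's AOIs of
#' `(1 - p_skip) * shape * scale`), averaged over the stratum mixture.
#' With well-separated, stochastically ordered dwell distributions this is
#' the ordering a category-level dominance analysis recovers.
#'
#' @param config A [synthetic_study_config()].
#' @param ad_id Ad identifier.
#' @return Tibble: `ad_id`, `category`, `expected_dwell_ms`, ordered
#'   descending.
#' @export
ground_truth_category_order <- function(config, ad_id) {
  aois <- config$ads[config$ads$ad_id == ad_id, ]
  if (nrow(aois) == 0) abort_gd("validation", sprintf("Unknown ad '%s'.", ad_id))
  combos <- strata_combos(config)
  rows <- match(paste(aois$ad_id, aois$aoi_id),
                paste(config$ads$ad_id, config$ads$aoi_id))
  ev <- rep(0, nrow(aois))
  for (s in seq_len(nrow(combos))) {
    m <- modifier_mults(config, combos[s, , drop = FALSE])
    ev <- ev + combos$.w[s] * (1 - aois$p_skip) * aois$dwell_shape *
      aois$dwell_scale * m$dwell[rows]
  }
  tibble::tibble(ad_id = ad_id, category = aois$category, ev = ev) |>
    dplyr::group_by(.data$ad_id, .data$category) |>
    dplyr::summarise(expected_dwell_ms = sum(.data$ev), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$expected_dwell_ms))
}
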