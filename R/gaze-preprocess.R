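#' I-VT classification parameters
#'
#' Velocity-threshold fixation identification: samples whose point-to-point
#' angular velocity stays below `velocity_threshold_deg_s` are fixational;
#' maximal fixational runs lasting at least `min_fixation_ms` become
#' fixations; adjacent fixations closer than `merge_max_dist_deg` with a gap
#' of at most `merge_max_gap_ms` are merged. Defaults: 30 deg/s threshold,
#' 60 ms minimum duration (the low end of the conventional 60-80 ms band),
#' merging within 0.5 deg and 75 ms.
#'
#' @param velocity_threshold_deg_s Angular velocity threshold, deg/s.
#' @param min_fixation_ms Minimum fixation duration, ms.
#' @param merge_max_gap_ms Maximum inter-fixation gap for merging, ms.
#' @param merge_max_dist_deg Maximum centroid distance for merging, deg.
#' @return An object of class `ivt_params`.
#' @export
ivt_params <- function(velocity_threshold_deg_s = 30,
                       min_fixation_ms = 60,
                       merge_max_gap_ms = 75,
                       merge_max_dist_deg = 0.5) {
  vals <- list(velocity_threshold_deg_s = velocity_threshold_deg_s,
               min_fixation_ms = min_fixation_ms,
               merge_max_gap_ms = merge_max_gap_ms,
               merge_max_dist_deg = merge_max_dist_deg)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      abort_gd("validation",
               sprintf("ivt_params field '%s' must be a single positive number.", nm))
    }
  }
  structure(vals, class = "ivt_params")
}

#' Classify raw gaze samples into fixations (I-VT)
#'
#' Point-to-point angular velocity is estimated by a two-point backward
#' difference between consecutive valid samples; invalid samples (blinks,
#' tracking loss) break fixational runs. A run-opening sample with no valid
#' backward neighbour joins the run when its forward velocity is below
#' threshold. Runs shorter than the minimum fixation duration are dropped.
#' The fixation centroid is the mean of the member sample coordinates.
#'
#' @param samples Tibble of gaze samples with columns `participant_id`,
#'   `ad_id`, `t_ms`, `x_px`, `y_px`, `valid`; timestamps strictly
#'   increasing within each (participant, ad) trial.
#' @param params An [ivt_params()].
#' @param geometry A [screen_geometry()].
#' @return Tibble of fixations: `participant_id`, `ad_id`, `onset_ms`,
#'   `duration_ms`, `cx_px`, `cy_px`, `n_samples`.
#' @export
classify_fixations <- function(samples, params = ivt_params(),
                               geometry = screen_geometry()) {
  stopifnot(is.data.frame(samples), inherits(params, "ivt_params"))
  ppd <- px_per_degree(geometry)
  samples <- tibble::as_tibble(samples)
  out <- samples |>
    dplyr::group_by(.data$participant_id, .data$ad_id) |>
    dplyr::group_modify(~ classify_trial(.x, params, ppd)) |>
    dplyr::ungroup()
  out
}

classify_trial <- function(trial, params, ppd) {
  empty <- tibble::tibble(onset_ms = double(), duration_ms = double(),
                          cx_px = double(), cy_px = double(),
                          n_samples = integer())
  trial <- trial[order(trial$t_ms), , drop = FALSE]
  if (any(diff(trial$t_ms) <= 0)) {
    abort_gd("validation", "Gaze timestamps must be strictly increasing within a trial.")
  }
  n <- nrow(trial)
  valid <- trial$valid & is.finite(trial$x_px) & is.finite(trial$y_px)
  if (sum(valid) < 2) return(empty)

  # velocity between consecutive samples when both are valid (deg/s)
  vel <- rep(NA_real_, n)
  if (n >= 2) {
    i <- 2:n
    both <- valid[i] & valid[i - 1]
    d_px <- sqrt((trial$x_px[i] - trial$x_px[i - 1])^2 +
                   (trial$y_px[i] - trial$y_px[i - 1])^2)
    dt_s <- (trial$t_ms[i] - trial$t_ms[i - 1]) / 1000
    vel[i][both] <- (d_px / ppd / dt_s)[both]
  }
  thr <- params$velocity_threshold_deg_s
  fix <- valid & !is.na(vel) & vel < thr
  # run-opening sample: no valid backward neighbour, joins forward
  fwd <- c(vel[-1], NA_real_)
  opener <- valid & is.na(vel) & !is.na(fwd) & fwd < thr
  fix <- fix | opener

  r <- rle(fix)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  if (length(keep) == 0) return(empty)
  rows <- purrr::map(keep, function(k) {
    idx <- starts[k]:ends[k]
    dur <- trial$t_ms[ends[k]] - trial$t_ms[starts[k]]
    if (dur < params$min_fixation_ms) return(NULL)
    tibble::tibble(onset_ms = trial$t_ms[starts[k]],
                   duration_ms = dur,
                   cx_px = mean(trial$x_px[idx]),
                   cy_px = mean(trial$y_px[idx]),
                   n_samples = length(idx))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) empty else out
}

#' Merge adjacent fixations
#'
#' Consecutive fixations within `merge_max_dist_deg` (centroid distance)
#' and separated by at most `merge_max_gap_ms` are merged into one fixation
#' spanning the first onset to the second offset, with a duration-weighted
#' centroid. Applied left-to-right within each trial until stable.
#'
#' @param fixations Tibble as returned by [classify_fixations()].
#' @inheritParams classify_fixations
#' @return Tibble of merged fixations (same columns; `n_samples` summed).
#' @export
merge_fixations <- function(fixations, params = ivt_params(),
                            geometry = screen_geometry()) {
  stopifnot(is.data.frame(fixations))
  ppd <- px_per_degree(geometry)
  fixations <- tibble::as_tibble(fixations)
  if (nrow(fixations) == 0) return(fixations)
  fixations |>
    dplyr::group_by(.data$participant_id, .data$ad_id) |>
    dplyr::group_modify(~ merge_trial(.x, params, ppd)) |>
    dplyr::ungroup()
}

merge_trial <- function(fx, params, ppd) {
  fx <- fx[order(fx$onset_ms), , drop = FALSE]
  if (!"n_samples" %in% names(fx)) fx$n_samples <- NA_integer_
  # weight carries the accumulated dwell mass for centroid averaging
  fx$.w <- fx$duration_ms
  repeat {
    if (nrow(fx) < 2) break
    merged_any <- FALSE
    i <- 1
    while (i < nrow(fx)) {
      gap <- fx$onset_ms[i + 1] - (fx$onset_ms[i] + fx$duration_ms[i])
      dist_deg <- sqrt((fx$cx_px[i + 1] - fx$cx_px[i])^2 +
                         (fx$cy_px[i + 1] - fx$cy_px[i])^2) / ppd
      if (gap <= params$merge_max_gap_ms && dist_deg <= params$merge_max_dist_deg) {
        w <- fx$.w[i] + fx$.w[i + 1]
        fx$cx_px[i] <- (fx$cx_px[i] * fx$.w[i] + fx$cx_px[i + 1] * fx$.w[i + 1]) / w
        fx$cy_px[i] <- (fx$cy_px[i] * fx$.w[i] + fx$cy_px[i + 1] * fx$.w[i + 1]) / w
        fx$duration_ms[i] <- fx$onset_ms[i + 1] + fx$duration_ms[i + 1] - fx$onset_ms[i]
        fx$n_samples[i] <- fx$n_samples[i] + fx$n_samples[i + 1]
        fx$.w[i] <- w
        fx <- fx[-(i + 1), , drop = FALSE]
        merged_any <- TRUE
      } else {
        i <- i + 1
      }
    }
    if (!merged_any) break
  }
  fx$.w <- NULL
  fx
}

#' Trial-level quality control
#'
#' Flags trials for exclusion when the proportion of valid gaze samples
#' falls below `valid_threshold` (default 0.70), when an externally
#' supplied calibration drift exceeds `drift_threshold_deg` (default 1
#' degree), or when the trial has no valid samples at all (disengaged).
#'
#' @param samples Gaze-sample tibble (see [classify_fixations()]).
#' @param drift Optional tibble `participant_id`, `ad_id`, `drift_deg` with
#'   per-trial calibration drift from validation screens.
#' @param valid_threshold Minimum proportion of valid samples.
#' @param drift_threshold_deg Maximum tolerated drift in degrees.
#' @return Tibble: `participant_id`, `ad_id`, `n_samples`,
#'   `valid_fraction`, `drift_deg`, `excluded`, `reason` (one of
#'   `valid_below_threshold`, `drift_exceeded`, `disengaged`, `none`).
#' @export
qc_trials <- function(samples, drift = NULL, valid_threshold = 0.70,
                      drift_threshold_deg = 1.0) {
  stopifnot(is.data.frame(samples))
  rep_tbl <- tibble::as_tibble(samples) |>
    dplyr::group_by(.data$participant_id, .data$ad_id) |>
    dplyr::summarise(n_samples = dplyr::n(),
                     valid_fraction = mean(.data$valid),
                     .groups = "drop")
  if (!is.null(drift)) {
    rep_tbl <- dplyr::left_join(rep_tbl, tibble::as_tibble(drift),
                                by = c("participant_id", "ad_id"))
    if (!"drift_deg" %in% names(rep_tbl)) {
      abort_gd("schema", "drift table must have a 'drift_deg' column.")
    }
  } else {
    rep_tbl$drift_deg <- NA_real_
  }
  rep_tbl |>
    dplyr::mutate(
      reason = dplyr::case_when(
        .data$n_samples == 0 | .data$valid_fraction == 0 ~ "disengaged",
        .data$valid_fraction < valid_threshold ~ "valid_below_threshold",
        !is.na(.data$drift_deg) & .data$drift_deg > drift_threshold_deg ~ "drift_exceeded",
        TRUE ~ "none"),
      excluded = .data$reason != "none")
}
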