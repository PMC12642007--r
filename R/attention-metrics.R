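#' Per-AOI attention metrics with right-censoring
#'
#' Collapses assigned fixations to the participant x ad x AOI level.
#' For each AOI of an ad: `ttff_ms` is the onset of the earliest fixation
#' inside it, `fc` the number of such fixations, and `fd_ms` their summed
#' duration. AOIs never fixated in a trial are right-censored: they get
#' `ttff_ms = censor_ms` with `censored = TRUE` and zeroed `fc`/`fd_ms`.
#' One record is emitted for every AOI of the ad in every observed trial.
#'
#' @param fixations Assigned fixation tibble (columns `participant_id`,
#'   `ad_id`, `onset_ms`, `duration_ms`, `aoi_id`; `aoi_id` may be NA for
#'   fixations outside every AOI — these contribute to no record).
#' @param aois An [aoi_set()] listing every AOI of each ad.
#' @param exposure_ms Stimulus exposure in ms.
#' @param censor_ms TTFF censoring value in ms.
#' @param geometry A [screen_geometry()] stored on the result.
#' @param strata Optional tibble `participant_id`, `age_band`, `household`,
#'   `education` joined onto the records.
#' @return A [study_table()].
#' @export
compute_aoi_metrics <- function(fixations, aois, exposure_ms = 10000,
                                censor_ms = 10000,
                                geometry = screen_geometry(),
                                strata = NULL) {
  stopifnot(is.data.frame(fixations), inherits(aois, "aoi_set"))
  fx <- tibble::as_tibble(fixations)
  fx <- fx[!is.na(fx$aoi_id), , drop = FALSE]
  known <- paste(aois$ad_id, aois$aoi_id)
  unknown <- setdiff(unique(paste(fx$ad_id, fx$aoi_id)), known)
  if (length(unknown) > 0) {
    abort_gd("validation",
             paste0("Fixations reference unknown AOI(s): ",
                    paste(unknown, collapse = ", "), "."))
  }
  trials <- dplyr::distinct(tibble::as_tibble(fixations),
                            .data$participant_id, .data$ad_id)
  grid <- dplyr::inner_join(
    trials,
    tibble::as_tibble(aois)[, c("ad_id", "aoi_id", "category")],
    by = "ad_id", relationship = "many-to-many")
  hits <- fx |>
    dplyr::group_by(.data$participant_id, .data$ad_id, .data$aoi_id) |>
    dplyr::summarise(ttff_ms = min(.data$onset_ms),
                     fc = dplyr::n(),
                     fd_ms = sum(.data$duration_ms),
                     .groups = "drop")
  rec <- dplyr::left_join(grid, hits,
                          by = c("participant_id", "ad_id", "aoi_id")) |>
    dplyr::mutate(
      censored = is.na(.data$ttff_ms),
      ttff_ms = dplyr::if_else(.data$censored, censor_ms, .data$ttff_ms),
      fc = dplyr::if_else(.data$censored, 0, as.double(.data$fc)),
      fd_ms = dplyr::if_else(.data$censored, 0, .data$fd_ms))
  if (!is.null(strata)) {
    rec <- dplyr::left_join(rec, tibble::as_tibble(strata),
                            by = "participant_id")
  }
  study_table(rec, geometry = geometry,
              exposure_ms = exposure_ms, censor_ms = censor_ms)
}

#' First-hit AOI per trial
#'
#' The first hit of a trial is the AOI with the minimum uncensored TTFF.
#' Trials where every AOI is censored yield `aoi_id = NA` and are excluded
#' from first-hit denominators downstream. Exact TTFF ties are broken by
#' category overlap priority, then lexicographic `aoi_id`, so output is
#' deterministic.
#'
#' @param records A [study_table()] (or compatible tibble).
#' @return Tibble: `participant_id`, `ad_id`, `aoi_id`, `category`,
#'   `ttff_ms`; one row per trial.
#' @export
first_hits <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) abort_gd("validation", "Empty record set.")
  tibble::as_tibble(records) |>
    dplyr::mutate(.prio = category_priority(.data$category)) |>
    dplyr::group_by(.data$participant_id, .data$ad_id) |>
    dplyr::group_modify(function(g, key) {
      un <- g[!g$censored, , drop = FALSE]
      if (nrow(un) == 0) {
        return(tibble::tibble(aoi_id = NA_character_,
                              category = NA_character_,
                              ttff_ms = NA_real_))
      }
      un <- un[order(un$ttff_ms, un$.prio, un$aoi_id), , drop = FALSE]
      tibble::tibble(aoi_id = un$aoi_id[1], category = un$category[1],
                     ttff_ms = un$ttff_ms[1])
    }) |>
    dplyr::ungroup()
}

#' First-hit distribution by AOI or category
#'
#' Shares of trials entering each AOI (or category) first, per ad.
#' Percentages are computed over trials with at least one uncensored AOI;
#' the number of excluded no-hit trials is reported alongside. `pct` is
#' exact (sums to 100 within each ad); round to one decimal for display.
#'
#' @param hits Output of [first_hits()].
#' @param level `"aoi"` or `"category"`.
#' @return Tibble: `ad_id`, key column (`aoi_id` or `category`), `n`,
#'   `pct`, `n_trials` (first-hit denominator), `n_no_hit`.
#' @export
first_hit_distribution <- function(hits, level = c("category", "aoi")) {
  level <- match.arg(level)
  stopifnot(is.data.frame(hits))
  key <- if (level == "aoi") "aoi_id" else "category"
  hits <- tibble::as_tibble(hits)
  valid <- hits[!is.na(hits$aoi_id), , drop = FALSE]
  if (nrow(valid) == 0) {
    abort_gd("compute", "No trial has an uncensored first hit.")
  }
  no_hit <- hits |>
    dplyr::group_by(.data$ad_id) |>
    dplyr::summarise(n_no_hit = sum(is.na(.data$aoi_id)), .groups = "drop")
  valid |>
    dplyr::count(.data$ad_id, .data[[key]], name = "n") |>
    dplyr::group_by(.data$ad_id) |>
    dplyr::mutate(n_trials = sum(.data$n),
                  pct = 100 * .data$n / .data$n_trials) |>
    dplyr::ungroup() |>
    dplyr::left_join(no_hit, by = "ad_id")
}

#' Benchmark summary table
#'
#' Medians and interquartile ranges of TTFF, fixation count, and dwell per
#' ad and AOI (or category), with the number of contributing participants.
#' Censored TTFF values are INCLUDED in the latency summaries at the censor
#' value, and censored fixation counts / dwell enter as zeros, so AOIs that
#' few participants ever fixate show inflated median latencies by design;
#' the `n_censored` column makes this visible. At the category level,
#' metrics are first aggregated per participant (minimum TTFF, summed FC
#' and FD over the category's AOIs; censored only when every AOI in the
#' category is censored).
#'
#' @param records A [study_table()].
#' @param level `"aoi"` or `"category"`.
#' @return Tibble: `ad_id`, key column, `n`, `n_censored`,
#'   `median_ttff_ms`, `iqr_ttff_ms`, `median_fc`, `iqr_fc`,
#'   `median_fd_ms`, `iqr_fd_ms`.
#' @export
benchmark_table <- function(records, level = c("aoi", "category")) {
  level <- match.arg(level)
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) abort_gd("validation", "Empty record set.")
  rec <- tibble::as_tibble(records)
  if (level == "category") {
    rec <- rec |>
      dplyr::group_by(.data$participant_id, .data$ad_id, .data$category) |>
      dplyr::summarise(ttff_ms = min(.data$ttff_ms),
                       fc = sum(.data$fc),
                       fd_ms = sum(.data$fd_ms),
                       censored = all(.data$censored),
                       .groups = "drop")
    key <- "category"
  } else {
    key <- "aoi_id"
  }
  rec |>
    dplyr::group_by(.data$ad_id, .data[[key]]) |>
    dplyr::summarise(
      n = dplyr::n_distinct(.data$participant_id),
      n_censored = sum(.data$censored),
      median_ttff_ms = stats::median(.data$ttff_ms),
      iqr_ttff_ms = stats::IQR(.data$ttff_ms),
      median_fc = stats::median(.data$fc),
      iqr_fc = stats::IQR(.data$fc),
      median_fd_ms = stats::median(.data$fd_ms),
      iqr_fd_ms = stats::IQR(.data$fd_ms),
      .groups = "drop")
}

#' Mean with a 95% t-interval
#'
#' Closed-form Student-t confidence interval for a group mean, used by the
#' descriptive group-summary plots.
#'
#' @param x Numeric vector.
#' @param conf Confidence level (default 0.95).
#' @return Tibble: `n`, `mean`, `ci_low`, `ci_high`.
#' @export
mean_ci <- function(x, conf = 0.95) {
  x <- x[is.finite(x)]
  n <- length(x)
  m <- mean(x)
  if (n < 2) {
    return(tibble::tibble(n = n, mean = m, ci_low = NA_real_, ci_high = NA_real_))
  }
  half <- stats::qt(1 - (1 - conf) / 2, df = n - 1) * stats::sd(x) / sqrt(n)
  tibble::tibble(n = n, mean = m, ci_low = m - half, ci_high = m + half)
}
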