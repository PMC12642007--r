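#' Stratified first-hit distributions
#'
#' Category-level first-hit distributions computed within each level of a
#' participant stratum (age band, household type, or education), with
#' per-level denominators. Every participant appearing in `hits` must be
#' present in the strata map.
#'
#' @param hits Output of [first_hits()].
#' @param strata Tibble mapping `participant_id` to stratum columns.
#' @param by Name of the stratum column in `strata` (e.g. `"age_band"`).
#' @param level `"category"` (conventional) or `"aoi"`.
#' @return Tibble: `ad_id`, `stratum` (the `by` column name), `level` (its
#'   value), key column, `n`, `pct`, `n_trials`, `n_no_hit`.
#' @export
stratified_first_hit <- function(hits, strata, by = "age_band",
                                 level = c("category", "aoi")) {
  level <- match.arg(level)
  stopifnot(is.data.frame(hits), is.data.frame(strata))
  if (!by %in% names(strata)) {
    abort_gd("schema", sprintf("Stratum column '%s' not found in strata.", by))
  }
  strata <- dplyr::distinct(tibble::as_tibble(strata),
                            .data$participant_id, .data[[by]])
  hits <- tibble::as_tibble(hits)
  missing_p <- setdiff(unique(hits$participant_id), strata$participant_id)
  if (length(missing_p) > 0) {
    abort_gd("validation",
             paste0("Participant(s) missing from the strata map: ",
                    paste(missing_p, collapse = ", "), "."))
  }
  hh <- dplyr::left_join(hits, strata, by = "participant_id")
  levels_present <- unique(hh[[by]])
  out <- purrr::map(levels_present, function(lv) {
    sub <- hh[hh[[by]] == lv, , drop = FALSE]
    if (all(is.na(sub$aoi_id))) {
      warning(sprintf("Stratum level '%s' has no uncensored first hit; omitted.", lv))
      return(NULL)
    }
    d <- first_hit_distribution(sub, level = level)
    d$stratum <- by
    d$level <- lv
    d
  })
  out <- dplyr::bind_rows(out)
  dplyr::relocate(out, "stratum", "level", .after = "ad_id")
}

#' Subgroup-minus-overall delta matrix
#'
#' Percentage-point differences between a subgroup first-hit distribution
#' and the within-ad overall distribution, per category. The sign
#' convention is subgroup minus overall: positive values mean the subgroup
#' enters that category comparatively more often. Categories missing from
#' either distribution are treated as 0%. Each ad's deltas cancel to about
#' zero since both distributions sum to 100%.
#'
#' @param subgroup A first-hit distribution tibble (one stratum level; from
#'   [stratified_first_hit()] or [first_hit_distribution()]).
#' @param overall The overall distribution at the same level.
#' @param key Name of the key column (default `"category"`).
#' @return Tibble: `ad_id`, key column, `pct_subgroup`, `pct_overall`,
#'   `delta_pp` (subgroup - overall, percentage points).
#' @export
delta_matrix <- function(subgroup, overall, key = "category") {
  stopifnot(is.data.frame(subgroup), is.data.frame(overall))
  s <- tibble::as_tibble(subgroup)[, c("ad_id", key, "pct")]
  o <- tibble::as_tibble(overall)[, c("ad_id", key, "pct")]
  names(s)[3] <- "pct_subgroup"
  names(o)[3] <- "pct_overall"
  j <- dplyr::full_join(s, o, by = c("ad_id", key))
  j$pct_subgroup[is.na(j$pct_subgroup)] <- 0
  j$pct_overall[is.na(j$pct_overall)] <- 0
  j$delta_pp <- j$pct_subgroup - j$pct_overall
  dplyr::arrange(j, .data$ad_id, .data[[key]])
}

#' All subgroup deltas for one stratum dimension
#'
#' Convenience wrapper computing the overall and per-level first-hit
#' distributions and their deltas in one call.
#'
#' @inheritParams stratified_first_hit
#' @return Tibble: `ad_id`, `stratum`, `level`, `category`,
#'   `pct_subgroup`, `pct_overall`, `delta_pp`, `n_trials`.
#' @export
first_hit_deltas <- function(hits, strata, by = "age_band") {
  overall <- first_hit_distribution(hits, level = "category")
  strat <- stratified_first_hit(hits, strata, by = by, level = "category")
  sizes <- dplyr::distinct(strat, .data$ad_id, .data$level, .data$n_trials)
  out <- purrr::map(unique(strat$level), function(lv) {
    d <- delta_matrix(strat[strat$level == lv, , drop = FALSE], overall)
    d$stratum <- by
    d$level <- lv
    d
  })
  out <- dplyr::bind_rows(out)
  out <- dplyr::left_join(out, sizes, by = c("ad_id", "level"))
  dplyr::relocate(out, "stratum", "level", .after = "ad_id")
}

quadrant_actions <- c(early_sticky = "protect",
                      late_sticky = "promote",
                      early_not_sticky = "unclutter",
                      neither = "reconsider")

#' Early-vs-sticky quadrant classification
#'
#' Crosses each AOI's first-hit percentage (early capture) with its
#' dominance score (sustained attention). "Early" means a first-hit share
#' at or above the within-ad median of first-hit percentages (computed over
#' all ranked AOIs, never-hit AOIs counting as 0%); "sticky" means a
#' strictly positive dominance score. The four quadrants map to design
#' actions: early + sticky -> protect; late + sticky -> promote (move
#' earlier); early + not sticky -> unclutter (strengthen payoff); neither
#' -> reconsider.
#'
#' @param dist AOI-level first-hit distribution for one ad (from
#'   [first_hit_distribution()] with `level = "aoi"`).
#' @param ranking AOI-level [dominance_scores()] for the same ad.
#' @return Tibble of class `quadrant_assignment`: `ad_id`, `aoi_id`,
#'   `first_hit_pct`, `s`, `early`, `sticky`, `quadrant`, `action`; the
#'   within-ad median is stored in the `median_first_hit_pct` attribute.
#' @export
classify_quadrants <- function(dist, ranking) {
  stopifnot(is.data.frame(dist), is.data.frame(ranking))
  rk <- tibble::as_tibble(ranking)
  if (!"aoi_id" %in% names(rk)) {
    abort_gd("schema", "classify_quadrants needs an AOI-level dominance ranking.")
  }
  d <- tibble::as_tibble(dist)
  extra <- setdiff(d$aoi_id, rk$aoi_id)
  if (length(extra) > 0) {
    abort_gd("validation",
             paste0("First-hit AOIs absent from the dominance ranking: ",
                    paste(extra, collapse = ", "), "."))
  }
  out <- dplyr::left_join(rk[, c("ad_id", "aoi_id", "s")],
                          d[, c("aoi_id", "pct")], by = "aoi_id")
  out$pct[is.na(out$pct)] <- 0
  med <- stats::median(out$pct)
  out <- out |>
    dplyr::mutate(
      first_hit_pct = .data$pct, pct = NULL,
      early = .data$first_hit_pct >= med,
      sticky = !is.na(.data$s) & .data$s > 0,
      quadrant = dplyr::case_when(
        .data$early & .data$sticky ~ "early_sticky",
        !.data$early & .data$sticky ~ "late_sticky",
        .data$early & !.data$sticky ~ "early_not_sticky",
        TRUE ~ "neither"),
      action = unname(quadrant_actions[.data$quadrant]))
  out <- dplyr::relocate(out, "first_hit_pct", .after = "aoi_id")
  structure(out,
            class = c("quadrant_assignment", class(tibble::tibble())),
            median_first_hit_pct = med)
}
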