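#' Canonical AOI semantic categories
#'
#' Six semantic classes cover every annotated AOI: `Text`, `Image/Visual`,
#' `Symbol`, `Logo`, `Website/CTA`, and `Source/Authority`. The vector is
#' ordered by overlap priority (highest first): when AOI polygons overlap,
#' a gaze point is attributed to the most actionable category —
#' Website/CTA > Logo > Symbol > Source/Authority > Text > Image/Visual.
#'
#' @return Character vector of the six category labels, highest priority
#'   first.
#' @export
#' @examples
#' aoi_categories()
aoi_categories <- function() {
  c("Website/CTA", "Logo", "Symbol", "Source/Authority", "Text", "Image/Visual")
}

#' Priority rank of a category (1 = highest)
#' @param category character vector of canonical category labels.
#' @return Integer ranks; smaller wins overlap contests.
#' @export
category_priority <- function(category) {
  rank <- match(category, aoi_categories())
  if (anyNA(rank)) {
    bad <- unique(category[is.na(rank)])
    abort_gd("validation",
      paste0("Unknown AOI category: ", paste(shQuote(bad), collapse = ", "),
             ". Canonical categories are: ",
             paste(aoi_categories(), collapse = ", "), "."))
  }
  rank
}

#' Screen and recording geometry
#'
#' Describes the display and eye-tracker set-up needed to convert between
#' pixels and degrees of visual angle. Defaults mirror a 24-inch 1920 x 1080
#' LCD (active area about 53 x 30 cm) viewed at 60 cm, sampled at 60 Hz.
#'
#' @param width_px,height_px Display resolution in pixels.
#' @param width_cm,height_cm Physical active area in cm.
#' @param viewing_distance_cm Eye-to-screen distance in cm.
#' @param sampling_rate_hz Gaze sampling rate in Hz.
#' @return An object of class `screen_geometry` (a named list).
#' @export
#' @examples
#' geom <- screen_geometry()
#' px_per_degree(geom)
screen_geometry <- function(width_px = 1920, height_px = 1080,
                            width_cm = 53, height_cm = 30,
                            viewing_distance_cm = 60,
                            sampling_rate_hz = 60) {
  vals <- list(width_px = width_px, height_px = height_px,
               width_cm = width_cm, height_cm = height_cm,
               viewing_distance_cm = viewing_distance_cm,
               sampling_rate_hz = sampling_rate_hz)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      abort_gd("validation",
               sprintf("screen_geometry field '%s' must be a single positive number.", nm))
    }
  }
  structure(vals, class = "screen_geometry")
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("<screen_geometry> %d x %d px (%.1f x %.1f cm), distance %.1f cm, %.0f Hz\n",
              x$width_px, x$height_px, x$width_cm, x$height_cm,
              x$viewing_distance_cm, x$sampling_rate_hz))
  invisible(x)
}

#' Split a combined AOI label into ad and AOI identifiers
#'
#' Labels follow the `Ad3_SmallText2` naming scheme: the ad identifier,
#' one underscore, then the AOI name. Only the FIRST underscore splits, so
#' AOI names may themselves contain underscores.
#'
#' @param label Character vector of combined labels.
#' @return A tibble with columns `ad_id` and `aoi_name`, one row per label.
#' @export
#' @examples
#' parse_aoi_label(c("Ad3_SmallText2", "Ad6_MinistryLogo"))
parse_aoi_label <- function(label) {
  if (length(label) == 0) {
    return(tibble::tibble(ad_id = character(), aoi_name = character()))
  }
  if (!is.character(label) || anyNA(label) || any(!nzchar(label))) {
    abort_gd("parse", "AOI labels must be non-empty, non-missing strings.")
  }
  pos <- regexpr("_", label, fixed = TRUE)
  ad <- ifelse(pos > 0, substr(label, 1, pos - 1), NA_character_)
  nm <- ifelse(pos > 0, substr(label, pos + 1, nchar(label)), NA_character_)
  bad <- is.na(ad) | !nzchar(ad) | is.na(nm) | !nzchar(nm)
  if (any(bad)) {
    abort_gd("parse",
      paste0("Malformed AOI label(s): ",
             paste(shQuote(label[bad]), collapse = ", "),
             ". Expected '<ad>_<aoi>' with both parts non-empty."))
  }
  tibble::tibble(ad_id = ad, aoi_name = nm)
}

# case-insensitive synonym table for category normalization
.category_synonyms <- local({
  map <- c(
    "text" = "Text",
    "image" = "Image/Visual",
    "image/visual" = "Image/Visual",
    "visual" = "Image/Visual",
    "symbol" = "Symbol",
    "logo" = "Logo",
    "website" = "Website/CTA",
    "website/cta" = "Website/CTA",
    "cta" = "Website/CTA",
    "source" = "Source/Authority",
    "authority" = "Source/Authority",
    "source/authority" = "Source/Authority"
  )
  map
})

#' Normalize raw category labels to the six canonical classes
#'
#' Case-insensitive; accepts common synonyms (`"Image"` for
#' `"Image/Visual"`, `"Website"` for `"Website/CTA"`, `"Source"` or
#' `"Authority"` for `"Source/Authority"`).
#'
#' @param raw Character vector of raw category labels.
#' @return Character vector of canonical labels (see [aoi_categories()]).
#' @export
#' @examples
#' normalize_category(c("Image", "website", "Source/Authority"))
normalize_category <- function(raw) {
  if (length(raw) == 0) return(character())
  key <- tolower(trimws(as.character(raw)))
  out <- unname(.category_synonyms[key])
  if (anyNA(out)) {
    bad <- unique(raw[is.na(out)])
    abort_gd("validation",
      paste0("Unknown AOI category label(s): ",
             paste(shQuote(bad), collapse = ", "),
             ". Canonical categories are: ",
             paste(aoi_categories(), collapse = ", "), "."))
  }
  out
}

# required long-form columns (censored is optional on read)
.study_cols <- c("participant_id", "ad_id", "aoi_id", "category",
                 "ttff_ms", "fc", "fd_ms")
.strata_cols <- c("age_band", "household", "education")

#' Assemble a long-form attention study table
#'
#' One row per participant x ad x AOI holding time to first fixation
#' (`ttff_ms`, right-censored at `censor_ms`), the censoring flag, fixation
#' count (`fc`), total fixation duration (`fd_ms`), and optional participant
#' strata (`age_band`, `household`, `education`). The returned tibble
#' carries the screen geometry and exposure/censor durations as attributes
#' and is validated against the record invariants: a censored row has
#' `ttff_ms == censor_ms`, `fc == 0`, `fd_ms == 0`; no `ttff_ms` exceeds the
#' censor value; no `fd_ms` exceeds the exposure; the (participant, ad, aoi)
#' key is unique.
#'
#' @param records A data frame with the columns above (`censored` optional:
#'   inferred as `ttff_ms == censor_ms & fc == 0` when absent).
#' @param geometry A [screen_geometry()].
#' @param exposure_ms Stimulus exposure duration in ms.
#' @param censor_ms Right-censoring value for TTFF in ms.
#' @return A `study_table` tibble.
#' @export
study_table <- function(records, geometry = screen_geometry(),
                        exposure_ms = 10000, censor_ms = 10000) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(.study_cols, names(records))
  if (length(missing_cols) > 0) {
    abort_gd("schema",
      paste0("Study table is missing required column(s): ",
             paste(missing_cols, collapse = ", "), "."))
  }
  rec <- tibble::as_tibble(records)
  rec$participant_id <- as.character(rec$participant_id)
  rec$ad_id <- as.character(rec$ad_id)
  rec$aoi_id <- as.character(rec$aoi_id)
  rec$category <- normalize_category(rec$category)
  for (col in c("ttff_ms", "fc", "fd_ms")) {
    rec[[col]] <- as.double(rec[[col]])
    bad <- which(!is.finite(rec[[col]]) | rec[[col]] < 0)
    if (length(bad) > 0) {
      abort_gd("validation",
        sprintf("Column '%s' has negative or missing values at row(s) %s.",
                col, paste(utils::head(bad, 5), collapse = ", ")))
    }
  }
  if (!"censored" %in% names(rec)) {
    rec$censored <- rec$ttff_ms >= censor_ms & rec$fc == 0
  } else {
    rec$censored <- as.logical(rec$censored)
  }
  for (col in .strata_cols) {
    if (!col %in% names(rec)) rec[[col]] <- NA_character_
    else rec[[col]] <- as.character(rec[[col]])
  }
  rec <- rec[, c(.study_cols[1:4], "ttff_ms", "censored", "fc", "fd_ms", .strata_cols)]

  key <- paste(rec$participant_id, rec$ad_id, rec$aoi_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    abort_gd("validation",
      sprintf("Duplicate (participant, ad, aoi) key at row(s) %s.",
              paste(utils::head(dup, 5), collapse = ", ")))
  }
  bad_cens <- which(rec$censored &
                      (rec$ttff_ms != censor_ms | rec$fc != 0 | rec$fd_ms != 0))
  if (length(bad_cens) > 0) {
    abort_gd("validation",
      sprintf("Censored row(s) %s must have ttff_ms == %g, fc == 0, fd_ms == 0.",
              paste(utils::head(bad_cens, 5), collapse = ", "), censor_ms))
  }
  bad_ttff <- which(rec$ttff_ms > censor_ms)
  if (length(bad_ttff) > 0) {
    abort_gd("validation",
      sprintf("ttff_ms exceeds the censor value (%g ms) at row(s) %s.",
              censor_ms, paste(utils::head(bad_ttff, 5), collapse = ", ")))
  }
  bad_fd <- which(rec$fd_ms > exposure_ms)
  if (length(bad_fd) > 0) {
    abort_gd("validation",
      sprintf("fd_ms exceeds the exposure duration (%g ms) at row(s) %s.",
              exposure_ms, paste(utils::head(bad_fd, 5), collapse = ", ")))
  }
  new_study_table(rec, geometry, exposure_ms, censor_ms)
}

new_study_table <- function(rec, geometry, exposure_ms, censor_ms) {
  structure(rec,
            class = c("study_table", class(tibble::tibble())),
            geometry = geometry,
            exposure_ms = exposure_ms,
            censor_ms = censor_ms)
}

#' @export
print.study_table <- function(x, ...) {
  cat(sprintf("<study_table> %d records | %d participants | %d ads | exposure %g ms, censor %g ms\n",
              nrow(x), dplyr::n_distinct(x$participant_id),
              dplyr::n_distinct(x$ad_id),
              attr(x, "exposure_ms"), attr(x, "censor_ms")))
  NextMethod()
}

#' Exposure / censoring metadata of a study table
#' @param x A `study_table`.
#' @return Named list with `geometry`, `exposure_ms`, `censor_ms`.
#' @export
study_meta <- function(x) {
  list(geometry = attr(x, "geometry") %||% screen_geometry(),
       exposure_ms = attr(x, "exposure_ms") %||% 10000,
       censor_ms = attr(x, "censor_ms") %||% 10000)
}

#' Read a long-form attention study table from CSV
#'
#' Expects lower_snake_case headers: `participant_id, ad_id, aoi_id,
#' category, ttff_ms, fc, fd_ms`, optionally `censored` and the strata
#' columns `age_band, household, education`. When `censored` is absent it is
#' inferred from `ttff_ms == censor_ms & fc == 0`; when present it is
#' authoritative.
#'
#' @param path CSV file path.
#' @inheritParams study_table
#' @return A `study_table` tibble.
#' @export
read_study_table <- function(path, geometry = screen_geometry(),
                             exposure_ms = 10000, censor_ms = 10000) {
  if (!file.exists(path)) {
    abort_gd("io", sprintf("Study table file not found: '%s'.", path))
  }
  rec <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  study_table(rec, geometry = geometry,
              exposure_ms = exposure_ms, censor_ms = censor_ms)
}

#' Write a study table to CSV
#' @param x A `study_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path, progress = FALSE)
  invisible(path)
}

# classed condition helper: kind in parse/schema/validation/io/compute
abort_gd <- function(kind, message, ...) {
  rlang::abort(message,
               class = c(paste0("gazedominion_", kind, "_error"),
                         "gazedominion_error"),
               ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
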