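#' Run the full attention-analytics pipeline
#'
#' Executes every stage end to end — input (synthetic simulation, a
#' pre-computed long-form metric table, or raw gaze samples plus AOI
#' polygons), preprocessing, per-AOI metrics, first-hit analytics,
#' benchmark tables, dominance matrices with axiom checks and concordance,
#' subgroup deltas, quadrant diagnostics, and (optionally) atlas figures —
#' writing each stage's tables to the output directory together with a
#' machine-readable JSON manifest (parameters, seed, package version, QC
#' exclusions). Runs are deterministic for a fixed config and seed.
#'
#' @param config A YAML/JSON file path or an equivalent named list. Keys:
#'   `seed` (integer), `mask_threshold` (default 5), `sigma_deg` (default
#'   1.0), `render` (logical, default FALSE), `synthetic` (list passed to
#'   [synthetic_study_config()], e.g. `n_participants`), or `inputs` with
#'   either `study_csv` or both `gaze_csv` and `aoi_json` (plus optional
#'   `drift_csv`).
#' @param out_dir Output directory (created); overrides `output_dir` in
#'   the config.
#' @return Invisibly, a named list with every stage's outputs and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) {
      abort_gd("io", sprintf("[stage read] config file not found: '%s'.", config))
    }
    yaml::read_yaml(config)
  } else config
  stopifnot(is.list(cfg))
  out_dir <- out_dir %||% cfg$output_dir %||% "gazedominion_out"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed %||% 1)
  mask_threshold <- cfg$mask_threshold %||% 5
  sigma_deg <- cfg$sigma_deg %||% 1.0
  log_line <- function(stage, msg) {
    message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      abort_gd("compute",
               sprintf("[stage %s] %s", name, conditionMessage(e)))
    })
    log_line(name, sprintf("done in %.2f s",
                           as.numeric(Sys.time() - t0, units = "secs")))
    res
  }
  save_tbl <- function(x, name) {
    readr::write_csv(tibble::as_tibble(x),
                     file.path(out_dir, paste0(name, ".csv")),
                     progress = FALSE)
  }

  qc <- NULL
  input_mode <- NULL
  if (!is.null(cfg$inputs$study_csv)) {
    input_mode <- "study_csv"
    study <- stage("read", read_study_table(cfg$inputs$study_csv))
    strata <- dplyr::distinct(tibble::as_tibble(study), .data$participant_id,
                              .data$age_band, .data$household, .data$education)
  } else if (!is.null(cfg$inputs$gaze_csv)) {
    input_mode <- "gaze_csv"
    geometry <- screen_geometry()
    aois <- stage("read", read_aoi_json(cfg$inputs$aoi_json, geometry))
    samples <- stage("read", readr::read_csv(cfg$inputs$gaze_csv,
                                             show_col_types = FALSE,
                                             progress = FALSE))
    drift <- if (!is.null(cfg$inputs$drift_csv)) {
      readr::read_csv(cfg$inputs$drift_csv, show_col_types = FALSE,
                      progress = FALSE)
    } else NULL
    qc <- stage("qc", qc_trials(samples, drift = drift))
    save_tbl(qc, "qc_report")
    keep <- qc[!qc$excluded, c("participant_id", "ad_id")]
    samples <- dplyr::semi_join(samples, keep,
                                by = c("participant_id", "ad_id"))
    fixations <- stage("preprocess", {
      fx <- classify_fixations(samples, geometry = geometry)
      merge_fixations(fx, geometry = geometry)
    })
    fixations <- stage("assign", assign_fixations(fixations, aois))
    study <- stage("metrics",
                   compute_aoi_metrics(fixations, aois, geometry = geometry))
    strata <- NULL
  } else {
    input_mode <- "synthetic"
    syn_args <- cfg$synthetic %||% list()
    syn_cfg <- stage("simulate-config",
                     do.call(synthetic_study_config, syn_args))
    sim <- stage("simulate",
                 generate_study(syn_cfg, seed = seed,
                                emit_samples = isTRUE(cfg$emit_samples)))
    study <- sim$study
    strata <- sim$strata
  }
  save_tbl(study, "study_table")

  hits <- stage("first-hits", first_hits(study))
  dist_cat <- stage("first-hits", first_hit_distribution(hits, "category"))
  dist_aoi <- stage("first-hits", first_hit_distribution(hits, "aoi"))
  save_tbl(hits, "first_hits")
  save_tbl(dist_cat, "first_hit_category")
  save_tbl(dist_aoi, "first_hit_aoi")

  bench_aoi <- stage("benchmark", benchmark_table(study, "aoi"))
  bench_cat <- stage("benchmark", benchmark_table(study, "category"))
  save_tbl(bench_aoi, "benchmark_aoi")
  save_tbl(bench_cat, "benchmark_category")

  ads <- unique(study$ad_id)
  dom <- stage("dominance", {
    per_ad <- purrr::map(ads, function(ad) {
      rec <- dplyr::filter(tibble::as_tibble(study), .data$ad_id == ad)
      m <- apply_support_mask(pairwise_dwell_matrix(rec, "aoi"),
                              mask_threshold)
      cm <- apply_support_mask(category_dominance(rec), mask_threshold)
      pm <- apply_support_mask(ttff_precedence_matrix(rec, "category"),
                               mask_threshold)
      rk <- suppressWarnings(dominance_scores(m))
      list(ad = ad, matrix = m, cat_matrix = cm, precedence = pm,
           ranking = rk,
           axioms = dplyr::bind_rows(verify_axioms(m), verify_axioms(cm),
                                     verify_axioms(pm)),
           concordance = tryCatch(
             concordance(rk, bench_aoi[bench_aoi$ad_id == ad, ]),
             error = function(e) NULL))
    })
    stats::setNames(per_ad, ads)
  })
  save_tbl(dplyr::bind_rows(purrr::map(dom, ~ tidy(.x$matrix))),
           "dominance_matrix_aoi")
  save_tbl(dplyr::bind_rows(purrr::map(dom, ~ tidy(.x$cat_matrix))),
           "dominance_matrix_category")
  save_tbl(dplyr::bind_rows(purrr::map(dom, ~ tidy(.x$precedence))),
           "precedence_matrix_category")
  save_tbl(dplyr::bind_rows(purrr::map(dom, ~ tibble::as_tibble(.x$ranking))),
           "dominance_scores")
  save_tbl(dplyr::bind_rows(purrr::map(dom, "axioms")), "axiom_checks")
  conc <- dplyr::bind_rows(purrr::map(dom, "concordance"))
  if (nrow(conc) > 0) save_tbl(conc, "concordance")

  quads <- stage("diagnostics", {
    dplyr::bind_rows(purrr::map(dom, function(d) {
      tibble::as_tibble(classify_quadrants(
        dist_aoi[dist_aoi$ad_id == d$ad, ], d$ranking))
    }))
  })
  save_tbl(quads, "quadrants")

  deltas <- NULL
  if (!is.null(strata) && all(!is.na(strata$age_band))) {
    deltas <- stage("audience", {
      dplyr::bind_rows(purrr::map(
        c("age_band", "household", "education"),
        ~ first_hit_deltas(hits, strata, by = .x)))
    })
    save_tbl(deltas, "first_hit_deltas")
  }

  if (isTRUE(cfg$render)) {
    stage("render", {
      fig_dir <- file.path(out_dir, "figures")
      for (d in dom) {
        q <- classify_quadrants(dist_aoi[dist_aoi$ad_id == d$ad, ], d$ranking)
        dd <- if (!is.null(deltas)) {
          deltas[deltas$ad_id == d$ad & deltas$stratum == "age_band", ]
        } else NULL
        render_atlas_panel(d$ad, d$matrix, d$ranking,
                           cat_matrix = d$cat_matrix, quadrants = q,
                           deltas = dd, out_dir = fig_dir,
                           plots = c("dominance", "bars", "support",
                                     "category", "quadrants",
                                     if (!is.null(dd)) "deltas"))
      }
      invisible(NULL)
    })
  }

  manifest <- list(
    package = "gazedominion",
    version = as.character(utils::packageVersion("gazedominion")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed, input_mode = input_mode,
    mask_threshold = mask_threshold, sigma_deg = sigma_deg,
    n_participants = dplyr::n_distinct(study$participant_id),
    n_ads = length(ads), n_records = nrow(study),
    qc_excluded = if (is.null(qc)) 0 else sum(qc$excluded),
    config = cfg)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  log_line("manifest", file.path(out_dir, "manifest.json"))

  invisible(list(study = study, strata = strata, hits = hits,
                 first_hit_category = dist_cat, first_hit_aoi = dist_aoi,
                 benchmark_aoi = bench_aoi, benchmark_category = bench_cat,
                 dominance = dom, quadrants = quads, deltas = deltas,
                 qc = qc, manifest = manifest, out_dir = out_dir))
}
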