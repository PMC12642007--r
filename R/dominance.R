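#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

new_pairwise_matrix <- function(ad_id, keys, P, N, kind, level,
                                mask = NULL, mask_threshold = NA_real_) {
  dimnames(P) <- list(keys, keys)
  dimnames(N) <- list(keys, keys)
  structure(list(ad_id = ad_id, keys = keys, P = P, N = N,
                 kind = kind, level = level, mask = mask,
                 mask_threshold = mask_threshold),
            class = "pairwise_matrix")
}

#' @export
print.pairwise_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("<pairwise_matrix> ad %s | %s | level %s | %d keys%s\n",
              x$ad_id, x$kind, x$level, length(x$keys),
              if (!is.na(x$mask_threshold))
                sprintf(" | masked below N = %g", x$mask_threshold) else ""))
  print(round(x$P, digits))
  invisible(x)
}

# per-participant wide value matrix (participants x keys), NA = unobserved
dwell_wide <- function(rec, key) {
  parts <- sort(unique(rec$participant_id))
  keys <- sort(unique(rec[[key]]))
  val <- matrix(NA_real_, length(parts), length(keys),
                dimnames = list(parts, keys))
  obs <- rec[!rec$censored, , drop = FALSE]
  val[cbind(match(obs$participant_id, parts), match(obs[[key]], keys))] <- obs$fd_ms
  val
}

#' Tie-aware pairwise dwell-dominance matrix
#'
#' For each unordered AOI (or category) pair (i, j) of one ad, restricted
#' to participants who fixated BOTH keys, `P[i, j]` estimates the
#' probability that key i receives more dwell than key j, with exact ties
#' counted as one half. The support `N[i, j]` is the number of contributing
#' participants. By construction `P[i, i] = 0.5` and
#' `P[i, j] + P[j, i] = 1` wherever defined; pairs with no joint observer
#' are `NA` (undefined, distinct from display masking). At the category
#' level, dwell is first summed within category per participant, and a
#' participant observes a category iff at least one of its AOIs was
#' fixated.
#'
#' @param records One ad's [study_table()] rows.
#' @param level `"aoi"` or `"category"`.
#' @return A `pairwise_matrix` object (fields `ad_id`, `keys`, `P`, `N`,
#'   `kind = "dwell"`).
#' @export
pairwise_dwell_matrix <- function(records, level = c("aoi", "category")) {
  level <- match.arg(level)
  rec <- one_ad(records)
  if (level == "category") {
    rec <- rec |>
      dplyr::group_by(.data$participant_id, .data$ad_id, .data$category) |>
      dplyr::summarise(fd_ms = sum(.data$fd_ms),
                       censored = all(.data$censored), .groups = "drop")
    key <- "category"
  } else {
    key <- "aoi_id"
  }
  if (dplyr::n_distinct(rec[[key]]) < 2) {
    abort_gd("validation",
             sprintf("Need at least 2 %s keys to build a pairwise matrix.", level))
  }
  val <- dwell_wide(rec, key)
  pm <- pairwise_from_values(val, tie_eq = TRUE)
  new_pairwise_matrix(rec$ad_id[1], colnames(val), pm$P, pm$N,
                      kind = "dwell", level = level)
}

# shared win-count core: val is participants x keys, NA = unobserved
pairwise_from_values <- function(val, tie_eq = TRUE) {
  K <- ncol(val)
  P <- matrix(NA_real_, K, K)
  N <- matrix(0, K, K)
  diag(P) <- 0.5
  diag(N) <- colSums(!is.na(val))
  if (K >= 2) {
    for (i in seq_len(K - 1)) {
      for (j in (i + 1):K) {
        both <- !is.na(val[, i]) & !is.na(val[, j])
        n <- sum(both)
        N[i, j] <- N[j, i] <- n
        if (n > 0) {
          wins <- sum(val[both, i] > val[both, j])
          ties <- sum(val[both, i] == val[both, j])
          P[i, j] <- (wins + 0.5 * ties) / n
          P[j, i] <- 1 - P[i, j]
        }
      }
    }
  }
  list(P = P, N = N)
}

#' Category-level dwell dominance
#'
#' Convenience wrapper: [pairwise_dwell_matrix()] at `level = "category"`,
#' i.e. dwell aggregated within category per participant before pairwise
#' comparison. Categories absent from the ad are simply not rows/columns.
#'
#' @inheritParams pairwise_dwell_matrix
#' @return A `pairwise_matrix`.
#' @export
category_dominance <- function(records) {
  pairwise_dwell_matrix(records, level = "category")
}

#' TTFF precedence matrix
#'
#' Pairwise matrix where an EARLIER first fixation counts as the win.
#' For a pair (i, j), participants contribute when at least one of the two
#' keys is uncensored: with both uncensored, the smaller TTFF wins (equal
#' values count one half); with exactly one censored, the uncensored key
#' wins; participants censored on both are excluded from the support.
#'
#' @param records One ad's [study_table()] rows.
#' @param level `"category"` (the conventional reporting level) or
#'   `"aoi"`.
#' @return A `pairwise_matrix` with `kind = "precedence"`.
#' @export
ttff_precedence_matrix <- function(records, level = c("category", "aoi")) {
  level <- match.arg(level)
  rec <- one_ad(records)
  if (level == "category") {
    rec <- rec |>
      dplyr::group_by(.data$participant_id, .data$ad_id, .data$category) |>
      dplyr::summarise(ttff_ms = min(.data$ttff_ms),
                       censored = all(.data$censored), .groups = "drop")
    key <- "category"
  } else {
    key <- "aoi_id"
  }
  if (dplyr::n_distinct(rec[[key]]) < 2) {
    abort_gd("validation",
             sprintf("Need at least 2 %s keys to build a pairwise matrix.", level))
  }
  parts <- sort(unique(rec$participant_id))
  keys <- sort(unique(rec[[key]]))
  tt <- matrix(NA_real_, length(parts), length(keys),
               dimnames = list(parts, keys))
  cen <- matrix(TRUE, length(parts), length(keys),
                dimnames = list(parts, keys))
  idx <- cbind(match(rec$participant_id, parts), match(rec[[key]], keys))
  tt[idx] <- rec$ttff_ms
  cen[idx] <- rec$censored
  K <- length(keys)
  P <- matrix(NA_real_, K, K); diag(P) <- 0.5
  N <- matrix(0, K, K)
  diag(N) <- colSums(!is.na(tt) & !cen)
  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) {
      seen <- !is.na(tt[, i]) & !is.na(tt[, j])   # key present in trial
      contrib <- seen & !(cen[, i] & cen[, j])
      n <- sum(contrib)
      N[i, j] <- N[j, i] <- n
      if (n > 0) {
        ci <- cen[contrib, i]; cj <- cen[contrib, j]
        ti <- tt[contrib, i]; tj <- tt[contrib, j]
        wins <- sum((!ci & cj) | (!ci & !cj & ti < tj))
        ties <- sum(!ci & !cj & ti == tj)
        P[i, j] <- (wins + 0.5 * ties) / n
        P[j, i] <- 1 - P[i, j]
      }
    }
  }
  new_pairwise_matrix(rec$ad_id[1], keys, P, N,
                      kind = "precedence", level = level)
}

#' Dominance scores from a pairwise matrix
#'
#' For each key, the mean win probability over its DEFINED off-diagonal
#' pairs, rescaled to `s = 2 * (pbar - 0.5)`, giving an index in
#' \[-1, 1\]: +1 wins every contest without ties, -1 loses every contest,
#' 0 is neutral. When every pair is defined the scores sum to zero. Keys
#' with no defined pair get `NA` with a warning. Ranks are by descending
#' score, ties broken by key order.
#'
#' @param matrix A `pairwise_matrix`.
#' @return A tibble of class `dominance_ranking`: `ad_id`, key column,
#'   `pbar`, `s`, `rank`, `n_pairs`.
#' @export
dominance_scores <- function(matrix) {
  stopifnot(inherits(matrix, "pairwise_matrix"))
  P <- matrix$P
  K <- length(matrix$keys)
  off <- P
  diag(off) <- NA_real_
  pbar <- rowMeans(off, na.rm = TRUE)
  n_pairs <- rowSums(!is.na(off))
  pbar[n_pairs == 0] <- NA_real_
  if (any(n_pairs == 0)) {
    warning("Isolated key(s) with no defined pairwise comparison: ",
            paste(matrix$keys[n_pairs == 0], collapse = ", "),
            "; dominance score reported as NA.")
  }
  s <- 2 * (pbar - 0.5)
  ord <- order(-s, matrix$keys, na.last = TRUE)
  rank <- integer(K)
  rank[ord] <- seq_len(K)
  key_col <- if (matrix$level == "category") "category" else "aoi_id"
  out <- tibble::tibble(ad_id = matrix$ad_id,
                        !!key_col := matrix$keys,
                        pbar = unname(pbar), s = unname(s),
                        rank = rank, n_pairs = unname(n_pairs))
  structure(out, class = c("dominance_ranking", class(tibble::tibble())),
            level = matrix$level, kind = matrix$kind)
}

#' Mask low-support cells for display
#'
#' Flags cells whose pairwise support `N` falls below `threshold`
#' (default 5 joint observers). Masking affects figures only: `P`, `N`,
#' and all downstream scores are unchanged.
#'
#' @param matrix A `pairwise_matrix`.
#' @param threshold Minimum support for display.
#' @return The matrix with a logical `mask` field set.
#' @export
apply_support_mask <- function(matrix, threshold = 5) {
  stopifnot(inherits(matrix, "pairwise_matrix"))
  mask <- matrix$N < threshold
  diag(mask) <- FALSE
  matrix$mask <- mask
  matrix$mask_threshold <- threshold
  matrix
}

#' Check pairwise-matrix construction axioms
#'
#' Verifies the two algebraic identities that every pairwise matrix must
#' satisfy by construction: off-diagonal complementarity
#' `P[i, j] + P[j, i] = 1` over defined pairs, and neutrality
#' `P[i, i] = 0.5` on the diagonal, both within `tol`.
#'
#' @param matrix A `pairwise_matrix`.
#' @param tol Numerical tolerance.
#' @return Tibble: `ad_id`, `kind`, `level`, `max_offdiag_dev`,
#'   `max_diag_dev`, `pass`.
#' @export
verify_axioms <- function(matrix, tol = 1e-12) {
  stopifnot(inherits(matrix, "pairwise_matrix"))
  P <- matrix$P
  S <- P + t(P)
  diag(S) <- NA_real_
  off_dev <- abs(S - 1)
  max_off <- if (all(is.na(off_dev))) 0 else max(off_dev, na.rm = TRUE)
  max_diag <- max(abs(diag(P) - 0.5))
  tibble::tibble(ad_id = matrix$ad_id, kind = matrix$kind,
                 level = matrix$level,
                 max_offdiag_dev = max_off, max_diag_dev = max_diag,
                 pass = max_off <= tol && max_diag <= tol)
}

#' Concordance between dominance scores and median dwell
#'
#' Pearson and Spearman correlations between each AOI's dominance score and
#' its median total fixation duration from the benchmark table — a
#' robustness check that the pairwise index agrees with conventional dwell
#' summaries.
#'
#' @param ranking A [dominance_scores()] result at AOI level.
#' @param benchmark A [benchmark_table()] at AOI level (same ad).
#' @return Tibble: `ad_id`, `n_keys`, `pearson_r`, `spearman_rho`.
#' @export
concordance <- function(ranking, benchmark) {
  stopifnot(is.data.frame(ranking), is.data.frame(benchmark))
  j <- dplyr::inner_join(
    tibble::as_tibble(ranking)[, c("ad_id", "aoi_id", "s")],
    tibble::as_tibble(benchmark)[, c("ad_id", "aoi_id", "median_fd_ms")],
    by = c("ad_id", "aoi_id"))
  j <- j[stats::complete.cases(j$s, j$median_fd_ms), , drop = FALSE]
  if (nrow(j) < 3) {
    abort_gd("validation",
             "Concordance needs at least 3 AOIs shared between ranking and benchmark.")
  }
  r <- rho <- NA_real_
  if (stats::sd(j$s) > 0 && stats::sd(j$median_fd_ms) > 0) {
    r <- stats::cor(j$s, j$median_fd_ms, method = "pearson")
    rho <- stats::cor(j$s, j$median_fd_ms, method = "spearman")
  } else {
    warning("Zero variance in scores or median dwell; correlation undefined.")
  }
  tibble::tibble(ad_id = j$ad_id[1], n_keys = nrow(j),
                 pearson_r = r, spearman_rho = rho)
}

#' @rdname tidy.pairwise_matrix
#' @export
tidy.pairwise_matrix <- function(x, ...) {
  K <- length(x$keys)
  grid <- expand.grid(i = seq_len(K), j = seq_len(K))
  tibble::tibble(
    ad_id = x$ad_id, kind = x$kind, level = x$level,
    key_i = x$keys[grid$i], key_j = x$keys[grid$j],
    p = x$P[cbind(grid$i, grid$j)],
    n = x$N[cbind(grid$i, grid$j)],
    masked = if (is.null(x$mask)) FALSE else x$mask[cbind(grid$i, grid$j)])
}

#' Tidy a pairwise matrix into long form
#'
#' One row per ordered key pair with win probability `p`, support `n`, and
#' the display `masked` flag.
#'
#' @param x A `pairwise_matrix`.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy.pairwise_matrix
NULL

#' @export
glance.pairwise_matrix <- function(x, ...) {
  ax <- verify_axioms(x)
  tibble::tibble(ad_id = x$ad_id, kind = x$kind, level = x$level,
                 n_keys = length(x$keys),
                 n_defined_pairs = sum(!is.na(x$P[upper.tri(x$P)])),
                 min_support = min(x$N[upper.tri(x$N)]),
                 axioms_pass = ax$pass)
}

one_ad <- function(records) {
  stopifnot(is.data.frame(records))
  rec <- tibble::as_tibble(records)
  if (nrow(rec) == 0) abort_gd("validation", "Empty record set.")
  if (dplyr::n_distinct(rec$ad_id) > 1) {
    abort_gd("validation",
             "Records span multiple ads; filter to one ad (e.g. with dplyr::filter) first.")
  }
  rec
}
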