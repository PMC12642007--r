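#' Gaussian attention heatmap
#'
#' Splats fixation centroids onto a pixel grid (weighted by fixation
#' duration by default, or by count), convolves with an isotropic Gaussian
#' whose width is given in degrees of visual angle, and normalizes the
#' grid maximum to 1. An empty fixation set yields an all-zero grid.
#'
#' @param fixations Fixation tibble with `cx_px`, `cy_px`, `duration_ms`.
#' @param geometry A [screen_geometry()].
#' @param sigma_deg Gaussian standard deviation in degrees (default 1.0,
#'   the low end of the conventional 1-1.5 degree band).
#' @param weight `"duration"` (dwell-proportional) or `"count"`.
#' @param downsample Integer grid down-sampling factor (1 = native
#'   resolution).
#' @param label Optional subgroup / ad label stored on the grid.
#' @return An object of class `heatmap_grid`: `values` (rows = y,
#'   columns = x, in \[0, 1\]), `sigma_deg`, `downsample`, `label`.
#' @export
attention_heatmap <- function(fixations, geometry = screen_geometry(),
                              sigma_deg = 1.0,
                              weight = c("duration", "count"),
                              downsample = 4, label = "overall") {
  weight <- match.arg(weight)
  if (sigma_deg <= 0) abort_gd("validation", "sigma_deg must be positive.")
  nx <- ceiling(geometry$width_px / downsample)
  ny <- ceiling(geometry$height_px / downsample)
  grid <- matrix(0, nrow = ny, ncol = nx)
  fx <- tibble::as_tibble(fixations)
  fx <- fx[is.finite(fx$cx_px) & is.finite(fx$cy_px), , drop = FALSE]
  fx <- fx[fx$cx_px >= 0 & fx$cx_px < geometry$width_px &
             fx$cy_px >= 0 & fx$cy_px < geometry$height_px, , drop = FALSE]
  if (nrow(fx) > 0) {
    ix <- pmin(floor(fx$cx_px / downsample) + 1, nx)
    iy <- pmin(floor(fx$cy_px / downsample) + 1, ny)
    w <- if (weight == "duration") fx$duration_ms else rep(1, nrow(fx))
    for (k in seq_len(nrow(fx))) {
      grid[iy[k], ix[k]] <- grid[iy[k], ix[k]] + w[k]
    }
    sigma_px <- sigma_deg * px_per_degree(geometry) / downsample
    grid <- gaussian_blur(grid, sigma_px)
    mx <- max(grid)
    if (mx > 0) grid <- grid / mx
  }
  structure(list(values = grid, sigma_deg = sigma_deg,
                 downsample = downsample, label = label,
                 weight = weight),
            class = "heatmap_grid")
}

# separable Gaussian convolution with zero padding
gaussian_blur <- function(m, sigma_px) {
  r <- max(1, ceiling(3 * sigma_px))
  k <- stats::dnorm(-r:r, sd = sigma_px)
  k <- k / sum(k)
  conv_same <- function(v) {
    full <- stats::convolve(v, k, type = "open")   # symmetric kernel
    full[(r + 1):(r + length(v))]
  }
  m <- apply(m, 2, conv_same)
  t(apply(m, 1, conv_same))
}

#' @export
print.heatmap_grid <- function(x, ...) {
  cat(sprintf("<heatmap_grid> %d x %d (downsample %d) | sigma %.2f deg | max %.3f | %s\n",
              nrow(x$values), ncol(x$values), x$downsample,
              x$sigma_deg, max(x$values), x$label))
  invisible(x)
}

#' @export
autoplot.heatmap_grid <- function(object, ...) {
  df <- tidyr::expand_grid(y = seq_len(nrow(object$values)),
                           x = seq_len(ncol(object$values)))
  df$intensity <- object$values[cbind(df$y, df$x)]
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = object$label, fill = "Intensity") +
    ggplot2::theme_minimal()
}

# long-form tibble of a pairwise matrix with dominance ordering applied
matrix_plot_data <- function(m, order_by_dominance = TRUE) {
  keys <- m$keys
  if (order_by_dominance) {
    rk <- suppressWarnings(dominance_scores(m))
    keys <- rk[[setdiff(names(rk), c("ad_id", "pbar", "s", "rank", "n_pairs"))]][
      order(rk$rank)]
  }
  td <- tidy(m)
  td$key_i <- factor(td$key_i, levels = rev(keys))
  td$key_j <- factor(td$key_j, levels = keys)
  td
}

#' Plot a pairwise matrix as a win-probability heatmap
#'
#' Rows and columns are ordered by descending dominance score; cells whose
#' support falls below the mask threshold (see [apply_support_mask()]) are
#' greyed out with their support printed, so low-evidence comparisons are
#' visible but not colour-coded.
#'
#' @param object A `pairwise_matrix`.
#' @param order_by_dominance Reorder keys by dominance score.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pairwise_matrix <- function(object, order_by_dominance = TRUE, ...) {
  td <- matrix_plot_data(object, order_by_dominance)
  td$fill <- ifelse(td$masked, NA_real_, td$p)
  ggplot2::ggplot(td, ggplot2::aes(.data$key_j, .data$key_i)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$fill), colour = "white") +
    ggplot2::geom_text(
      data = td[td$masked, , drop = FALSE],
      ggplot2::aes(label = paste0("N=", .data$n)), size = 2.6) +
    ggplot2::scale_fill_gradient2(midpoint = 0.5, limits = c(0, 1),
                                  low = "#2166AC", high = "#B2182B",
                                  mid = "#F7F7F7", na.value = "grey85") +
    ggplot2::labs(title = sprintf("%s %s matrix, ad %s", object$level,
                                  object$kind, object$ad_id),
                  x = NULL, y = NULL, fill = "P(win)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Companion support-N heatmap
#'
#' @param m A `pairwise_matrix`.
#' @return A ggplot object showing the pairwise support counts.
#' @export
plot_support <- function(m) {
  td <- matrix_plot_data(m, order_by_dominance = FALSE)
  ggplot2::ggplot(td, ggplot2::aes(.data$key_j, .data$key_i, fill = .data$n)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 2.6) +
    ggplot2::scale_fill_gradient(low = "#FFFFFF", high = "#2C7FB8") +
    ggplot2::labs(title = sprintf("Pairwise support, ad %s", m$ad_id),
                  x = NULL, y = NULL, fill = "N") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Bar chart of the top AOIs by dominance score
#'
#' @param ranking A [dominance_scores()] tibble.
#' @param top_n Number of top-ranked keys to show (default 5).
#' @return A ggplot object.
#' @export
plot_dominance_bars <- function(ranking, top_n = 5) {
  key_col <- intersect(c("aoi_id", "category"), names(ranking))[1]
  d <- tibble::as_tibble(ranking)
  d <- d[order(d$rank), , drop = FALSE][seq_len(min(top_n, nrow(d))), ]
  d$key <- factor(d[[key_col]], levels = rev(d[[key_col]]))
  ggplot2::ggplot(d, ggplot2::aes(.data$s, .data$key)) +
    ggplot2::geom_col(fill = "#2C7FB8") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(title = sprintf("Top %d by dominance, ad %s",
                                  nrow(d), d$ad_id[1]),
                  x = "Dominance score s", y = NULL) +
    ggplot2::theme_minimal()
}

#' Early-vs-sticky quadrant scatter
#'
#' First-hit percentage against dominance score, with the within-ad median
#' first-hit reference (vertical) and the s = 0 reference (horizontal).
#'
#' @param object A [classify_quadrants()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.quadrant_assignment <- function(object, ...) {
  med <- attr(object, "median_first_hit_pct")
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$first_hit_pct, .data$s,
                               colour = .data$action)) +
    ggplot2::geom_vline(xintercept = med, linetype = 2, colour = "grey40") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_text(ggplot2::aes(label = .data$aoi_id),
                       vjust = -0.8, size = 2.8, show.legend = FALSE) +
    ggplot2::labs(title = sprintf("Early vs sticky, ad %s", object$ad_id[1]),
                  x = "First-hit %", y = "Dominance score s",
                  colour = "Action") +
    ggplot2::theme_minimal()
}

#' Stacked first-hit distribution bars
#'
#' @param dist A [first_hit_distribution()] tibble (any number of ads).
#' @return A ggplot object.
#' @export
plot_first_hit <- function(dist) {
  key_col <- intersect(c("category", "aoi_id"), names(dist))[1]
  ggplot2::ggplot(dist, ggplot2::aes(.data$ad_id, .data$pct,
                                     fill = .data[[key_col]])) +
    ggplot2::geom_col() +
    ggplot2::labs(title = "First-hit distribution", x = NULL,
                  y = "First-hit %", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Subgroup delta heatmap
#'
#' Percentage-point first-hit shifts (subgroup minus overall) by category
#' and stratum level.
#'
#' @param deltas A [first_hit_deltas()] tibble for one ad.
#' @return A ggplot object.
#' @export
plot_delta <- function(deltas) {
  ggplot2::ggplot(deltas, ggplot2::aes(.data$level, .data$category,
                                       fill = .data$delta_pp)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%+.1f", .data$delta_pp)),
                       size = 2.6) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "#F7F7F7",
                                  high = "#B2182B", midpoint = 0) +
    ggplot2::labs(title = sprintf("First-hit deltas (%s), ad %s",
                                  deltas$stratum[1], deltas$ad_id[1]),
                  x = NULL, y = NULL, fill = expression(Delta ~ "pp")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Render an atlas panel for one ad
#'
#' Writes the selected figures (vector PDF and raster PNG) together with
#' the exact tables they render, so every plotted number is also available
#' as delimited text. The dominance heatmap is ordered by descending
#' dominance score; masked cells show their support; the quadrant scatter
#' carries the within-ad median and s = 0 reference lines.
#'
#' @param ad_id Ad identifier (used in file names).
#' @param matrix AOI-level `pairwise_matrix` (masked via
#'   [apply_support_mask()]).
#' @param ranking AOI-level [dominance_scores()].
#' @param cat_matrix Optional category-level `pairwise_matrix`.
#' @param quadrants Optional [classify_quadrants()] result.
#' @param deltas Optional [first_hit_deltas()] tibble for this ad.
#' @param out_dir Output directory (created if absent).
#' @param plots Subset of `c("dominance", "bars", "category", "quadrants",
#'   "deltas", "support")` to render.
#' @param formats Figure formats, subset of `c("pdf", "png")`.
#' @param width,height Figure size in inches.
#' @return Invisibly, a tibble of written files.
#' @export
render_atlas_panel <- function(ad_id, matrix, ranking,
                               cat_matrix = NULL, quadrants = NULL,
                               deltas = NULL, out_dir,
                               plots = c("dominance", "bars", "support",
                                         "category", "quadrants", "deltas"),
                               formats = c("pdf", "png"),
                               width = 6, height = 4.5) {
  if (length(plots) == 0) abort_gd("validation", "No plots selected for the panel.")
  known <- c("dominance", "bars", "support", "category", "quadrants", "deltas")
  bad <- setdiff(plots, known)
  if (length(bad) > 0) {
    abort_gd("validation", paste0("Unknown panel plot(s): ",
                                  paste(bad, collapse = ", "), "."))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  items <- list()
  add <- function(name, plot_obj, table_obj) {
    items[[name]] <<- list(plot = plot_obj, table = table_obj)
  }
  if ("dominance" %in% plots) add("dominance", autoplot(matrix), tidy(matrix))
  if ("bars" %in% plots) {
    add("bars", plot_dominance_bars(ranking), tibble::as_tibble(ranking))
  }
  if ("support" %in% plots) add("support", plot_support(matrix), tidy(matrix))
  if ("category" %in% plots) {
    if (is.null(cat_matrix)) {
      abort_gd("validation", "Panel requests the category plot but cat_matrix is missing.")
    }
    add("category", autoplot(cat_matrix), tidy(cat_matrix))
  }
  if ("quadrants" %in% plots) {
    if (is.null(quadrants)) {
      abort_gd("validation", "Panel requests the quadrant plot but quadrants is missing.")
    }
    add("quadrants", autoplot(quadrants), tibble::as_tibble(quadrants))
  }
  if ("deltas" %in% plots) {
    if (is.null(deltas)) {
      abort_gd("validation", "Panel requests the delta plot but deltas is missing.")
    }
    add("deltas", plot_delta(deltas), tibble::as_tibble(deltas))
  }
  written <- list()
  for (nm in names(items)) {
    stem <- file.path(out_dir, sprintf("%s_%s", ad_id, nm))
    tab_path <- paste0(stem, ".csv")
    readr::write_csv(items[[nm]]$table, tab_path, progress = FALSE)
    written[[length(written) + 1]] <- tibble::tibble(
      ad_id = ad_id, item = nm, kind = "table", path = tab_path)
    for (fmt in formats) {
      fig_path <- paste0(stem, ".", fmt)
      ggplot2::ggsave(fig_path, items[[nm]]$plot, width = width,
                      height = height, dpi = 150)
      written[[length(written) + 1]] <- tibble::tibble(
        ad_id = ad_id, item = nm, kind = "figure", path = fig_path)
    }
  }
  invisible(dplyr::bind_rows(written))
}
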