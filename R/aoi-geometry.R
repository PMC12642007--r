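#' Pixels per degree of visual angle
#'
#' Converts the angular subtense of one degree at the viewing distance into
#' screen pixels: `2 * d * tan(0.5 deg)` centimetres, times the horizontal
#' pixel density. At 60 cm this is about 1.05 cm, i.e. roughly 38 px on a
#' 1920 px / 53 cm display.
#'
#' @param geometry A [screen_geometry()].
#' @return Pixels per degree (scalar).
#' @export
px_per_degree <- function(geometry) {
  stopifnot(inherits(geometry, "screen_geometry"))
  if (geometry$viewing_distance_cm <= 0) {
    abort_gd("validation", "Viewing distance must be strictly positive.")
  }
  cm_per_deg <- 2 * geometry$viewing_distance_cm * tan(pi / 360)
  cm_per_deg * geometry$width_px / geometry$width_cm
}

#' Build an AOI set from polygon definitions
#'
#' An AOI set is a tibble with one row per AOI: identifiers, semantic
#' category, the polygon vertices (list-column of two-column `x`/`y` pixel
#' matrices), the category overlap-priority rank, and the derived layout
#' covariates `area_px2` (shoelace area) and `eccentricity_px` (distance
#' from the polygon centroid to the screen centre).
#'
#' @param ad_id,aoi_id Character vectors (recycled) identifying each AOI.
#' @param category Raw category labels, normalized via
#'   [normalize_category()].
#' @param vertices List of numeric matrices / data frames with columns x, y
#'   (pixels, origin top-left), at least 3 vertices each.
#' @param geometry A [screen_geometry()] for eccentricity.
#' @return A tibble of class `aoi_set`.
#' @export
aoi_set <- function(ad_id, aoi_id, category, vertices,
                    geometry = screen_geometry()) {
  n <- length(vertices)
  ad_id <- rep_len(as.character(ad_id), n)
  aoi_id <- rep_len(as.character(aoi_id), n)
  category <- normalize_category(rep_len(category, n))
  verts <- lapply(vertices, function(v) {
    m <- as.matrix(as.data.frame(v))[, 1:2, drop = FALSE]
    storage.mode(m) <- "double"
    colnames(m) <- c("x", "y")
    if (nrow(m) < 3 || anyNA(m)) {
      abort_gd("validation", "Each AOI polygon needs >= 3 finite vertices.")
    }
    m
  })
  desc <- purrr::map(verts, polygon_descriptors, geometry = geometry)
  out <- tibble::tibble(
    ad_id = ad_id, aoi_id = aoi_id, category = category,
    vertices = verts,
    priority_rank = category_priority(category),
    area_px2 = purrr::map_dbl(desc, "area_px2"),
    eccentricity_px = purrr::map_dbl(desc, "eccentricity_px"))
  if (any(out$area_px2 <= 0)) {
    bad <- out$aoi_id[out$area_px2 <= 0]
    abort_gd("validation",
             paste0("Degenerate (zero-area) AOI polygon(s): ",
                    paste(bad, collapse = ", "), "."))
  }
  class(out) <- c("aoi_set", class(out))
  out
}

# shoelace area + centroid-to-screen-centre distance
polygon_descriptors <- function(vertices, geometry) {
  x <- vertices[, 1]; y <- vertices[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  cross <- x * ys - xs * y
  a2 <- sum(cross)                        # 2 * signed area
  area <- abs(a2) / 2
  if (area > 0) {
    cx <- sum((x + xs) * cross) / (3 * a2)
    cy <- sum((y + ys) * cross) / (3 * a2)
  } else {
    cx <- mean(x); cy <- mean(y)
  }
  ecc <- sqrt((cx - geometry$width_px / 2)^2 + (cy - geometry$height_px / 2)^2)
  list(area_px2 = area, eccentricity_px = ecc,
       centroid = c(x = cx, y = cy))
}

#' AOI layout covariates
#'
#' @param aois An [aoi_set()].
#' @return Tibble with `ad_id`, `aoi_id`, `category`, `area_px2`,
#'   `eccentricity_px`.
#' @export
aoi_descriptors <- function(aois) {
  stopifnot(inherits(aois, "aoi_set"))
  tibble::as_tibble(aois)[, c("ad_id", "aoi_id", "category",
                              "area_px2", "eccentricity_px")]
}

#' Point-in-polygon test (closed boundary)
#'
#' Even-odd ray casting with an explicit edge test: points exactly on a
#' polygon edge or vertex count as inside, matching the closed-polygon
#' convention used for AOI delineation.
#'
#' @param x,y Point coordinates (vectors of equal length), pixels.
#' @param vertices Two-column vertex matrix of a simple polygon.
#' @return Logical vector.
#' @export
point_in_polygon <- function(x, y, vertices) {
  vx <- vertices[, 1]; vy <- vertices[, 2]
  n <- length(vx)
  jx <- c(vx[n], vx[-n]); jy <- c(vy[n], vy[-n])   # previous vertex
  vapply(seq_along(x), function(k) {
    px <- x[k]; py <- y[k]
    # edge / vertex membership
    on_edge <- any(
      (vx - px) * (jy - py) - (jx - px) * (vy - py) == 0 &
        px >= pmin(vx, jx) & px <= pmax(vx, jx) &
        py >= pmin(vy, jy) & py <= pmax(vy, jy))
    if (on_edge) return(TRUE)
    crosses <- ((vy > py) != (jy > py)) &
      (px < (jx - vx) * (py - vy) / (jy - vy) + vx)
    sum(crosses) %% 2 == 1
  }, logical(1))
}

#' Assign points to AOIs under the overlap-priority rule
#'
#' Among the AOIs of one ad that contain a point, returns the AOI whose
#' category has the highest overlap priority
#' (Website/CTA > Logo > Symbol > Source/Authority > Text > Image/Visual).
#' Equal-priority overlaps are broken deterministically: smaller pixel area
#' first, then lexicographic `aoi_id`. Points inside no polygon map to
#' `NA`.
#'
#' @param x,y Point coordinates in pixels (equal-length vectors).
#' @param aois An [aoi_set()]; all rows must share one `ad_id`.
#' @return Character vector of `aoi_id` (NA where unassigned).
#' @export
assign_fixation <- function(x, y, aois) {
  stopifnot(inherits(aois, "aoi_set"), length(x) == length(y))
  if (dplyr::n_distinct(aois$ad_id) > 1) {
    abort_gd("validation", "assign_fixation expects AOIs of a single ad.")
  }
  ord <- order(aois$priority_rank, aois$area_px2, aois$aoi_id)
  hits <- matrix(FALSE, nrow = length(x), ncol = nrow(aois))
  for (j in seq_len(nrow(aois))) {
    hits[, j] <- point_in_polygon(x, y, aois$vertices[[j]])
  }
  apply(hits[, ord, drop = FALSE], 1, function(h) {
    w <- which(h)
    if (length(w) == 0) NA_character_ else aois$aoi_id[ord[w[1]]]
  })
}

#' Attach AOI assignments to a fixation table
#'
#' Adds/overwrites an `aoi_id` column by assigning each fixation centroid
#' within its ad, and joins the AOI `category`.
#'
#' @param fixations Tibble with `ad_id`, `cx_px`, `cy_px` (one row per
#'   fixation).
#' @param aois An [aoi_set()] covering the ads present.
#' @return `fixations` with `aoi_id` and `category` columns.
#' @export
assign_fixations <- function(fixations, aois) {
  stopifnot(is.data.frame(fixations), inherits(aois, "aoi_set"))
  fixations <- tibble::as_tibble(fixations)
  fixations$aoi_id <- NA_character_
  for (ad in unique(fixations$ad_id)) {
    sub <- aois[aois$ad_id == ad, ]
    idx <- which(fixations$ad_id == ad)
    if (nrow(sub) == 0 || length(idx) == 0) next
    fixations$aoi_id[idx] <- assign_fixation(
      fixations$cx_px[idx], fixations$cy_px[idx], sub)
  }
  cat_map <- stats::setNames(aois$category, paste(aois$ad_id, aois$aoi_id))
  fixations$category <- unname(cat_map[paste(fixations$ad_id, fixations$aoi_id)])
  fixations
}

#' Read AOI definitions from JSON
#'
#' The JSON layout is a list of stimuli, each with `ad_id` and `aois`, each
#' AOI carrying `aoi_id`, `category`, and `vertices` (array of `[x, y]`
#' pixel pairs).
#'
#' @param path JSON file path.
#' @param geometry A [screen_geometry()].
#' @return An [aoi_set()].
#' @export
read_aoi_json <- function(path, geometry = screen_geometry()) {
  if (!file.exists(path)) {
    abort_gd("io", sprintf("AOI definition file not found: '%s'.", path))
  }
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- purrr::map(doc, function(stim) {
    purrr::map(stim$aois, function(a) {
      verts <- do.call(rbind, purrr::map(a$vertices, ~ as.numeric(unlist(.x))))
      list(ad_id = stim$ad_id, aoi_id = a$aoi_id,
           category = a$category, vertices = verts)
    })
  })
  rows <- purrr::flatten(rows)
  aoi_set(ad_id = purrr::map_chr(rows, "ad_id"),
          aoi_id = purrr::map_chr(rows, "aoi_id"),
          category = purrr::map_chr(rows, "category"),
          vertices = purrr::map(rows, "vertices"),
          geometry = geometry)
}

#' Write AOI definitions to JSON
#' @param aois An [aoi_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_aoi_json <- function(aois, path) {
  stopifnot(inherits(aois, "aoi_set"))
  by_ad <- split(seq_len(nrow(aois)), aois$ad_id)
  doc <- purrr::map(names(by_ad), function(ad) {
    idx <- by_ad[[ad]]
    list(ad_id = ad,
         aois = purrr::map(idx, function(i) {
           v <- aois$vertices[[i]]
           list(aoi_id = aois$aoi_id[i],
                category = aois$category[i],
                vertices = purrr::map(seq_len(nrow(v)),
                                      ~ c(v[.x, 1], v[.x, 2])))
         }))
  })
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
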