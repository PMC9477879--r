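# Voronoi quadrats over a tissue section and their typing into
# synchronous-DCIS / IDC / mixed / excluded components.

#' Number of Voronoi seeds for a region of interest
#'
#' The number of quadrat seeds is the cube root of the number of cells in the
#' region, rounded to the nearest integer (half away from zero) with a floor
#' of 2; fewer than two cells cannot be partitioned and give 0.
#'
#' @param n_cells Non-negative cell count.
#' @return Integer seed count.
#' @export
#' @examples
#' seed_count(1000) # 10
#' seed_count(100) # 5
seed_count <- function(n_cells) {
  if (!is.numeric(n_cells) || length(n_cells) != 1 || is.na(n_cells) || n_cells < 0) {
    abort("`n_cells` must be a non-negative count.", class = "ductcoloc_parameter_error")
  }
  if (n_cells < 2) {
    return(0L)
  }
  max(2L, as.integer(round(n_cells^(1 / 3))))
}

#' Voronoi tessellation of a cell map
#'
#' Seeds are the k-means centroids of the cell coordinates with
#' `k = seed_count(n)` (deterministic given `rng_seed`); the Voronoi diagram
#' of the seeds is clipped to the region of interest and every cell is
#' assigned to the polygon containing it (equivalently its nearest seed,
#' ties to the lowest polygon id). The default ROI is the convex hull of the
#' cells buffered by 50 um.
#'
#' @param cells A [cell_map()] or data frame with `x_um`, `y_um` (and
#'   ideally `cell_id`, `cell_class`).
#' @param roi Optional convex ROI ring (two-column matrix, microns).
#' @param rng_seed Seed for the k-means initialisation.
#' @param k Optional override of the seed count.
#' @param roi_buffer Buffer for the default ROI, microns.
#'
#' @return A `region_partition`: list with `polygons` (list of CCW rings),
#'   `regions` (tibble: `polygon_id`, `area_um2`, `n_cells`, `region_type`,
#'   `duct_area_fraction`, `duct_cell_fraction`), `assignment` (tibble:
#'   `cell_id`, `polygon_id`), `seeds`, `roi`, `cells`, `section_id`.
#' @export
tessellate <- function(cells, roi = NULL, rng_seed = 1L, k = NULL, roi_buffer = 50) {
  xy <- cbind(cells$x_um, cells$y_um)
  if (nrow(xy) < 2 || nrow(unique(xy)) < 2) {
    abort("fewer than two distinct cells; cannot partition the region.",
      class = "ductcoloc_degenerate_error"
    )
  }
  if (is.null(roi)) {
    roi <- convex_hull_buffered(xy[, 1], xy[, 2], buffer = roi_buffer)
  } else {
    roi <- normalise_ring(as.matrix(roi), "ccw")
    inside <- points_in_ring(xy[, 1], xy[, 2], roi)
    cells <- cells[inside, , drop = FALSE]
    xy <- xy[inside, , drop = FALSE]
  }
  if (abs(poly_area(roi)) <= 0) {
    abort("region of interest has zero area.", class = "ductcoloc_geometry_error")
  }
  n <- nrow(xy)
  k <- k %||% seed_count(n)
  if (k < 2) {
    abort("fewer than two cells (or seeds) in the region of interest.",
      class = "ductcoloc_degenerate_error"
    )
  }
  uxy <- unique(xy)
  k <- min(k, nrow(uxy))
  if (k < 2) {
    abort("cells are coincident; cannot place two distinct seeds.",
      class = "ductcoloc_degenerate_error"
    )
  }
  km <- withr::with_seed(
    as.integer(rng_seed),
    kmeans(uxy, centers = k, nstart = 5, iter.max = 100)
  )
  seeds <- unname(km$centers)
  polygons <- lapply(seq_len(k), voronoi_cell, seeds = seeds, roi = roi)
  # nearest-seed assignment == containing polygon; first minimum wins ties
  d2 <- outer(xy[, 1], seeds[, 1], `-`)^2 + outer(xy[, 2], seeds[, 2], `-`)^2
  poly_of_cell <- max.col(-d2, ties.method = "first")
  assignment <- tibble(
    cell_id = cells$cell_id %||% as.character(seq_len(n)),
    polygon_id = poly_of_cell
  )
  regions <- tibble(
    polygon_id = seq_len(k),
    area_um2 = vapply(polygons, function(p) abs(poly_area(p)), numeric(1)),
    n_cells = as.integer(tabulate(poly_of_cell, nbins = k)),
    region_type = NA_character_,
    duct_area_fraction = NA_real_,
    duct_cell_fraction = NA_real_
  )
  structure(
    list(
      polygons = polygons, regions = regions, assignment = assignment,
      seeds = seeds, roi = roi, cells = as_tibble(cells),
      section_id = section_id_of(cells)
    ),
    class = "region_partition"
  )
}

#' @export
print.region_partition <- function(x, ...) {
  cat(
    "<region_partition>", x$section_id, "-", length(x$polygons),
    "Voronoi polygons,", nrow(x$cells), "cells\n"
  )
  if (!all(is.na(x$regions$region_type))) {
    print(dplyr::count(x$regions, .data$region_type))
  }
  invisible(x)
}

#' Summarise a region partition
#'
#' @param x A `region_partition`.
#' @param ... Unused.
#' @return One-row tibble: polygon and cell counts, total area, and (after
#'   [classify_polygons()]) counts per region type.
#' @export
glance.region_partition <- function(x, ...) {
  out <- tibble(
    section_id = x$section_id,
    n_polygons = length(x$polygons),
    n_cells = nrow(x$cells),
    area_um2 = sum(x$regions$area_um2)
  )
  if (!all(is.na(x$regions$region_type))) {
    tt <- table(factor(x$regions$region_type,
      levels = c("synchronous_DCIS", "IDC", "mixed", "excluded")
    ))
    out <- bind_cols(out, as_tibble(as.list(tt)))
  }
  out
}

#' Tidy a region partition
#'
#' @param x A `region_partition`.
#' @param ... Unused.
#' @return The per-polygon `regions` tibble.
#' @export
tidy.region_partition <- function(x, ...) x$regions

#' Type Voronoi polygons from a duct mask
#'
#' Each polygon is typed by the composition of its epithelial cells:
#' `synchronous_DCIS` when at least `t_high` of them lie inside duct
#' polygons, `IDC` when at most `t_low` do, `mixed` in between, and
#' `excluded` when the polygon holds no epithelial cells at all (regions of
#' stroma, lymphocytes or empty space, which enter no component). The
#' geometric duct area fraction of every polygon is also computed (by exact
#' clipping of the duct polygons against each convex quadrat) and reported
#' alongside.
#'
#' @param partition A `region_partition` from [tessellate()].
#' @param ducts A [duct_mask()] in the same frame.
#' @param t_low,t_high In-duct epithelial fraction thresholds,
#'   `0 <= t_low < t_high <= 1` (defaults 0.1 / 0.9).
#' @return The partition with `region_type`, `duct_area_fraction` and
#'   `duct_cell_fraction` filled in.
#' @export
classify_polygons <- function(partition, ducts, t_low = 0.1, t_high = 0.9) {
  if (!(t_low >= 0 && t_low < t_high && t_high <= 1)) {
    abort("need 0 <= t_low < t_high <= 1.", class = "ductcoloc_parameter_error")
  }
  ps <- partition$section_id
  ds <- ducts$section_id
  if (!is.null(ps) && !is.null(ds) && ps != ds &&
    !("section" %in% c(ps, ds))) { # "section" is the anonymous default
    abort(
      paste0("section mismatch: partition '", ps, "' vs mask '", ds, "'"),
      class = "ductcoloc_consistency_error"
    )
  }
  cells <- partition$cells
  epi <- cells$cell_class %in% epithelial_classes()
  in_duct <- points_in_mask(cells$x_um, cells$y_um, ducts)
  poly_id <- partition$assignment$polygon_id
  k <- length(partition$polygons)
  n_epi <- tabulate(poly_id[epi], nbins = k)
  n_epi_duct <- tabulate(poly_id[epi & in_duct], nbins = k)
  cell_frac <- ifelse(n_epi > 0, n_epi_duct / n_epi, NA_real_)
  area_frac <- vapply(seq_len(k), function(i) {
    a <- sum(vapply(
      ducts$polygons, intersection_area_convex,
      numeric(1),
      convex_ring = partition$polygons[[i]]
    ))
    min(a / abs(poly_area(partition$polygons[[i]])), 1)
  }, numeric(1))
  type <- dplyr::case_when(
    n_epi == 0 ~ "excluded",
    cell_frac >= t_high ~ "synchronous_DCIS",
    cell_frac <= t_low ~ "IDC",
    TRUE ~ "mixed"
  )
  partition$regions$region_type <- type
  partition$regions$duct_area_fraction <- area_frac
  partition$regions$duct_cell_fraction <- cell_frac
  partition$thresholds <- c(t_low = t_low, t_high = t_high)
  partition
}

#' Write a typed partition as GeoJSON
#'
#' Each Voronoi polygon becomes a Feature with `polygon_id`, `region_type`,
#' `duct_area_fraction`, `duct_cell_fraction` and `n_cells` properties —
#' the format used to overlay typed quadrats on a slide viewer.
#'
#' @param partition A `region_partition` (typed or not).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  features <- lapply(seq_along(partition$polygons), function(i) {
    r <- partition$regions[i, ]
    list(
      type = "Feature",
      properties = list(
        polygon_id = r$polygon_id, region_type = r$region_type,
        duct_area_fraction = r$duct_area_fraction,
        duct_cell_fraction = r$duct_cell_fraction, n_cells = r$n_cells
      ),
      geometry = list(
        type = "Polygon",
        coordinates = list(ring_to_geojson(partition$polygons[[i]]))
      )
    )
  })
  doc <- list(
    type = "FeatureCollection",
    properties = list(
      section_id = partition$section_id,
      coordinate_units = "micron", axis_convention = "image_y_down"
    ),
    features = features
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Extract the cells of one tissue component
#'
#' Returns the sub-table of cells whose Voronoi polygon carries the
#' requested type. Mixed and excluded polygons contribute to neither
#' component. A component with no polygons yields an empty table flagged
#' `insufficient_region` rather than an error, mirroring sections that lack
#' synchronous DCIS regions altogether.
#'
#' @param cells The cell table used to build `partition` (a [cell_map()]).
#' @param partition A classified `region_partition`.
#' @param component `"synchronous_DCIS"` or `"IDC"`.
#' @return A tibble of cells with attribute `insufficient_region` (logical).
#' @export
component_cells <- function(cells, partition, component = c("synchronous_DCIS", "IDC")) {
  component <- match.arg(component)
  if (all(is.na(partition$regions$region_type))) {
    abort("partition has not been classified; run classify_polygons() first.",
      class = "ductcoloc_validation_error"
    )
  }
  ids <- partition$regions$polygon_id[partition$regions$region_type == component]
  keep <- partition$assignment$polygon_id %in% ids
  out <- as_tibble(partition$cells)[keep, , drop = FALSE]
  attr(out, "insufficient_region") <- length(ids) == 0
  attr(out, "section_id") <- partition$section_id
  out
}
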