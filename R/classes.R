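# Core containers: cell maps (tibble-first) and duct masks (polygon lists).

#' The five cell classes
#'
#' Cells in a dual CA9/FOXP3 immunohistochemistry section are assigned one of
#' five classes: CA9-positive or CA9-negative epithelial cells, FOXP3-positive
#' or FOXP3-negative lymphocytes, and stromal cells.
#'
#' @return Character vector of the five canonical class labels.
#' @export
#' @examples
#' cell_classes()
cell_classes <- function() {
  c(
    "CA9_pos_epithelial", "CA9_neg_epithelial",
    "FOXP3_pos_lymphocyte", "FOXP3_neg_lymphocyte",
    "stroma"
  )
}

epithelial_classes <- function() c("CA9_pos_epithelial", "CA9_neg_epithelial")
lymphocyte_classes <- function() c("FOXP3_pos_lymphocyte", "FOXP3_neg_lymphocyte")

#' Construct a cell map
#'
#' A cell map is a tibble with one row per detected cell: an identifier,
#' coordinates in microns (image convention: origin top-left, y increasing
#' downward) and one of the five classes from [cell_classes()]. Section-level
#' metadata travel as attributes so the table itself stays tidy.
#'
#' @param cells Data frame with columns `cell_id`, `x_um`, `y_um`,
#'   `cell_class`.
#' @param section_id Non-empty section identifier.
#' @param sample_type `"pure_DCIS"` or `"IDC_DCIS"`.
#' @param pixel_size Scan resolution in microns per pixel (default 0.5, the
#'   resolution of a x20 whole-slide scan).
#' @param metadata Optional named list (e.g. `er_status`, `grade`).
#'
#' @return A `cell_map`: a tibble with the columns above and attributes
#'   `section_id`, `sample_type`, `pixel_size`, `metadata`.
#' @export
#' @examples
#' cm <- cell_map(
#'   tibble::tibble(
#'     cell_id = c("a", "b"), x_um = c(1, 2), y_um = c(3, 4),
#'     cell_class = c("stroma", "CA9_pos_epithelial")
#'   ),
#'   section_id = "s1", sample_type = "pure_DCIS"
#' )
cell_map <- function(cells, section_id = "section", sample_type = c("pure_DCIS", "IDC_DCIS"),
                     pixel_size = 0.5, metadata = list()) {
  sample_type <- match.arg(sample_type)
  if (!is.character(section_id) || length(section_id) != 1L || !nzchar(section_id)) {
    abort("`section_id` must be a non-empty string.", class = "ductcoloc_validation_error")
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    abort("`pixel_size` must be a positive scalar (microns per pixel).",
      class = "ductcoloc_validation_error"
    )
  }
  cells <- as_tibble(cells)
  required <- c("cell_id", "x_um", "y_um", "cell_class")
  missing_cols <- setdiff(required, names(cells))
  if (length(missing_cols) > 0) {
    abort(
      paste0("cell table is missing required column(s): ", paste(missing_cols, collapse = ", ")),
      class = "ductcoloc_format_error"
    )
  }
  cells$cell_class <- as.character(cells$cell_class)
  bad <- setdiff(unique(cells$cell_class), cell_classes())
  if (length(bad) > 0) {
    abort(
      paste0("unknown cell class label(s): ", paste(bad, collapse = ", ")),
      class = "ductcoloc_validation_error"
    )
  }
  if (nrow(cells) > 0 && (any(!is.finite(cells$x_um)) || any(!is.finite(cells$y_um)) ||
    any(cells$x_um < 0) || any(cells$y_um < 0))) {
    abort("cell coordinates must be finite and non-negative microns.",
      class = "ductcoloc_validation_error"
    )
  }
  cells <- cells[, c(required, setdiff(names(cells), required))]
  structure(cells,
    class = c("cell_map", class(cells)),
    section_id = section_id, sample_type = sample_type,
    pixel_size = pixel_size, metadata = metadata
  )
}

#' @export
print.cell_map <- function(x, ...) {
  cat(
    "<cell_map> section", attr(x, "section_id"),
    paste0("(", attr(x, "sample_type"), "),"),
    nrow(x), "cells\n"
  )
  NextMethod()
}

section_id_of <- function(cells, default = "section") {
  attr(cells, "section_id") %||% default
}

sample_type_of <- function(cells, default = "pure_DCIS") {
  attr(cells, "sample_type") %||% default
}

# Re-attach cell_map attributes after a dplyr verb stripped them.
restore_cell_map <- function(cells, template) {
  cell_map(as_tibble(cells),
    section_id = section_id_of(template),
    sample_type = sample_type_of(template),
    pixel_size = attr(template, "pixel_size") %||% 0.5,
    metadata = attr(template, "metadata") %||% list()
  )
}

#' Construct a duct mask
#'
#' A duct mask delineates DCIS duct regions as a collection of simple
#' polygons, optionally with holes, in the same micron coordinate frame as
#' the cell map.
#'
#' @param polygons List of polygons. Each polygon is a list with `exterior`
#'   (two-column matrix of x/y vertices in microns, not closed) and `holes`
#'   (possibly empty list of such matrices). A bare matrix is promoted to a
#'   hole-free polygon.
#' @param section_id Section identifier.
#'
#' @return A `duct_mask` object.
#' @export
duct_mask <- function(polygons = list(), section_id = "section") {
  polygons <- lapply(polygons, function(p) {
    if (is.matrix(p)) p <- list(exterior = p, holes = list())
    if (is.null(p$holes)) p$holes <- list()
    p$exterior <- normalise_ring(p$exterior, orientation = "ccw")
    p$holes <- lapply(p$holes, normalise_ring, orientation = "cw")
    if (abs(poly_area(p$exterior)) <= 0) {
      abort("duct polygon has zero area.", class = "ductcoloc_geometry_error")
    }
    p
  })
  structure(list(polygons = polygons, section_id = section_id), class = "duct_mask")
}

#' @export
print.duct_mask <- function(x, ...) {
  cat(
    "<duct_mask> section", x$section_id, "-", length(x$polygons),
    "polygon(s), total area", round(mask_area(x), 1), "um^2\n"
  )
  invisible(x)
}

#' Total duct area of a mask
#'
#' @param mask A [duct_mask()].
#' @return Total area in square microns (holes subtracted).
#' @export
mask_area <- function(mask) {
  sum(vapply(mask$polygons, polygon_net_area, numeric(1)))
}

#' Tidy a duct mask into a vertex table
#'
#' @param x A [duct_mask()].
#' @param ... Unused.
#' @return Tibble with columns `polygon`, `ring` (`"exterior"` or `"hole<i>"`),
#'   `x_um`, `y_um`, in drawing order.
#' @export
tidy.duct_mask <- function(x, ...) {
  purrr::imap_dfr(x$polygons, function(p, i) {
    rings <- c(list(exterior = p$exterior), setNames(
      p$holes,
      if (length(p$holes)) paste0("hole", seq_along(p$holes)) else character()
    ))
    purrr::imap_dfr(rings, function(r, nm) {
      tibble(polygon = i, ring = nm, x_um = r[, 1], y_um = r[, 2])
    })
  })
}
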