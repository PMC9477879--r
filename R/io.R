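# Readers/writers: cell tables as CSV, duct masks as GeoJSON
# FeatureCollections (micron coordinates, image-convention y-down, no CRS)
# or as label images (PNG/TIFF), results as CSV/JSON.

#' Read a cell table from CSV
#'
#' Expects a UTF-8 CSV with header columns `cell_id`, `cell_class` and either
#' micron coordinates (`x_um`, `y_um`) or pixel coordinates (`x_px`, `y_px`)
#' converted using `pixel_size`. Unknown class labels are rejected with the
#' offending labels listed.
#'
#' @param path CSV file path.
#' @param section_id,sample_type,pixel_size,metadata Passed to [cell_map()];
#'   `pixel_size` also converts pixel columns to microns.
#' @return A [cell_map()].
#' @export
read_cells <- function(path, section_id = basename(path),
                       sample_type = c("pure_DCIS", "IDC_DCIS"),
                       pixel_size = 0.5, metadata = list()) {
  sample_type <- match.arg(sample_type)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "ductcoloc_format_error")
  }
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (all(c("x_px", "y_px") %in% names(tab)) && !all(c("x_um", "y_um") %in% names(tab))) {
    tab$x_um <- tab$x_px * pixel_size
    tab$y_um <- tab$y_px * pixel_size
  }
  for (col in c("cell_id", "x_um", "y_um", "cell_class")) {
    if (!col %in% names(tab)) {
      abort(paste0("cell CSV is missing required column: ", col),
        class = "ductcoloc_format_error"
      )
    }
  }
  cell_map(tab,
    section_id = section_id, sample_type = sample_type,
    pixel_size = pixel_size, metadata = metadata
  )
}

#' Write a cell table to CSV
#'
#' @param cells A [cell_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cells <- function(cells, path) {
  readr::write_csv(
    as_tibble(cells)[, c("cell_id", "x_um", "y_um", "cell_class")],
    path
  )
  invisible(path)
}

ring_to_geojson <- function(ring) {
  closed <- rbind(ring, ring[1, , drop = FALSE])
  lapply(seq_len(nrow(closed)), function(i) c(closed[i, 1], closed[i, 2]))
}

#' Write a duct mask as GeoJSON
#'
#' Polygons are written as an RFC 7946-style FeatureCollection whose
#' coordinates are microns in the image frame (origin top-left, y down);
#' that convention is recorded in the collection's `properties`. Exteriors
#' are written counter-clockwise, holes clockwise (by shoelace sign in the
#' stored frame).
#'
#' @param mask A [duct_mask()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_duct_mask <- function(mask, path) {
  features <- lapply(seq_along(mask$polygons), function(i) {
    p <- mask$polygons[[i]]
    rings <- c(list(ring_to_geojson(p$exterior)), lapply(p$holes, ring_to_geojson))
    list(
      type = "Feature",
      properties = list(polygon_id = i),
      geometry = list(type = "Polygon", coordinates = rings)
    )
  })
  doc <- list(
    type = "FeatureCollection",
    properties = list(
      section_id = mask$section_id,
      coordinate_units = "micron",
      axis_convention = "image_y_down"
    ),
    features = features
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

geojson_ring <- function(coords) {
  m <- do.call(rbind, lapply(coords, function(pt) c(pt[[1]], pt[[2]])))
  m
}

#' Read a duct mask
#'
#' Two dialects are supported. `"geojson"` reads a FeatureCollection of
#' Polygon/MultiPolygon features (coordinates in microns); rings are
#' validated, trivially repaired (duplicate vertices removed, winding
#' normalised) and rejected with the feature index when degenerate.
#' `"label_image"` reads an 8-bit PNG/TIFF label raster (0 = background,
#' each positive value one duct) and traces pixel-boundary contours, holes
#' preserved, scaled by `pixel_size`; traced areas are exact pixel areas.
#'
#' @param path Input file.
#' @param dialect `"geojson"` or `"label_image"`.
#' @param pixel_size Microns per pixel, required for `"label_image"`.
#' @param section_id Section identifier.
#' @return A [duct_mask()].
#' @export
read_duct_mask <- function(path, dialect = c("geojson", "label_image"),
                           pixel_size = NULL, section_id = basename(path)) {
  dialect <- match.arg(dialect)
  if (dialect == "geojson") {
    doc <- jsonlite::read_json(path)
    if (!identical(doc$type, "FeatureCollection")) {
      abort("expected a GeoJSON FeatureCollection.", class = "ductcoloc_format_error")
    }
    polys <- list()
    for (i in seq_along(doc$features)) {
      geom <- doc$features[[i]]$geometry
      ringsets <- switch(geom$type,
        Polygon = list(geom$coordinates),
        MultiPolygon = geom$coordinates,
        abort(paste0("feature ", i, ": unsupported geometry type ", geom$type),
          class = "ductcoloc_geometry_error"
        )
      )
      for (rs in ringsets) {
        p <- tryCatch(
          list(
            exterior = normalise_ring(geojson_ring(rs[[1]]), "ccw"),
            holes = lapply(rs[-1], function(r) normalise_ring(geojson_ring(r), "cw"))
          ),
          error = function(e) {
            abort(paste0("feature ", i, ": invalid ring (", conditionMessage(e), ")"),
              class = "ductcoloc_geometry_error"
            )
          }
        )
        if (has_self_intersection(p$exterior)) {
          abort(paste0("feature ", i, ": self-intersecting exterior ring."),
            class = "ductcoloc_geometry_error"
          )
        }
        polys[[length(polys) + 1L]] <- p
      }
    }
    sid <- doc$properties$section_id %||% section_id
    return(duct_mask(polys, section_id = sid))
  }
  # label image
  if (is.null(pixel_size)) {
    abort("`pixel_size` (um/px) is required for label-image masks.",
      class = "ductcoloc_parameter_error"
    )
  }
  img <- read_label_image(path)
  mask_from_labels(img, pixel_size = pixel_size, section_id = section_id)
}

read_label_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) {
      abort("reading PNG masks requires the 'png' package.", class = "ductcoloc_format_error")
    }
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      abort("reading TIFF masks requires the 'tiff' package.", class = "ductcoloc_format_error")
    }
    tiff::readTIFF(path)
  } else {
    abort(paste0("unsupported label-image extension: ", ext),
      class = "ductcoloc_format_error"
    )
  }
  if (length(dim(img)) == 3) img <- img[, , 1]
  round(img * 255)
}

#' Vectorise a label matrix into a duct mask
#'
#' Traces the pixel-boundary outline of every labelled region (8-connected
#' foreground) in a label matrix. Pixel `[i, j]` occupies the square
#' `[(j-1), j] x [(i-1), i]` scaled by `pixel_size`, so traced polygon areas
#' equal pixel counts times `pixel_size^2` exactly.
#'
#' @param labels Integer matrix; 0 = background.
#' @param pixel_size Microns per pixel.
#' @param section_id Section identifier.
#' @return A [duct_mask()].
#' @export
mask_from_labels <- function(labels, pixel_size = 0.5, section_id = "section") {
  labs <- sort(setdiff(unique(as.vector(labels)), 0))
  polys <- list()
  for (lb in labs) {
    rings <- trace_rings(labels == lb)
    if (length(rings) == 0) next
    # outer rings have positive shoelace sign under the tracing convention
    signs <- vapply(rings, poly_area, numeric(1))
    outers <- rings[signs > 0]
    holes <- rings[signs < 0]
    for (o in outers) {
      hs <- Filter(function(h) {
        points_in_ring(mean(h[, 1]), mean(h[, 2]), o)
      }, holes)
      polys[[length(polys) + 1L]] <- list(
        exterior = o * pixel_size,
        holes = lapply(hs, function(h) h * pixel_size)
      )
    }
  }
  duct_mask(polys, section_id = section_id)
}

# Trace closed rings along pixel boundaries of a logical matrix. Directed
# boundary edges keep foreground on the left; at 4-valent vertices the
# sharpest left turn is taken, which keeps diagonally touching pixels
# (8-connectivity) in a single outer ring. Coordinates are in pixel units
# with x along columns and y along rows (image frame).
trace_rings <- function(fg) {
  nr <- nrow(fg)
  nc <- ncol(fg)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- fg
  edges <- list() # each: c(x0, y0, x1, y1), directed, fg on left
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!fg[i, j]) next
      x0 <- j - 1; x1 <- j; y0 <- i - 1; y1 <- i
      if (!pad[i, j + 1]) edges[[length(edges) + 1L]] <- c(x0, y0, x1, y0) # top: ->
      if (!pad[i + 1, j + 2]) edges[[length(edges) + 1L]] <- c(x1, y0, x1, y1) # right: v
      if (!pad[i + 2, j + 1]) edges[[length(edges) + 1L]] <- c(x1, y1, x0, y1) # bottom: <-
      if (!pad[i + 1, j]) edges[[length(edges) + 1L]] <- c(x0, y1, x0, y0) # left: ^
    }
  }
  if (length(edges) == 0) {
    return(list())
  }
  em <- do.call(rbind, edges)
  key <- paste(em[, 1], em[, 2], sep = ",")
  by_start <- split(seq_len(nrow(em)), key)
  used <- logical(nrow(em))
  rings <- list()
  for (s in seq_len(nrow(em))) {
    if (used[s]) next
    ring <- list()
    e <- s
    repeat {
      used[e] <- TRUE
      ring[[length(ring) + 1L]] <- em[e, 1:2]
      nxt_key <- paste(em[e, 3], em[e, 4], sep = ",")
      cand <- by_start[[nxt_key]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0) break
      if (length(cand) == 1) {
        e <- cand
      } else {
        # pick the sharpest left turn relative to the incoming direction
        din <- em[e, 3:4] - em[e, 1:2]
        turn <- vapply(cand, function(k) {
          dout <- em[k, 3:4] - em[k, 1:2]
          atan2(din[1] * dout[2] - din[2] * dout[1], sum(din * dout))
        }, numeric(1))
        e <- cand[which.max(turn)]
      }
    }
    rings[[length(rings) + 1L]] <- do.call(rbind, ring)
  }
  # In the image frame (y down) an outer ring traced with fg-on-left runs
  # clockwise on screen, which is a positive shoelace sign here because the
  # top edge of the topmost pixel is emitted left-to-right at minimal y.
  rings
}

# O(n^2) segment-crossing check, sufficient for annotation-scale rings.
has_self_intersection <- function(ring) {
  n <- nrow(ring)
  if (n > 400) {
    return(FALSE)
  } # skip the quadratic check for very dense rings
  seg <- cbind(ring, ring[c(2:n, 1), ])
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      if (segments_cross(
        seg[i, 1:2], seg[i, 3:4],
        seg[j, 1:2], seg[j, 3:4]
      )) {
        return(TRUE)
      }
    }
  }
  FALSE
}

segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1)
  d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3)
  d4 <- d(p1, p2, p4)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

#' Rasterise a duct mask to a label matrix
#'
#' Inverse of [mask_from_labels()] up to pixel discretisation: pixel centres
#' falling inside polygon `i` receive label `i`.
#'
#' @param mask A [duct_mask()].
#' @param width_px,height_px Raster dimensions in pixels.
#' @param pixel_size Microns per pixel.
#' @return Integer matrix of labels (0 = background).
#' @export
mask_to_labels <- function(mask, width_px, height_px, pixel_size = 0.5) {
  out <- matrix(0L, nrow = height_px, ncol = width_px)
  xc <- (seq_len(width_px) - 0.5) * pixel_size
  yc <- (seq_len(height_px) - 0.5) * pixel_size
  gx <- rep(xc, times = height_px)
  gy <- rep(yc, each = width_px)
  for (i in seq_along(mask$polygons)) {
    inside <- points_in_polygon(gx, gy, mask$polygons[[i]])
    out[matrix(inside, nrow = height_px, byrow = TRUE)] <- i
  }
  out
}
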