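# Planar geometry primitives used by the tessellation and region-typing
# stages. Everything works on plain two-column matrices of vertices in
# microns (rings are open: the closing edge is implicit). Coordinates follow
# the image convention (y down), so the "counter-clockwise" exterior
# orientation corresponds to a negative shoelace sum in screen terms; we
# define orientation purely by the sign of the shoelace formula evaluated in
# the stored coordinates.

# Signed shoelace area; positive = counter-clockwise in the stored frame.
poly_area <- function(ring) {
  n <- nrow(ring)
  if (is.null(n) || n < 3) {
    return(0)
  }
  x <- ring[, 1]
  y <- ring[, 2]
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

polygon_net_area <- function(polygon) {
  abs(poly_area(polygon$exterior)) - sum(vapply(polygon$holes, function(h) abs(poly_area(h)), numeric(1)))
}

# Drop duplicated consecutive vertices, drop an explicit closing vertex and
# enforce a winding orientation.
normalise_ring <- function(ring, orientation = c("ccw", "cw")) {
  orientation <- match.arg(orientation)
  ring <- as.matrix(ring)
  if (ncol(ring) != 2) {
    abort("a ring must be a two-column matrix of vertices.", class = "ductcoloc_geometry_error")
  }
  storage.mode(ring) <- "double"
  n <- nrow(ring)
  if (n >= 2 && all(ring[1, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
  keep <- c(TRUE, rowSums(abs(diff(ring))) > 0)[seq_len(nrow(ring))]
  ring <- ring[keep, , drop = FALSE]
  if (nrow(ring) < 3) {
    abort("a ring needs at least three distinct vertices.", class = "ductcoloc_geometry_error")
  }
  a <- poly_area(ring)
  flip <- (orientation == "ccw" && a < 0) || (orientation == "cw" && a > 0)
  if (flip) ring <- ring[rev(seq_len(nrow(ring))), , drop = FALSE]
  ring
}

# Even-odd point-in-ring test, vectorised over points. Boundary points count
# as inside (adequate here: ties are broken upstream by assignment order).
points_in_ring <- function(x, y, ring) {
  n <- nrow(ring)
  rx <- ring[, 1]
  ry <- ring[, 2]
  inside <- logical(length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- rx[i]; yi <- ry[i]; xj <- rx[j]; yj <- ry[j]
    cross <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

points_in_polygon <- function(x, y, polygon) {
  inside <- points_in_ring(x, y, polygon$exterior)
  for (h in polygon$holes) inside <- inside & !points_in_ring(x, y, h)
  inside
}

# TRUE for points inside any duct polygon of a mask.
points_in_mask <- function(x, y, mask) {
  inside <- logical(length(x))
  for (p in mask$polygons) inside <- inside | points_in_polygon(x, y, p)
  inside
}

# Sutherland-Hodgman: clip a (possibly non-convex) subject ring against one
# half-plane a*x + b*y <= c. Returns a matrix (possibly with < 3 rows when
# the intersection is empty/degenerate).
clip_halfplane <- function(ring, a, b, cc) {
  n <- nrow(ring)
  if (n == 0) return(ring)
  val <- a * ring[, 1] + b * ring[, 2] - cc
  keep_any <- any(val <= 0)
  if (!keep_any) return(ring[0, , drop = FALSE])
  if (all(val <= 1e-12)) return(ring)
  out_x <- numeric(2L * n)
  out_y <- numeric(2L * n)
  m <- 0L
  j <- n
  for (i in seq_len(n)) {
    ci <- val[i] <= 0
    cj <- val[j] <= 0
    if (ci != cj) {
      t <- val[j] / (val[j] - val[i])
      m <- m + 1L
      out_x[m] <- ring[j, 1] + t * (ring[i, 1] - ring[j, 1])
      out_y[m] <- ring[j, 2] + t * (ring[i, 2] - ring[j, 2])
    }
    if (ci) {
      m <- m + 1L
      out_x[m] <- ring[i, 1]
      out_y[m] <- ring[i, 2]
    }
    j <- i
  }
  cbind(out_x[seq_len(m)], out_y[seq_len(m)])
}

# Clip a subject ring against a convex clip ring (vertices in CCW order per
# the stored frame). For non-convex subjects the output may contain
# degenerate bridge edges along the clip boundary; the shoelace area of the
# result still equals the true intersection area, which is all downstream
# code uses.
clip_to_convex <- function(subject, clip) {
  clip <- if (poly_area(clip) > 0) clip else clip[rev(seq_len(nrow(clip))), , drop = FALSE]
  out <- subject
  n <- nrow(clip)
  j <- n
  for (i in seq_len(n)) {
    # interior of a CCW convex polygon is the left side of each edge:
    # cross(e, p - v_j) >= 0, i.e. ey*x - ex*y <= ey*vx - ex*vy
    ex <- clip[i, 1] - clip[j, 1]
    ey <- clip[i, 2] - clip[j, 2]
    out <- clip_halfplane(out, ey, -ex, ey * clip[j, 1] - ex * clip[j, 2])
    if (nrow(out) == 0) break
    j <- i
  }
  out
}

# Area of polygon-with-holes intersected with a convex ring.
intersection_area_convex <- function(polygon, convex_ring) {
  a <- abs(poly_area(clip_to_convex(polygon$exterior, convex_ring)))
  for (h in polygon$holes) a <- a - abs(poly_area(clip_to_convex(h, convex_ring)))
  max(a, 0)
}

# Convex hull of points, dilated by `buffer` via a Minkowski sum with a
# 32-gon, returned as a CCW ring. Used as the default analysis ROI.
convex_hull_buffered <- function(x, y, buffer = 50) {
  if (length(x) < 3) {
    abort("need at least three points to form a region of interest.",
      class = "ductcoloc_geometry_error"
    )
  }
  h <- grDevices::chull(x, y)
  hx <- x[h]
  hy <- y[h]
  if (buffer > 0) {
    theta <- seq(0, 2 * pi, length.out = 33)[-33]
    ox <- as.vector(outer(hx, buffer * cos(theta), `+`))
    oy <- as.vector(outer(hy, buffer * sin(theta), `+`))
    h2 <- grDevices::chull(ox, oy)
    hx <- ox[h2]
    hy <- oy[h2]
  }
  normalise_ring(cbind(hx, hy), orientation = "ccw")
}

# Voronoi cell of seed i within a convex CCW ROI ring: intersect the ROI
# with the bisector half-planes against every other seed.
voronoi_cell <- function(i, seeds, roi) {
  cell <- roi
  si <- seeds[i, ]
  for (j in seq_len(nrow(seeds))) {
    if (j == i) next
    sj <- seeds[j, ]
    a <- 2 * (sj[1] - si[1])
    b <- 2 * (sj[2] - si[2])
    cc <- sum(sj^2) - sum(si^2)
    cell <- clip_halfplane(cell, a, b, cc)
    if (nrow(cell) < 3) break
  }
  if (nrow(cell) < 3) {
    abort("degenerate Voronoi cell (coincident seeds?).", class = "ductcoloc_geometry_error")
  }
  normalise_ring(cell, orientation = "ccw")
}

# Rasterise a duct mask onto a pixel grid (pixel centres at (j-0.5, i-0.5)
# * pixel_size), returning a logical matrix (rows = y). Used for
# vector-vs-raster mask metrics and round-trip checks.
rasterize_mask <- function(mask, width_px, height_px, pixel_size) {
  xc <- (seq_len(width_px) - 0.5) * pixel_size
  yc <- (seq_len(height_px) - 0.5) * pixel_size
  gx <- rep(xc, times = height_px)
  gy <- rep(yc, each = width_px)
  inside <- points_in_mask(gx, gy, mask)
  matrix(inside, nrow = height_px, ncol = width_px, byrow = TRUE)
}
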