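# Independent oracles used across the suite.

# Brute-force maximum one-to-one matching within a radius, by recursive
# enumeration over the truth points (feasible for <= ~12 points). Returns
# the maximum number of matched pairs.
brute_force_match <- function(predicted, truth, radius) {
  np <- nrow(predicted)
  nt <- nrow(truth)
  if (np == 0 || nt == 0) {
    return(0L)
  }
  d <- sqrt(outer(predicted$x_um, truth$x_um, `-`)^2 +
    outer(predicted$y_um, truth$y_um, `-`)^2)
  ok <- d <= radius
  best <- 0L
  recurse <- function(t_idx, used_pred, matched) {
    if (matched + (nt - t_idx + 1L) <= best) {
      return()
    }
    if (t_idx > nt) {
      best <<- max(best, matched)
      return()
    }
    recurse(t_idx + 1L, used_pred, matched) # leave this truth unmatched
    for (p in which(ok[, t_idx])) {
      if (!used_pred[p]) {
        used_pred[p] <- TRUE
        recurse(t_idx + 1L, used_pred, matched + 1L)
        used_pred[p] <- FALSE
      }
    }
  }
  recurse(1L, logical(np), 0L)
  best
}

# Monte-Carlo area of the intersection of a polygon (with holes) and a
# convex ring, for validating the exact clipping code.
mc_intersection_area <- function(polygon, convex_ring, n = 2e5, seed = 42) {
  withr::with_seed(seed, {
    bx <- range(polygon$exterior[, 1])
    by <- range(polygon$exterior[, 2])
    x <- runif(n, bx[1], bx[2])
    y <- runif(n, by[1], by[2])
    inside <- ductcoloc:::points_in_polygon(x, y, polygon) &
      ductcoloc:::points_in_ring(x, y, convex_ring)
    mean(inside) * diff(bx) * diff(by)
  })
}

# Hand-executed Holm step-down: sort raw p, multiply by (m - rank + 1),
# enforce monotonicity, cap at 1.
holm_by_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(cummax(p[o] * (m - seq_len(m) + 1L)), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Small deterministic cell table helper.
toy_cells <- function(xy, classes, section_id = "toy", sample_type = "pure_DCIS") {
  cell_map(
    tibble::tibble(
      cell_id = sprintf("t%03d", seq_len(nrow(xy))),
      x_um = xy[, 1], y_um = xy[, 2], cell_class = classes
    ),
    section_id = section_id, sample_type = sample_type
  )
}

small_params <- function(seed, ...) {
  simulation_params(
    rng_seed = seed, n_epithelial = 600, n_lymphocyte = 500,
    n_stroma = 90, ...
  )
}
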