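# Synthetic tissue sections: duct geometry, five-class cell placement with a
# tunable FOXP3+/CA9+ attraction, and a detector-degradation model used to
# exercise the evaluation metrics.

#' Simulation parameters for a synthetic tissue section
#'
#' Defaults emulate a whole section scanned at 0.5 um/px: a 2 x 2 mm field,
#' a handful of ducts of 120-220 um radius, and class frequencies following
#' the proportions of the annotation set used to train the original
#' single-cell classifier (stroma 7%, lymphocytes 47% of which 8.7% FOXP3+,
#' epithelium 46% of which 26% CA9+), scaled to the requested totals.
#'
#' @param rng_seed Integer seed; the whole section is deterministic given it.
#' @param field_width,field_height Field size in microns.
#' @param n_ducts Number of duct polygons.
#' @param duct_radius_range Two-element min/max duct radius (microns).
#' @param duct_shape `"ellipse"` or `"lobed"` (ellipse with a three-lobed
#'   radial perturbation).
#' @param invasive_fraction Fraction of epithelial cells placed outside
#'   ducts (the invasive component); forced to 0 for `pure_DCIS` sections.
#' @param n_epithelial,n_lymphocyte,n_stroma Cell counts per compartment.
#' @param ca9_pos_fraction Fraction of epithelial cells labelled CA9+.
#' @param foxp3_pos_fraction Fraction of lymphocytes labelled FOXP3+.
#' @param hypoxia_focality Number of hypoxic (CA9+) foci; CA9+ labels are
#'   given to the epithelial cells nearest these focal centres, so CA9
#'   expression is focal rather than salt-and-pepper.
#' @param attraction Non-negative strength of FOXP3+ attraction to CA9+
#'   cells. Each FOXP3+ lymphocyte is drawn, with probability
#'   `attraction / (1 + attraction)`, from a Gaussian kernel (s.d.
#'   `attraction_bandwidth`) centred on a random CA9+ cell, and otherwise
#'   from the uniform lymphocyte field. At 0 the placement is independent
#'   of CA9 status.
#' @param attraction_bandwidth Kernel bandwidth in microns.
#' @param jitter_sd,drop_rate,spurious_rate,confusion_rate Degradation
#'   defaults passed to [degrade_detections()].
#'
#' @return A validated list of class `simulation_params`.
#' @export
simulation_params <- function(rng_seed = 1L,
                              field_width = 2000, field_height = 2000,
                              n_ducts = 8, duct_radius_range = c(120, 220),
                              duct_shape = c("ellipse", "lobed"),
                              invasive_fraction = 0.5,
                              n_epithelial = 1800, n_lymphocyte = 1700,
                              n_stroma = 260,
                              ca9_pos_fraction = 0.257,
                              foxp3_pos_fraction = 0.087,
                              hypoxia_focality = 3,
                              attraction = 0, attraction_bandwidth = 50,
                              jitter_sd = 0, drop_rate = 0, spurious_rate = 0,
                              confusion_rate = 0) {
  duct_shape <- match.arg(duct_shape)
  p <- list(
    rng_seed = as.integer(rng_seed), field_width = field_width,
    field_height = field_height, n_ducts = n_ducts,
    duct_radius_range = duct_radius_range, duct_shape = duct_shape,
    invasive_fraction = invasive_fraction, n_epithelial = n_epithelial,
    n_lymphocyte = n_lymphocyte, n_stroma = n_stroma,
    ca9_pos_fraction = ca9_pos_fraction,
    foxp3_pos_fraction = foxp3_pos_fraction,
    hypoxia_focality = hypoxia_focality, attraction = attraction,
    attraction_bandwidth = attraction_bandwidth, jitter_sd = jitter_sd,
    drop_rate = drop_rate, spurious_rate = spurious_rate,
    confusion_rate = confusion_rate
  )
  counts <- c("n_ducts", "n_epithelial", "n_lymphocyte", "n_stroma", "hypoxia_focality")
  for (nm in counts) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || p[[nm]] < 0 || p[[nm]] != round(p[[nm]])) {
      abort(paste0("`", nm, "` must be a non-negative integer count."),
        class = "ductcoloc_parameter_error"
      )
    }
  }
  fracs <- c(
    "invasive_fraction", "ca9_pos_fraction", "foxp3_pos_fraction",
    "drop_rate", "spurious_rate", "confusion_rate"
  )
  for (nm in fracs) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || p[[nm]] < 0 || p[[nm]] > 1) {
      abort(paste0("`", nm, "` must be a fraction in [0, 1]."),
        class = "ductcoloc_parameter_error"
      )
    }
  }
  if (length(p$duct_radius_range) != 2 || p$duct_radius_range[1] > p$duct_radius_range[2] ||
    any(p$duct_radius_range <= 0)) {
    abort("`duct_radius_range` must be (min, max) with 0 < min <= max.",
      class = "ductcoloc_parameter_error"
    )
  }
  if (p$attraction < 0) {
    abort("`attraction` must be non-negative.", class = "ductcoloc_parameter_error")
  }
  if (p$jitter_sd < 0) {
    abort("`jitter_sd` must be non-negative.", class = "ductcoloc_parameter_error")
  }
  if (p$field_width <= 0 || p$field_height <= 0) {
    abort("field dimensions must be positive.", class = "ductcoloc_parameter_error")
  }
  structure(p, class = "simulation_params")
}

# One duct outline: an ellipse (optionally lobed) as a 64-gon.
duct_outline <- function(cx, cy, r, aspect, angle, shape) {
  theta <- seq(0, 2 * pi, length.out = 65)[-65]
  rr <- if (shape == "lobed") r * (1 + 0.15 * cos(3 * theta + runif(1, 0, 2 * pi))) else rep(r, 64)
  ex <- rr * cos(theta)
  ey <- rr * aspect * sin(theta)
  x <- cx + ex * cos(angle) - ey * sin(angle)
  y <- cy + ex * sin(angle) + ey * cos(angle)
  cbind(x, y)
}

# Rejection-sample non-overlapping ducts. For IDC/DCIS sections ducts are
# confined to the left part of the field so that the invasive compartment
# (right part) is spatially distinct, as in sections where DCIS ducts sit
# beside an invasive front.
sample_ducts <- function(params, sample_type) {
  if (params$n_ducts == 0) {
    return(duct_mask(list(), section_id = "pending"))
  }
  rmin <- params$duct_radius_range[1]
  rmax <- params$duct_radius_range[2]
  x_hi <- if (sample_type == "IDC_DCIS") 0.45 * params$field_width else params$field_width
  centres <- matrix(numeric(0), ncol = 2)
  bound_r <- numeric(0)
  outlines <- list()
  attempts <- 0L
  while (length(outlines) < params$n_ducts) {
    attempts <- attempts + 1L
    if (attempts > 20000L) {
      abort("could not place non-overlapping ducts; reduce `n_ducts` or radii.",
        class = "ductcoloc_configuration_error"
      )
    }
    # crowded fields: progressively prefer smaller radii so dense layouts
    # still terminate (smaller ducts fill remaining gaps, as real sections
    # mix duct sizes)
    shrink <- 0.9^(attempts %/% 500L)
    r <- runif(1, rmin, max(rmin, rmax * shrink))
    aspect <- runif(1, 0.7, 1)
    rb <- r * 1.15 + 5 # bounding radius incl. lobe perturbation
    if (2 * rb >= min(x_hi, params$field_height)) next
    cx <- runif(1, rb, x_hi - rb)
    cy <- runif(1, rb, params$field_height - rb)
    if (nrow(centres) > 0) {
      d <- sqrt((centres[, 1] - cx)^2 + (centres[, 2] - cy)^2)
      if (any(d < bound_r + rb + 10)) next
    }
    outlines[[length(outlines) + 1L]] <-
      duct_outline(cx, cy, r, aspect, runif(1, 0, pi), params$duct_shape)
    centres <- rbind(centres, c(cx, cy))
    bound_r <- c(bound_r, rb)
  }
  duct_mask(outlines, section_id = "pending")
}

# Uniform points inside a polygon by rejection in its bounding box.
runif_in_polygon <- function(n, polygon) {
  if (n == 0) {
    return(cbind(numeric(0), numeric(0)))
  }
  bx <- range(polygon$exterior[, 1])
  by <- range(polygon$exterior[, 2])
  out <- matrix(numeric(0), ncol = 2)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 16L)
    x <- runif(m, bx[1], bx[2])
    y <- runif(m, by[1], by[2])
    ok <- points_in_polygon(x, y, polygon)
    out <- rbind(out, cbind(x[ok], y[ok]))
  }
  out[seq_len(n), , drop = FALSE]
}

# n uniform points over the duct interiors, ducts weighted by area.
runif_in_mask <- function(n, mask) {
  areas <- vapply(mask$polygons, polygon_net_area, numeric(1))
  idx <- sample.int(length(mask$polygons), n, replace = TRUE, prob = areas)
  counts <- tabulate(idx, nbins = length(mask$polygons))
  pts <- vector("list", length(mask$polygons))
  for (i in seq_along(mask$polygons)) {
    pts[[i]] <- runif_in_polygon(counts[i], mask$polygons[[i]])
  }
  do.call(rbind, pts)
}

#' Simulate a synthetic tissue section
#'
#' Generates a ground-truth cell map plus duct mask with controllable
#' statistical structure: CA9+ epithelial cells clustered into hypoxic foci,
#' FOXP3+ lymphocytes drawn toward CA9+ cells with tunable strength, and
#' (for IDC/DCIS sections) an invasive epithelial compartment spatially
#' separated from the ducts. Deterministic given `params$rng_seed`.
#'
#' @param params A [simulation_params()] object.
#' @param sample_type `"pure_DCIS"` (all epithelial cells inside ducts) or
#'   `"IDC_DCIS"` (an `invasive_fraction` of epithelial cells outside).
#' @param section_id Section identifier; default derives from the seed.
#'
#' @return A list of class `synthetic_section` with elements `cells`
#'   (a [cell_map()]), `ducts` (a [duct_mask()]), `sample_type` and `params`.
#' @export
#' @examples
#' sec <- simulate_section(simulation_params(
#'   rng_seed = 7, n_epithelial = 200,
#'   n_lymphocyte = 100, n_stroma = 50, n_ducts = 4
#' ), "pure_DCIS")
#' nrow(sec$cells)
simulate_section <- function(params, sample_type = c("pure_DCIS", "IDC_DCIS"),
                             section_id = NULL) {
  if (!inherits(params, "simulation_params")) params <- do.call(simulation_params, params)
  sample_type <- match.arg(sample_type)
  if (sample_type == "pure_DCIS") params$invasive_fraction <- 0
  if (params$n_ducts == 0 && params$n_epithelial > 0 && params$invasive_fraction < 1) {
    abort("no ducts to hold in-duct epithelial cells; set `n_ducts` > 0 or invasive_fraction = 1.",
      class = "ductcoloc_configuration_error"
    )
  }
  section_id <- section_id %||% paste0("sim_", sample_type, "_", params$rng_seed)

  withr::with_seed(params$rng_seed, {
    ducts <- sample_ducts(params, sample_type)
    ducts$section_id <- section_id

    # --- epithelial compartment ---
    n_inv <- round(params$n_epithelial * params$invasive_fraction)
    n_duct <- params$n_epithelial - n_inv
    ep_duct <- if (n_duct > 0) runif_in_mask(n_duct, ducts) else cbind(numeric(0), numeric(0))
    ep_inv <- if (n_inv > 0) {
      cbind(
        runif(n_inv, 0.55 * params$field_width, params$field_width),
        runif(n_inv, 0, params$field_height)
      )
    } else {
      cbind(numeric(0), numeric(0))
    }
    ep <- rbind(ep_duct, ep_inv)
    in_duct <- c(rep(TRUE, n_duct), rep(FALSE, n_inv))

    # focal CA9 positivity: the n_ca9 epithelial cells nearest a focus centre
    n_ca9 <- round(params$ca9_pos_fraction * params$n_epithelial)
    ca9_pos <- rep(FALSE, params$n_epithelial)
    if (n_ca9 > 0 && params$n_epithelial > 0) {
      k <- max(1L, min(params$hypoxia_focality, params$n_epithelial))
      foci <- ep[sample.int(params$n_epithelial, k), , drop = FALSE]
      dmin <- rep(Inf, params$n_epithelial)
      for (i in seq_len(k)) {
        dmin <- pmin(dmin, (ep[, 1] - foci[i, 1])^2 + (ep[, 2] - foci[i, 2])^2)
      }
      ca9_pos[order(dmin)[seq_len(n_ca9)]] <- TRUE
    }

    # --- lymphocytes ---
    n_fp <- round(params$foxp3_pos_fraction * params$n_lymphocyte)
    n_fn <- params$n_lymphocyte - n_fp
    w <- params$attraction / (1 + params$attraction)
    ca9_xy <- ep[ca9_pos, , drop = FALSE]
    fp <- matrix(numeric(0), ncol = 2)
    if (n_fp > 0) {
      near <- if (nrow(ca9_xy) > 0) runif(n_fp) < w else rep(FALSE, n_fp)
      fp <- matrix(0, nrow = n_fp, ncol = 2)
      n_near <- sum(near)
      if (n_near > 0) {
        anchor <- ca9_xy[sample.int(nrow(ca9_xy), n_near, replace = TRUE), , drop = FALSE]
        pt <- anchor + matrix(rnorm(2 * n_near, 0, params$attraction_bandwidth), ncol = 2)
        pt[, 1] <- pmin(pmax(pt[, 1], 0), params$field_width)
        pt[, 2] <- pmin(pmax(pt[, 2], 0), params$field_height)
        fp[near, ] <- pt
      }
      if (n_fp - n_near > 0) {
        fp[!near, ] <- cbind(
          runif(n_fp - n_near, 0, params$field_width),
          runif(n_fp - n_near, 0, params$field_height)
        )
      }
    }
    fn <- cbind(
      runif(n_fn, 0, params$field_width),
      runif(n_fn, 0, params$field_height)
    )

    # --- stroma ---
    st <- cbind(
      runif(params$n_stroma, 0, params$field_width),
      runif(params$n_stroma, 0, params$field_height)
    )

    xy <- rbind(ep, fp, fn, st)
    classes <- c(
      if_else(ca9_pos, "CA9_pos_epithelial", "CA9_neg_epithelial"),
      rep("FOXP3_pos_lymphocyte", n_fp),
      rep("FOXP3_neg_lymphocyte", n_fn),
      rep("stroma", params$n_stroma)
    )
    cells <- cell_map(
      tibble(
        cell_id = sprintf("c%06d", seq_len(nrow(xy))),
        x_um = xy[, 1], y_um = xy[, 2], cell_class = classes,
        in_duct = c(in_duct, rep(NA, nrow(xy) - length(in_duct)))
      ),
      section_id = section_id, sample_type = sample_type
    )
    structure(
      list(cells = cells, ducts = ducts, sample_type = sample_type, params = params),
      class = "synthetic_section"
    )
  })
}

#' @export
print.synthetic_section <- function(x, ...) {
  cat(
    "<synthetic_section>", attr(x$cells, "section_id"), "-", x$sample_type,
    ":", nrow(x$cells), "cells,", length(x$ducts$polygons), "ducts\n"
  )
  invisible(x)
}

#' Degrade a ground-truth cell map into synthetic detector output
#'
#' Emulates an imperfect cell detector/classifier: each true cell is
#' independently dropped with probability `drop_rate`; surviving cells are
#' displaced by isotropic Gaussian noise of s.d. `jitter_sd`; spurious
#' detections are added (binomial with rate `spurious_rate` per true cell) at
#' uniform positions with random classes; and surviving labels are replaced
#' by a random different class with probability `confusion_rate`.
#'
#' @param cells A [cell_map()] (ground truth).
#' @param jitter_sd Positional noise s.d. in microns (>= 0).
#' @param drop_rate,spurious_rate,confusion_rate Rates in [0, 1].
#' @param rng_seed Integer seed.
#' @param field Two-element width/height used to place spurious points;
#'   default the bounding box of the input.
#'
#' @return A predicted [cell_map()].
#' @export
degrade_detections <- function(cells, jitter_sd = 0, drop_rate = 0,
                               spurious_rate = 0, confusion_rate = 0,
                               rng_seed = 1L, field = NULL) {
  if (jitter_sd < 0) {
    abort("`jitter_sd` must be non-negative.", class = "ductcoloc_parameter_error")
  }
  for (r in c(drop_rate, spurious_rate, confusion_rate)) {
    if (r < 0 || r > 1) abort("rates must lie in [0, 1].", class = "ductcoloc_parameter_error")
  }
  n <- nrow(cells)
  field <- field %||% c(max(cells$x_um, 1), max(cells$y_um, 1))
  withr::with_seed(as.integer(rng_seed), {
    keep <- runif(n) >= drop_rate
    out <- as_tibble(cells)[keep, , drop = FALSE]
    m <- nrow(out)
    if (m > 0 && jitter_sd > 0) {
      out$x_um <- pmax(out$x_um + rnorm(m, 0, jitter_sd), 0)
      out$y_um <- pmax(out$y_um + rnorm(m, 0, jitter_sd), 0)
    }
    if (m > 0 && confusion_rate > 0) {
      flip <- runif(m) < confusion_rate
      if (any(flip)) {
        out$cell_class[flip] <- vapply(
          out$cell_class[flip],
          function(cl) sample(setdiff(cell_classes(), cl), 1L), character(1)
        )
      }
    }
    n_spur <- if (n > 0) rbinom(1L, n, spurious_rate) else 0L
    if (n_spur > 0) {
      spur <- tibble(
        cell_id = sprintf("spur%05d", seq_len(n_spur)),
        x_um = runif(n_spur, 0, field[1]),
        y_um = runif(n_spur, 0, field[2]),
        cell_class = sample(cell_classes(), n_spur, replace = TRUE)
      )
      for (nm in setdiff(names(out), names(spur))) spur[[nm]] <- NA
      out <- bind_rows(out, spur[, names(out)])
    }
    restore_cell_map(out, cells)
  })
}
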