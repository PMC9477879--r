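# Morisita-Horn colocalization over Voronoi quadrats and cellular abundance
# fractions, per whole section (pure DCIS) or per component (IDC/DCIS).

#' Morisita-Horn index of two quadrat count vectors
#'
#' The Horn (1966) simplified Morisita index
#' \deqn{MH = \frac{2\sum_i x_i y_i}{(\sum_i x_i^2/X^2 + \sum_i y_i^2/Y^2)\,XY}}
#' with \eqn{X = \sum_i x_i}, \eqn{Y = \sum_i y_i}, bounded in \[0, 1\]:
#' 0 means complete spatial segregation of the two populations across the
#' quadrats, 1 maximal colocalization (proportional counts everywhere). The
#' index is symmetric in its arguments.
#'
#' @param x,y Non-negative integer count vectors of equal length, one entry
#'   per quadrat.
#' @return The index, or `NA` when either population is absent (`X = 0` or
#'   `Y = 0`) — an insufficient-data result, not an error.
#' @export
#' @examples
#' morisita_horn(c(3, 7), c(6, 14)) # proportional -> 1
#' morisita_horn(c(5, 0), c(0, 5)) # disjoint -> 0
morisita_horn <- function(x, y) {
  if (length(x) != length(y)) {
    abort("quadrat count vectors must have equal length.",
      class = "ductcoloc_validation_error"
    )
  }
  if (any(x < 0) || any(y < 0)) {
    abort("quadrat counts must be non-negative.", class = "ductcoloc_validation_error")
  }
  x <- as.numeric(x)
  y <- as.numeric(y)
  X <- sum(x)
  Y <- sum(y)
  if (X == 0 || Y == 0) {
    return(NA_real_)
  }
  # integer-product form of 2*Sxy / ((Sxx/X^2 + Syy/Y^2) * X * Y): with
  # count data every term is an exact integer (within double precision), so
  # proportional counts give exactly 1, disjoint support exactly 0, and the
  # index is exactly symmetric in (x, y)
  sxy <- sum(x * y)
  2 * sxy * X * Y / (sum(x^2) * Y^2 + sum(y^2) * X^2)
}

#' Per-quadrat counts of two cell classes
#'
#' @param partition A `region_partition`.
#' @param class_a,class_b Two of [cell_classes()].
#' @param polygon_ids Optional subset of polygons (e.g. one component's).
#' @return Tibble with `polygon_id`, `x`, `y` counts.
#' @export
quadrat_counts <- function(partition, class_a, class_b, polygon_ids = NULL) {
  k <- length(partition$polygons)
  ids <- polygon_ids %||% seq_len(k)
  cls <- partition$cells$cell_class
  pid <- partition$assignment$polygon_id
  tibble(
    polygon_id = ids,
    x = tabulate(pid[cls == class_a], nbins = k)[ids],
    y = tabulate(pid[cls == class_b], nbins = k)[ids]
  )
}

#' Cellular abundance fractions
#'
#' FOXP3+ lymphocyte abundance is the number of FOXP3+ lymphocytes over all
#' lymphocytes; CA9+ epithelial abundance is the number of CA9+ epithelial
#' cells over all epithelial cells. A zero denominator yields `NA` with the
#' `insufficient_data` flag set.
#'
#' @param cells A cell table with a `cell_class` column.
#' @param component Label recorded in the output (e.g. `"whole_section"`).
#' @return One-row tibble with counts, the two abundance fractions and an
#'   `insufficient_data` flag.
#' @export
#' @examples
#' abundance(simulate_section(simulation_params(rng_seed = 1))$cells)
abundance <- function(cells, component = "whole_section") {
  cls <- cells$cell_class
  n_fp <- sum(cls == "FOXP3_pos_lymphocyte")
  n_lym <- sum(cls %in% lymphocyte_classes())
  n_cp <- sum(cls == "CA9_pos_epithelial")
  n_epi <- sum(cls %in% epithelial_classes())
  tibble(
    component = component,
    n_foxp3_pos = n_fp, n_lymphocyte = n_lym,
    n_ca9_pos = n_cp, n_epithelial = n_epi,
    foxp3_pos_abundance = if (n_lym > 0) n_fp / n_lym else NA_real_,
    ca9_pos_abundance = if (n_epi > 0) n_cp / n_epi else NA_real_,
    insufficient_data = n_lym == 0 || n_epi == 0
  )
}

#' Default colocalization class pairs
#'
#' The four FOXP3 x CA9 pairs compared in the analysis.
#'
#' @return List of length-2 character vectors.
#' @export
default_pairs <- function() {
  list(
    c("FOXP3_pos_lymphocyte", "CA9_pos_epithelial"),
    c("FOXP3_neg_lymphocyte", "CA9_pos_epithelial"),
    c("FOXP3_pos_lymphocyte", "CA9_neg_epithelial"),
    c("FOXP3_neg_lymphocyte", "CA9_neg_epithelial")
  )
}

mh_result_row <- function(section_id, sample_type, component, pair, q, min_cells) {
  n_component_cells <- if (is.null(attr(q, "component_n"))) NA_integer_ else attr(q, "component_n")
  insufficient <- nrow(q) < 2 ||
    (!is.na(n_component_cells) && n_component_cells < min_cells)
  mh <- if (insufficient) NA_real_ else morisita_horn(q$x, q$y)
  tibble(
    section_id = section_id, sample_type = sample_type, component = component,
    class_a = pair[1], class_b = pair[2],
    mh_index = mh,
    n_polygons = nrow(q), x_total = sum(q$x), y_total = sum(q$y),
    insufficient_data = insufficient || is.na(mh)
  )
}

#' Colocalization and abundance for one tissue section
#'
#' For a pure-DCIS section the whole region of interest is tessellated once
#' and one Morisita-Horn index per class pair is returned
#' (`component = "whole_section"`). For an IDC/DCIS section the tessellation
#' is typed against the duct mask and each pair's index is computed
#' separately over the synchronous-DCIS quadrats and over the IDC quadrats;
#' quadrat identity is shared across components (one tessellation, filtered
#' by type) unless `retessellate = TRUE`. Components failing the
#' minimum-data rule (fewer than `min_cells` cells or fewer than two
#' quadrats) yield a flagged `NA` index, never an error.
#'
#' @param cells A [cell_map()].
#' @param ducts A [duct_mask()]; required when the section's sample type is
#'   `IDC_DCIS`.
#' @param pairs List of class pairs (default [default_pairs()]).
#' @param t_low,t_high Typing thresholds, see [classify_polygons()].
#' @param min_cells Minimum cells for a component to yield an index.
#' @param rng_seed Seed for the tessellation.
#' @param roi Optional convex ROI ring.
#' @param retessellate If `TRUE`, re-tessellate each component's own cells
#'   instead of filtering the shared quadrats.
#' @param sample_type Override of the cell map's sample type attribute.
#'
#' @return A list with `colocalization` (tibble, one row per pair x
#'   component), `abundance` (tibble, one row per component) and
#'   `partition` (the `region_partition`, classified for IDC/DCIS).
#' @export
colocalize_section <- function(cells, ducts = NULL, pairs = default_pairs(),
                               t_low = 0.1, t_high = 0.9, min_cells = 50,
                               rng_seed = 1L, roi = NULL, retessellate = FALSE,
                               sample_type = NULL) {
  sample_type <- sample_type %||% sample_type_of(cells)
  section_id <- section_id_of(cells)
  bad <- setdiff(unlist(pairs), cell_classes())
  if (length(bad) > 0) {
    abort(paste0("unknown class in `pairs`: ", paste(bad, collapse = ", ")),
      class = "ductcoloc_validation_error"
    )
  }

  if (sample_type == "pure_DCIS") {
    part <- tessellate(cells, roi = roi, rng_seed = rng_seed)
    coloc <- purrr::map_dfr(pairs, function(pr) {
      q <- quadrat_counts(part, pr[1], pr[2])
      attr(q, "component_n") <- nrow(part$cells)
      mh_result_row(section_id, sample_type, "whole_section", pr, q, min_cells)
    })
    abund <- abundance(cells, "whole_section")
    abund$section_id <- section_id
    return(list(colocalization = coloc, abundance = abund, partition = part))
  }

  if (is.null(ducts)) {
    abort("IDC/DCIS sections require a duct mask to separate components.",
      class = "ductcoloc_configuration_error"
    )
  }
  part <- tessellate(cells, roi = roi, rng_seed = rng_seed)
  part <- classify_polygons(part, ducts, t_low = t_low, t_high = t_high)
  components <- c("synchronous_DCIS", "IDC")
  coloc <- purrr::map_dfr(components, function(comp) {
    comp_cells <- component_cells(cells, part, comp)
    if (retessellate && nrow(comp_cells) >= max(min_cells, 2)) {
      sub <- tryCatch(tessellate(comp_cells, rng_seed = rng_seed), error = function(e) NULL)
      purrr::map_dfr(pairs, function(pr) {
        if (is.null(sub)) {
          q <- tibble(polygon_id = integer(), x = integer(), y = integer())
        } else {
          q <- quadrat_counts(sub, pr[1], pr[2])
        }
        attr(q, "component_n") <- nrow(comp_cells)
        mh_result_row(section_id, sample_type, comp, pr, q, min_cells)
      })
    } else {
      ids <- part$regions$polygon_id[part$regions$region_type == comp]
      purrr::map_dfr(pairs, function(pr) {
        q <- quadrat_counts(part, pr[1], pr[2], polygon_ids = ids)
        attr(q, "component_n") <- nrow(comp_cells)
        mh_result_row(section_id, sample_type, comp, pr, q, min_cells)
      })
    }
  })
  abund <- purrr::map_dfr(components, function(comp) {
    abundance(component_cells(cells, part, comp), comp)
  })
  abund$section_id <- section_id
  list(colocalization = coloc, abundance = abund, partition = part)
}
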