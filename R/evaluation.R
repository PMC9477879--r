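# Validation metrics for detection, classification and segmentation stages:
# point matching with precision/recall/F1, five-class confusion summaries,
# mask overlap (Dice and friends) and the CA9-abundance/pathologist-score
# cross-tabulation.

detection_eval <- function(TP, FP, FN, match_radius = NA_real_, degenerate = FALSE) {
  precision <- if (TP + FP > 0) TP / (TP + FP) else if (degenerate) 1 else NA_real_
  recall <- if (TP + FN > 0) TP / (TP + FN) else if (degenerate) 1 else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && (precision + recall) > 0) {
    2 * precision * recall / (precision + recall)
  } else if (degenerate) {
    1
  } else {
    0
  }
  tibble(
    TP = TP, FP = FP, FN = FN,
    precision = precision, recall = recall, f1 = f1,
    match_radius = match_radius, degenerate = degenerate
  )
}

#' Detection metrics from raw counts
#'
#' Precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and their harmonic mean F1,
#' carried at full precision; round only for presentation.
#'
#' @param TP,FP,FN Non-negative counts.
#' @return One-row tibble (`TP`, `FP`, `FN`, `precision`, `recall`, `f1`,
#'   `degenerate`).
#' @export
#' @examples
#' metrics_from_counts(3591, 1200, 564)
metrics_from_counts <- function(TP, FP, FN) {
  if (any(c(TP, FP, FN) < 0)) {
    abort("counts must be non-negative.", class = "ductcoloc_parameter_error")
  }
  detection_eval(TP, FP, FN, degenerate = (TP + FP == 0 && TP + FN == 0))
}

#' F1 score from precision and recall
#'
#' @param precision,recall Values in [0, 1], not both zero.
#' @return The harmonic mean `2pr/(p+r)`.
#' @export
#' @examples
#' f1_from_pr(0.73, 0.62)
f1_from_pr <- function(precision, recall) {
  if (any(c(precision, recall) < 0) || any(c(precision, recall) > 1)) {
    abort("precision and recall must lie in [0, 1].", class = "ductcoloc_parameter_error")
  }
  if (precision + recall == 0) {
    abort("precision and recall cannot both be zero.", class = "ductcoloc_parameter_error")
  }
  2 * precision * recall / (precision + recall)
}

#' Match predicted cell centres against ground truth
#'
#' Builds the bipartite graph of predicted/truth point pairs closer than
#' `match_radius` and finds a maximum one-to-one matching (so the true
#' positive count is maximal; no greedy order-dependence). Matched pairs are
#' TP, unmatched predictions FP, unmatched truth FN. The default radius of
#' 10 um is about one nucleus diameter at 0.5 um/px.
#'
#' @param predicted,truth Data frames with `x_um`, `y_um` (extra columns
#'   ignored).
#' @param match_radius Maximum pairing distance in microns.
#' @return One-row tibble as in [metrics_from_counts()], plus
#'   `match_radius`. Empty truth and empty prediction give perfect vacuous
#'   agreement flagged `degenerate`.
#' @export
match_detections <- function(predicted, truth, match_radius = 10) {
  if (!is.numeric(match_radius) || match_radius <= 0) {
    abort("`match_radius` must be positive.", class = "ductcoloc_parameter_error")
  }
  np <- nrow(predicted)
  nt <- nrow(truth)
  if (np == 0 && nt == 0) {
    return(detection_eval(0L, 0L, 0L, match_radius, degenerate = TRUE))
  }
  if (np == 0 || nt == 0) {
    return(detection_eval(0L, np, nt, match_radius))
  }
  d2 <- outer(predicted$x_um, truth$x_um, `-`)^2 +
    outer(predicted$y_um, truth$y_um, `-`)^2
  hits <- which(d2 <= match_radius^2, arr.ind = TRUE)
  if (nrow(hits) == 0) {
    return(detection_eval(0L, np, nt, match_radius))
  }
  g <- igraph::graph_from_edgelist(
    cbind(hits[, 1], np + hits[, 2]),
    directed = FALSE
  )
  g <- igraph::add_vertices(g, max(0L, np + nt - igraph::vcount(g)))
  igraph::V(g)$type <- seq_len(np + nt) > np
  tp <- igraph::max_bipartite_match(g)$matching_size
  detection_eval(tp, np - tp, nt - tp, match_radius)
}

#' Segmentation overlap metrics for binary masks
#'
#' Pixelwise comparison of a predicted and a ground-truth mask: Dice
#' `2TP/(2TP+FP+FN)`, precision, recall (= sensitivity) and specificity
#' `TN/(TN+FP)`. Inputs are logical/0-1 matrices of identical shape, or
#' [duct_mask()] objects rasterised at `pixel_size` over a shared frame.
#'
#' @param predicted,truth Matrices or [duct_mask()] objects.
#' @param pixel_size,width_px,height_px Rasterisation frame for vector
#'   input; dimensions default to the joint bounding box.
#' @return One-row tibble with pixel counts and the five metrics.
#' @export
mask_metrics <- function(predicted, truth, pixel_size = 0.5,
                         width_px = NULL, height_px = NULL) {
  if (inherits(predicted, "duct_mask") || inherits(truth, "duct_mask")) {
    all_xy <- bind_rows(
      if (inherits(predicted, "duct_mask")) tidy.duct_mask(predicted) else NULL,
      if (inherits(truth, "duct_mask")) tidy.duct_mask(truth) else NULL
    )
    width_px <- width_px %||% ceiling(max(all_xy$x_um) / pixel_size + 2)
    height_px <- height_px %||% ceiling(max(all_xy$y_um) / pixel_size + 2)
    if (inherits(predicted, "duct_mask")) {
      predicted <- rasterize_mask(predicted, width_px, height_px, pixel_size)
    }
    if (inherits(truth, "duct_mask")) {
      truth <- rasterize_mask(truth, width_px, height_px, pixel_size)
    }
  }
  predicted <- as.matrix(predicted) != 0
  truth <- as.matrix(truth) != 0
  if (!identical(dim(predicted), dim(truth))) {
    abort("masks must have identical dimensions.", class = "ductcoloc_validation_error")
  }
  TP <- sum(predicted & truth)
  FP <- sum(predicted & !truth)
  FN <- sum(!predicted & truth)
  TN <- sum(!predicted & !truth)
  tibble(
    TP = TP, FP = FP, FN = FN, TN = TN,
    dice = if (2 * TP + FP + FN > 0) 2 * TP / (2 * TP + FP + FN) else 1,
    precision = if (TP + FP > 0) TP / (TP + FP) else NA_real_,
    recall = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
    sensitivity = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
    specificity = if (TN + FP > 0) TN / (TN + FP) else NA_real_
  )
}

#' Five-class confusion summary
#'
#' Confusion counts (true class in rows, predicted in columns), the
#' percentage of correct calls per predicted class (diagonal over column
#' sum, the column summary of a confusion table) and overall accuracy.
#'
#' @param true_labels,predicted_labels Character vectors over
#'   [cell_classes()] (or a common custom vocabulary via `levels`).
#' @param levels Label vocabulary; defaults to the five cell classes.
#' @return List with `confusion` (matrix), `per_predicted_pct` (named
#'   vector), `accuracy` (fraction) and `n`.
#' @export
classification_metrics <- function(true_labels, predicted_labels,
                                   levels = cell_classes()) {
  bad <- setdiff(unique(c(true_labels, predicted_labels)), levels)
  if (length(bad) > 0) {
    abort(paste0("unknown label(s): ", paste(bad, collapse = ", ")),
      class = "ductcoloc_validation_error"
    )
  }
  if (length(true_labels) != length(predicted_labels)) {
    abort("label vectors must have equal length.", class = "ductcoloc_validation_error")
  }
  conf <- table(
    true = factor(true_labels, levels = levels),
    predicted = factor(predicted_labels, levels = levels)
  )
  conf <- unclass(conf)
  colsum <- colSums(conf)
  per_pred <- ifelse(colsum > 0, 100 * diag(conf) / colsum, NA_real_)
  list(
    confusion = conf,
    per_predicted_pct = per_pred,
    accuracy = sum(diag(conf)) / max(sum(conf), 1),
    n = sum(conf)
  )
}

#' CA9 abundance bins versus pathologist score
#'
#' Cross-tabulates per-section CA9+ epithelial abundance, binned on the
#' percent scale into 0-1% (`[0, 1]`), 1-5% (`(1, 5]`) and >5% (`(5, 100]`),
#' against the pathologist's Positive/Negative CA9 score, with row
#' percentages rounded to the nearest integer.
#'
#' @param abundances Per-section CA9+ abundance fractions in [0, 1].
#' @param groups Per-section labels, `"Positive"` or `"Negative"`.
#' @return Tibble with one row per occupied bin: counts and row percentages
#'   per group plus the row total.
#' @export
#' @examples
#' ca9_bin_crosstab(c(0.005, 0.03, 0.2), c("Negative", "Positive", "Positive"))
ca9_bin_crosstab <- function(abundances, groups) {
  if (length(abundances) != length(groups)) {
    abort("need one group label per abundance.", class = "ductcoloc_validation_error")
  }
  if (any(abundances < 0 | abundances > 1, na.rm = TRUE)) {
    abort("abundances must be fractions in [0, 1].", class = "ductcoloc_validation_error")
  }
  groups <- as.character(groups)
  bad <- setdiff(unique(groups), c("Positive", "Negative"))
  if (length(bad) > 0) {
    abort(paste0("unknown pathologist group(s): ", paste(bad, collapse = ", ")),
      class = "ductcoloc_validation_error"
    )
  }
  bin <- cut(100 * abundances,
    breaks = c(0, 1, 5, 100),
    labels = c("0-1%", "1-5%", ">5%"), include.lowest = TRUE, right = TRUE
  )
  tab <- table(bin = bin, group = factor(groups, levels = c("Positive", "Negative")))
  out <- as_tibble(as.data.frame.matrix(unclass(tab)))
  out$bin <- rownames(unclass(tab))
  out <- out[, c("bin", "Positive", "Negative")]
  out$n <- out$Positive + out$Negative
  out$pct_positive <- ifelse(out$n > 0, round(100 * out$Positive / out$n), NA_real_)
  out$pct_negative <- ifelse(out$n > 0, round(100 * out$Negative / out$n), NA_real_)
  as_tibble(out[out$n > 0, , drop = FALSE])
}
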