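# Group comparisons of per-section colocalization/abundance values:
# pairwise Wilcoxon rank-sum with Holm adjustment, and covariate-adjusted
# linear-model tests of independence.

#' Pairwise Wilcoxon rank-sum tests with Holm adjustment
#'
#' Compares a per-section measurement between every pair of groups with the
#' Wilcoxon rank-sum test (exact when the combined sample is small and
#' tie-free, tie-corrected normal approximation otherwise — the default
#' behaviour of [stats::wilcox.test()]), then applies the Holm step-down
#' adjustment across the pairs of one call as a single family. `NA` values
#' are dropped (not zero-filled) and the retained group sizes reported.
#'
#' @param data Data frame of measurements.
#' @param value,group Column names (strings) of the measurement and the
#'   group label.
#' @param min_n Minimum retained values per group; pairs with a smaller
#'   group are skipped with a warning.
#' @return Tibble with `group1`, `group2`, `n1`, `n2`, `p_raw`, `p_holm`.
#' @export
#' @examples
#' d <- data.frame(v = c(1, 2, 3, 8, 9, 10), g = rep(c("a", "b"), each = 3))
#' pairwise_wilcoxon_holm(d, "v", "g")
pairwise_wilcoxon_holm <- function(data, value = "mh_index", group = "group", min_n = 2) {
  vals <- data[[value]]
  grp <- as.character(data[[group]])
  keep <- !is.na(vals) & is.finite(vals) & !is.na(grp)
  vals <- vals[keep]
  grp <- grp[keep]
  groups <- unique(grp)
  if (length(groups) < 2) {
    abort("need at least two groups with retained values.",
      class = "ductcoloc_validation_error"
    )
  }
  combos <- utils::combn(sort(groups), 2)
  rows <- purrr::map_dfr(seq_len(ncol(combos)), function(i) {
    g1 <- combos[1, i]
    g2 <- combos[2, i]
    v1 <- vals[grp == g1]
    v2 <- vals[grp == g2]
    if (length(v1) < min_n || length(v2) < min_n) {
      warn(paste0("skipping ", g1, " vs ", g2, ": a group has fewer than ", min_n, " values."))
      return(tibble(
        group1 = g1, group2 = g2, n1 = length(v1), n2 = length(v2),
        p_raw = NA_real_
      ))
    }
    p <- suppressWarnings(wilcox.test(v1, v2)$p.value)
    tibble(group1 = g1, group2 = g2, n1 = length(v1), n2 = length(v2), p_raw = p)
  })
  rows$p_holm <- NA_real_
  tested <- !is.na(rows$p_raw)
  rows$p_holm[tested] <- p.adjust(rows$p_raw[tested], method = "holm")
  rows
}

#' Covariate-adjusted group difference
#'
#' Tests whether a group difference in an outcome (e.g. a colocalization
#' index) survives adjustment for covariates, by fitting an ordinary linear
#' model `outcome ~ group + covariates` and reporting the group
#' coefficient's p-value as the adjusted test. `method = "rank"` fits the
#' same model to the rank-transformed outcome, a rank-based alternative
#' that is robust to outcome scale.
#'
#' @param data Data frame.
#' @param outcome,group Column names (strings); the group column is coerced
#'   to a factor (two or more levels).
#' @param covariates Character vector of covariate column names.
#' @param method `"linear"` or `"rank"`.
#' @return Object of class `adjusted_difference` wrapping the `lm` fit;
#'   use [tidy()] for the coefficient table and [glance()] for fit
#'   summaries.
#' @export
adjusted_difference <- function(data, outcome, group, covariates = character(),
                                method = c("linear", "rank")) {
  method <- match.arg(method)
  cols <- c(outcome, group, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
      class = "ductcoloc_validation_error"
    )
  }
  d <- data[stats::complete.cases(data[, cols, drop = FALSE]), cols, drop = FALSE]
  d[[group]] <- factor(d[[group]])
  if (nlevels(d[[group]]) < 2) {
    abort("`group` must have at least two levels after dropping NAs.",
      class = "ductcoloc_validation_error"
    )
  }
  y <- if (method == "rank") rank(d[[outcome]]) else d[[outcome]]
  d$.outcome <- y
  rhs <- paste(c(group, covariates), collapse = " + ")
  fit <- lm(stats::as.formula(paste(".outcome ~", rhs)), data = d)
  if (fit$rank < length(coef(fit))) {
    dropped <- names(coef(fit))[is.na(coef(fit))]
    abort(paste0(
      "rank-deficient design; collinear term(s): ",
      paste(dropped, collapse = ", ")
    ), class = "ductcoloc_validation_error")
  }
  structure(
    list(fit = fit, outcome = outcome, group = group,
      covariates = covariates, method = method, n = nrow(d)),
    class = "adjusted_difference"
  )
}

#' @export
print.adjusted_difference <- function(x, ...) {
  cat(
    "<adjusted_difference>", x$outcome, "~", x$group,
    if (length(x$covariates)) paste("+", paste(x$covariates, collapse = " + ")) else "",
    paste0("(", x$method, ", n = ", x$n, ")\n")
  )
  print(tidy(x))
  invisible(x)
}

#' Coefficient table of an adjusted group-difference fit
#'
#' @param x An [adjusted_difference()] object.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std_error`, `statistic`,
#'   `p_value` and `is_group_term` marking the group-indicator rows whose
#'   p-values constitute the adjusted test.
#' @export
tidy.adjusted_difference <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  out <- tibble(
    term = rownames(sm),
    estimate = sm[, 1], std_error = sm[, 2],
    statistic = sm[, 3], p_value = sm[, 4]
  )
  out$is_group_term <- startsWith(out$term, x$group)
  out
}

#' Fit summary of an adjusted group-difference fit
#'
#' @param x An [adjusted_difference()] object.
#' @param ... Unused.
#' @return One-row tibble with `r_squared`, `adj_r_squared`, `sigma`,
#'   `df_residual`, `n`, `method`.
#' @export
glance.adjusted_difference <- function(x, ...) {
  sm <- summary(x$fit)
  tibble(
    r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
    sigma = sm$sigma, df_residual = x$fit$df.residual,
    n = x$n, method = x$method
  )
}

#' Group p-value of an adjusted difference
#'
#' Convenience accessor: the smallest p-value among the group-indicator
#' coefficients (for a two-level group, the single adjusted p-value).
#'
#' @param x An [adjusted_difference()] object.
#' @return A p-value.
#' @export
adjusted_p <- function(x) {
  td <- tidy(x)
  min(td$p_value[td$is_group_term])
}
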