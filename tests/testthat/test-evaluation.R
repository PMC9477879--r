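# Detection, classification, segmentation and cross-tab metrics.

test_that("detection metrics recompute from counts at full precision", {
  m <- metrics_from_counts(3591, 1200, 564)
  expect_equal(m$precision, 3591 / 4791)
  expect_equal(m$recall, 3591 / 4155)
  expect_equal(round(m$recall, 2), 0.86)
  expect_equal(round(m$f1, 2), 0.80)
  expect_equal(metrics_from_counts(1, 0, 0)[, c("precision", "recall", "f1")],
    tibble::tibble(precision = 1, recall = 1, f1 = 1),
    ignore_attr = TRUE
  )
  z <- metrics_from_counts(0, 5, 5)
  expect_equal(c(z$precision, z$recall, z$f1), c(0, 0, 0))
  expect_error(metrics_from_counts(-1, 0, 0), class = "ductcoloc_parameter_error")
})

test_that("F1 is the harmonic mean of precision and recall", {
  expect_equal(round(f1_from_pr(0.73, 0.62), 2), 0.67)
  expect_equal(f1_from_pr(1, 1), 1)
  expect_equal(f1_from_pr(0.5, 0.5), 0.5)
  withr::with_seed(4, {
    for (i in 1:50) {
      p <- runif(1, 0.05, 1)
      r <- runif(1, 0.05, 1)
      f1 <- f1_from_pr(p, r)
      expect_gte(f1, min(p, r) - 1e-12)
      expect_lte(f1, max(p, r) + 1e-12)
    }
  })
  expect_error(f1_from_pr(0, 0), class = "ductcoloc_parameter_error")
})

test_that("point matching is optimal (brute-force oracle) and handles edge cases", {
  pts <- tibble::tibble(x_um = c(1, 2, 3), y_um = c(1, 2, 3))
  ev <- match_detections(pts, pts, match_radius = 5)
  expect_equal(c(ev$precision, ev$recall, ev$f1), c(1, 1, 1))

  # 10 truth points, two dropped, one far spurious
  withr::with_seed(17, {
    truth <- tibble::tibble(x_um = runif(10, 0, 100), y_um = runif(10, 0, 100))
    pred <- truth[1:8, ]
    pred <- rbind(pred, tibble::tibble(x_um = 500, y_um = 500))
  })
  ev <- match_detections(pred, truth, match_radius = 5)
  expect_equal(c(ev$TP, ev$FP, ev$FN), c(8, 1, 2))

  # randomly jittered clouds: matching size equals the brute-force optimum
  withr::with_seed(23, {
    for (i in 1:10) {
      truth <- tibble::tibble(x_um = runif(8, 0, 30), y_um = runif(8, 0, 30))
      pred <- tibble::tibble(
        x_um = runif(9, 0, 30), y_um = runif(9, 0, 30)
      )
      ev <- match_detections(pred, truth, match_radius = 8)
      expect_equal(ev$TP, brute_force_match(pred, truth, 8))
    }
  })

  # vacuous agreement
  empty <- tibble::tibble(x_um = numeric(), y_um = numeric())
  ev0 <- match_detections(empty, empty)
  expect_true(ev0$degenerate)
  expect_equal(c(ev0$precision, ev0$recall, ev0$f1), c(1, 1, 1))
  ev1 <- match_detections(empty, pts)
  expect_equal(c(ev1$TP, ev1$FP, ev1$FN), c(0, 0, 3))
})

test_that("count-based and matching-based metrics agree when matching is unambiguous", {
  truth <- tibble::tibble(x_um = seq(0, 900, by = 100), y_um = rep(0, 10))
  pred <- truth[c(1:7), ]
  pred$x_um <- pred$x_um + 0.5 # well inside the radius
  pred <- rbind(pred, tibble::tibble(x_um = c(5000, 6000), y_um = 0))
  ev <- match_detections(pred, truth, match_radius = 10)
  expect_equal(
    ev[, c("TP", "FP", "FN", "precision", "recall", "f1")],
    metrics_from_counts(7, 2, 3)[, c("TP", "FP", "FN", "precision", "recall", "f1")],
    ignore_attr = TRUE
  )
})

test_that("mask metrics satisfy the Dice identities", {
  a <- matrix(0L, 20, 20)
  a[5:14, 5:14] <- 1L
  expect_equal(mask_metrics(a, a)$dice, 1)
  expect_equal(mask_metrics(a, a)$specificity, 1)
  b <- matrix(0L, 20, 20)
  b[5:14, 15:20] <- 1L # disjoint, different area
  expect_equal(mask_metrics(a, b)$dice, 0)
  # unit squares overlapping by half their area -> Dice 0.5
  c1 <- matrix(0L, 10, 20)
  c2 <- matrix(0L, 10, 20)
  c1[1:10, 1:10] <- 1L
  c2[1:10, 6:15] <- 1L
  m <- mask_metrics(c1, c2)
  expect_equal(m$dice, 0.5)
  # symmetry and translation invariance
  expect_equal(mask_metrics(c2, c1)$dice, m$dice)
  d1 <- cbind(matrix(0L, 10, 3), c1[, 1:17])
  d2 <- cbind(matrix(0L, 10, 3), c2[, 1:17])
  expect_equal(mask_metrics(d1, d2)$dice, 0.5)
  expect_error(mask_metrics(a, c1), class = "ductcoloc_validation_error")
})

test_that("vector masks rasterise consistently for segmentation metrics", {
  truth <- duct_mask(list(cbind(c(0, 20, 20, 0), c(0, 0, 20, 20))))
  pred <- duct_mask(list(cbind(c(10, 30, 30, 10), c(0, 0, 20, 20))))
  m <- mask_metrics(pred, truth, pixel_size = 0.5)
  expect_equal(m$dice, 0.5, tolerance = 0.02)
})

test_that("confusion summaries give per-predicted-class percentages and accuracy", {
  lv <- cell_classes()
  truth <- rep(lv, times = c(20, 20, 20, 20, 20))
  m <- classification_metrics(truth, truth)
  expect_equal(m$accuracy, 1)
  expect_true(all(m$per_predicted_pct == 100))

  # 2-class toy with a custom vocabulary: 9 of 10 predicted-A correct
  tr <- c(rep("A", 9), "B", rep("B", 5))
  pr <- c(rep("A", 10), rep("B", 5))
  m2 <- classification_metrics(tr, pr, levels = c("A", "B"))
  expect_equal(unname(m2$per_predicted_pct["A"]), 90)
  expect_error(classification_metrics(c("A", "X"), c("A", "A"), levels = c("A", "B")),
    class = "ductcoloc_validation_error"
  )
})

test_that("random-label accuracy matches the class-frequency expectation", {
  withr::with_seed(31, {
    freqs <- c(0.07, 0.04, 0.43, 0.12, 0.34)
    n <- 20000
    tr <- sample(cell_classes(), n, replace = TRUE, prob = freqs)
    pr <- sample(cell_classes(), n, replace = TRUE, prob = freqs)
    m <- classification_metrics(tr, pr)
    expected <- sum(freqs^2)
    se <- sqrt(expected * (1 - expected) / n)
    expect_lt(abs(m$accuracy - expected), 4 * se)
  })
})

test_that("CA9 abundance bins cross-tabulate against pathologist groups", {
  # a 1-5% bin with 5 positive of 11 sections gives a 45% row
  ab <- rep(0.03, 11)
  gr <- c(rep("Positive", 5), rep("Negative", 6))
  tab <- ca9_bin_crosstab(ab, gr)
  row <- tab[tab$bin == "1-5%", ]
  expect_equal(row$Positive, 5)
  expect_equal(row$pct_positive, 45)
  expect_equal(row$pct_negative, 55)

  # boundary placement: half-open upward bins
  tab2 <- ca9_bin_crosstab(c(0.005, 0.01, 0.03, 0.05, 0.2), rep("Negative", 5))
  expect_equal(tab2$n[tab2$bin == "0-1%"], 2) # 0.5% and exactly 1%
  expect_equal(tab2$n[tab2$bin == "1-5%"], 2) # 3% and exactly 5%
  expect_equal(tab2$n[tab2$bin == ">5%"], 1)

  # all-negative sections with zero abundance collapse to one row
  tab3 <- ca9_bin_crosstab(rep(0, 4), rep("Negative", 4))
  expect_equal(nrow(tab3), 1)
  expect_equal(tab3$pct_negative, 100)
  expect_error(ca9_bin_crosstab(c(1.2), "Positive"), class = "ductcoloc_validation_error")
  # row percentages always recompute from the counts
  expect_equal(tab$pct_positive, round(100 * tab$Positive / tab$n))
})
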