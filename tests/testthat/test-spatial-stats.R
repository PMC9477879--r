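# Morisita-Horn index, abundance fractions and per-section colocalization.

test_that("Morisita-Horn hits its closed-form anchor values", {
  expect_equal(morisita_horn(c(5, 0), c(0, 5)), 0) # disjoint support
  expect_equal(morisita_horn(c(3, 7), c(6, 14)), 1) # proportional counts
  expect_equal(morisita_horn(c(1, 1), c(1, 0)), 2 / 3) # hand-evaluated
  expect_true(is.na(morisita_horn(c(0, 0), c(1, 2)))) # absent population
  expect_error(morisita_horn(c(1, 2), c(1, 2, 3)), class = "ductcoloc_validation_error")
  expect_error(morisita_horn(c(-1, 2), c(1, 2)), class = "ductcoloc_validation_error")
})

test_that("Morisita-Horn is symmetric, bounded and scale-invariant (property sweep)", {
  withr::with_seed(99, {
    for (i in 1:500) {
      k <- sample(2:20, 1)
      x <- rpois(k, sample(1:10, 1))
      y <- rpois(k, sample(1:10, 1))
      if (sum(x) == 0 || sum(y) == 0) next
      mh <- morisita_horn(x, y)
      expect_gte(mh, 0)
      expect_lte(mh, 1 + 1e-12)
      expect_identical(mh, morisita_horn(y, x))
      expect_equal(mh == 0, sum(x * y) == 0)
      c_scale <- sample(1:5, 1)
      expect_equal(morisita_horn(x, c_scale * x), 1)
    }
  })
})

test_that("abundance implements the two ratio definitions with null handling", {
  cls <- c(
    rep("FOXP3_pos_lymphocyte", 5), rep("FOXP3_neg_lymphocyte", 15),
    rep("CA9_pos_epithelial", 2), rep("CA9_neg_epithelial", 8)
  )
  cells <- toy_cells(cbind(seq_along(cls), seq_along(cls)), cls)
  ab <- abundance(cells)
  expect_equal(ab$foxp3_pos_abundance, 0.25)
  expect_equal(ab$ca9_pos_abundance, 0.2)
  expect_false(ab$insufficient_data)
  # zero FOXP3+ of ten lymphocytes
  ab0 <- abundance(toy_cells(cbind(1:10, 1:10), rep("FOXP3_neg_lymphocyte", 10)))
  expect_equal(ab0$foxp3_pos_abundance, 0)
  # no lymphocytes at all -> flagged null
  abn <- abundance(toy_cells(cbind(1:4, 1:4), rep("CA9_pos_epithelial", 4)))
  expect_true(is.na(abn$foxp3_pos_abundance))
  expect_true(abn$insufficient_data)
})

test_that("colocalize_section bookkeeping: 4 indices for pure DCIS, 8 for IDC/DCIS", {
  pure <- simulate_section(small_params(11), "pure_DCIS")
  res_p <- colocalize_section(pure$cells, rng_seed = 11)
  expect_equal(nrow(res_p$colocalization), 4)
  expect_true(all(res_p$colocalization$component == "whole_section"))

  idc <- simulate_section(small_params(12), "IDC_DCIS")
  res_i <- colocalize_section(idc$cells, idc$ducts, rng_seed = 12)
  expect_equal(nrow(res_i$colocalization), 8)
  expect_equal(
    sort(unique(res_i$colocalization$component)),
    c("IDC", "synchronous_DCIS")
  )
  expect_equal(nrow(res_i$abundance), 2)
})

test_that("IDC/DCIS sections without a duct mask are a configuration error", {
  idc <- simulate_section(small_params(13), "IDC_DCIS")
  expect_error(colocalize_section(idc$cells), class = "ductcoloc_configuration_error")
})

test_that("a duct-free IDC/DCIS section yields flagged null synchronous indices", {
  idc <- simulate_section(small_params(14, invasive_fraction = 1, n_ducts = 0), "IDC_DCIS")
  res <- colocalize_section(idc$cells, duct_mask(list()), rng_seed = 14)
  sync <- dplyr::filter(res$colocalization, component == "synchronous_DCIS")
  expect_true(all(sync$insufficient_data))
  expect_true(all(is.na(sync$mh_index)))
  idc_rows <- dplyr::filter(res$colocalization, component == "IDC")
  expect_true(all(!idc_rows$insufficient_data))
})

test_that("FOXP3+ cells confined to the invasive component give zero synchronous abundance", {
  sec <- simulate_section(small_params(15), "IDC_DCIS")
  # move every FOXP3+ lymphocyte into the invasive zone (x > 1100)
  cells <- as.data.frame(sec$cells)
  fp <- cells$cell_class == "FOXP3_pos_lymphocyte"
  cells$x_um[fp] <- withr::with_seed(99, runif(sum(fp), 1300, 1990))
  cells <- cell_map(cells,
    section_id = sec$ducts$section_id,
    sample_type = "IDC_DCIS"
  )
  res <- colocalize_section(cells, sec$ducts, rng_seed = 15)
  sync_ab <- dplyr::filter(res$abundance, component == "synchronous_DCIS")
  expect_equal(sync_ab$foxp3_pos_abundance, 0)
})

test_that("colocalization output is reproducible bit-for-bit under a fixed seed", {
  sec <- simulate_section(small_params(16), "IDC_DCIS")
  r1 <- colocalize_section(sec$cells, sec$ducts, rng_seed = 3)
  r2 <- colocalize_section(sec$cells, sec$ducts, rng_seed = 3)
  expect_identical(r1$colocalization, r2$colocalization)
  expect_identical(r1$abundance, r2$abundance)
})

test_that("attraction raises the FOXP3+/CA9+ index in paired sections", {
  diffs <- vapply(1:25, function(s) {
    hi <- simulate_section(small_params(s, attraction = 5), "pure_DCIS")
    lo <- simulate_section(small_params(s, attraction = 0), "pure_DCIS")
    mh <- function(sec) {
      q <- quadrat_counts(
        tessellate(sec$cells, rng_seed = s),
        "FOXP3_pos_lymphocyte", "CA9_pos_epithelial"
      )
      morisita_horn(q$x, q$y)
    }
    mh(hi) - mh(lo)
  }, numeric(1))
  expect_gte(mean(diffs > 0), 0.95)
})
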