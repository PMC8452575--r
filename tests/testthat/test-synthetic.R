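test_that("phantom generation honours geometry, intensities and determinism", {
  ps <- phantom_spec(haematoma_radius_mm = 15, slice_thickness_mm = 1, seed = 71)
  ph <- generate_phantom(ps)
  v_ml <- region_volume_ml(ph$mask, 1)
  expect_lt(abs(v_ml - 4 / 3 * pi * 15^3 / 1000) / (4 / 3 * pi * 15^3 / 1000),
            0.05)
  inside <- ph$volume$data[ph$mask$labels == 1L]
  expect_lt(abs(mean(inside) - 65), 2 * 8 / sqrt(length(inside)))
  ph2 <- generate_phantom(ps)
  expect_identical(ph$volume$data, ph2$volume$data)
  expect_identical(ph$mask$labels, ph2$mask$labels)
  # anisotropic acquisition stores the slab spacing
  ph5 <- generate_phantom(phantom_spec(slice_thickness_mm = 5, seed = 71))
  expect_equal(ph5$volume$spacing, c(1, 1, 5))
  expect_error(phantom_spec(haematoma_radius_mm = 60), "envelope")
})

test_that("batch-effect injection is the stated location-scale map", {
  set.seed(72)
  X <- matrix(rnorm(300 * 10), 300, 10)
  b <- rep(1:3, each = 100)
  expect_identical(inject_batch_effects(X, b, c(0, 0, 0), c(1, 1, 1)), X)
  Xb <- inject_batch_effects(X, b, c(0, 5, -5), c(1, 1, 1))
  expect_gt(batch_mixing_score(Xb, b), 0.5)
  expect_error(inject_batch_effects(X, b, c(0, 0, 0), c(1, 0, 1)), "> 0")
})

test_that("outcome simulation hits its calibrated prevalence targets", {
  spec <- cohort_spec(n = 2000, beta_growth = 0, beta_outcome = 0, seed = 73)
  coh <- generate_cohort(spec)
  expect_lt(abs(mean(coh$outcomes$expansion) - 0.27), 0.04)
  expect_lt(abs(mean(coh$outcomes$poor_outcome) - 0.50), 0.04)
  # poor outcome iff mRS 4-6
  expect_identical(coh$outcomes$poor_outcome,
                   unname(label_poor_outcome(coh$outcomes$mrs_day90)))
  # determinism
  coh2 <- generate_cohort(spec)
  expect_identical(coh$outcomes, coh2$outcomes)
})

test_that("expansion risk is monotone in baseline volume under volume signal", {
  spec <- cohort_spec(n = 4000, beta_growth = 0, beta_outcome = 0,
                      v0_beta_growth = 1, seed = 74)
  coh <- generate_cohort(spec)
  qt <- cut(coh$clinical$v0_ml,
            quantile(coh$clinical$v0_ml, seq(0, 1, 0.25)),
            include.lowest = TRUE)
  rates <- tapply(coh$outcomes$expansion, qt, mean)
  expect_true(all(diff(as.numeric(rates)) > 0))
})

test_that("the duplicate feature block is collapsed by the correlation filter", {
  spec <- cohort_spec(n = 600, p = 30, duplicate_block = 5,
                      duplicate_r = 0.95, seed = 75)
  coh <- generate_cohort(spec)
  block <- sprintf("feat_%03d", 1:5)
  C <- cor(coh$features[, block])
  expect_gt(min(C[upper.tri(C)]), 0.9)
  kept <- correlation_filter(coh$features, 0.9)
  expect_equal(sum(block %in% kept), 1)
})

test_that("image-level cohort shares the schema and flows through extraction", {
  spec <- cohort_spec(n = 2, seed = 76)
  coh <- generate_cohort(spec, level = "image")
  expect_equal(dim(coh$features), c(2L, 754L))
  expect_identical(colnames(coh$features), feature_catalogue()$id)
  expect_true(all(c("age", "gender", "batch") %in% names(coh$clinical)))
  expect_true(all(c("v0_ml", "expansion", "poor_outcome") %in%
                  names(coh$outcomes)))
})
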