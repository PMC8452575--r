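test_that("NIfTI round trip preserves data, spacing and squeezes singletons", {
  tmp <- tempfile(fileext = ".nii.gz")
  on.exit(unlink(tmp))
  set.seed(1)
  v <- make_grid(rnorm(20 * 20 * 4), c(20, 20, 4), spacing = c(1, 1, 5))
  write_volume(v, tmp)
  v2 <- read_volume(tmp)
  expect_equal(v2$spacing, c(1, 1, 5))
  expect_lt(max(abs(v2$data - v$data)), 1e-6)

  # 4th singleton dimension is squeezed
  img <- RNifti::asNifti(array(rnorm(8^3), c(8, 8, 8, 1)))
  tmp2 <- tempfile(fileext = ".nii.gz")
  on.exit(unlink(tmp2), add = TRUE)
  RNifti::writeNifti(img, tmp2)
  expect_length(dim(read_volume(tmp2)$data), 3)
})

test_that("invalid volumes are rejected with informative errors", {
  expect_error(volume_grid(array(1, c(4, 4)), c(1, 1, 1)), "3 axes")
  expect_error(volume_grid(array(1, c(4, 4, 4)), c(1, 0, 1)), "spacing")
  bad <- array(1, c(4, 4, 4)); bad[1] <- NA
  expect_error(volume_grid(bad, c(1, 1, 1)), "non-finite")
  expect_error(region_mask(array(7L, c(2, 2, 2)), c(1, 1, 1)), "label_map")
})

test_that("isotropic resampling covers the extent and is exact on analytic fields", {
  set.seed(2)
  v <- make_grid(rnorm(20 * 20 * 4), c(20, 20, 4), spacing = c(0.5, 0.5, 5))
  r <- resample_isotropic(v, 1)
  expect_equal(dim(r$data), c(10L, 10L, 20L))
  expect_equal(r$spacing, c(1, 1, 1))

  # constant field stays constant under interpolation
  cv <- resample_isotropic(make_grid(7, c(8, 8, 8), c(2, 1, 3)), 1)
  expect_lt(max(abs(cv$data - 7)), 1e-12)

  # linear ramp: resampled values match the analytic ramp at new voxel centres
  ramp <- make_grid(rep(seq_len(16), times = 16 * 16), c(16, 16, 16),
                    spacing = c(2, 2, 2))
  rr <- resample_isotropic(ramp, 1)
  u <- pmin(pmax((seq_len(32) - 0.5) * 0.5 - 0.5, 0), 15)
  expect_lt(max(abs(rr$data[, 1, 1] - (u + 1))), 1e-6)

  # idempotent at target spacing
  same <- resample_isotropic(rr, 1)
  expect_lt(max(abs(same$data - rr$data)), 1e-6)

  expect_error(resample_isotropic(v, -1), "positive")
})

test_that("mask resampling preserves labels and approximately preserves volume", {
  ball <- digital_ball(10)
  m <- region_mask(ball$labels, c(0.8, 0.8, 2.4))
  r <- resample_isotropic(m, 1)
  expect_true(all(r$labels %in% c(0L, 1L)))
  v_in <- region_volume_ml(m, 1)
  v_out <- region_volume_ml(r, 1)
  expect_lt(abs(v_out - v_in) / v_in, 0.02)
})

test_that("region volumes follow the unit conversion exactly", {
  m <- make_mask(c(rep(1, 1000), rep(0, 24)), c(8, 8, 16))
  expect_equal(region_volume_ml(m, 1), 1.0)
  expect_equal(region_volume_ml(m, 3), 0.0)
  m2 <- region_mask(array(c(rep(1L, 125), rep(0L, 91)), c(6, 6, 6)), c(2, 2, 2))
  expect_equal(region_volume_ml(m2, 1), 1.0)
  expect_error(region_volume_ml(m2, 9), "unknown label")
})
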