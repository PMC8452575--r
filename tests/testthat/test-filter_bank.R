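test_that("LoG filter is zero on constants, negative at a bright blob, linear", {
  const <- make_grid(7, c(12, 12, 12))
  expect_lt(max(abs(log_filter(const, 1.5)$data)), 1e-8)

  # bright Gaussian blob: LoG at the mode is strictly negative
  n <- 21; ctr <- 11
  idx <- as.matrix(expand.grid(1:n, 1:n, 1:n))
  blob <- array(exp(-colSums((t(idx) - ctr)^2) / (2 * 9)), c(n, n, n))
  resp <- log_filter(volume_grid(blob, c(1, 1, 1)), 1.5)
  expect_lt(resp$data[ctr, ctr, ctr], 0)

  set.seed(3)
  x <- make_grid(rnorm(10^3), c(10, 10, 10))
  y <- make_grid(rnorm(10^3), c(10, 10, 10))
  lin <- volume_grid(2 * x$data - 3 * y$data, c(1, 1, 1))
  expect_lt(max(abs(log_filter(lin, 2.5)$data -
                    (2 * log_filter(x, 2.5)$data - 3 * log_filter(y, 2.5)$data))),
            1e-6)
  expect_error(log_filter(x, 0), "positive")
})

test_that("stationary wavelet subbands: vanishing details, shape, Parseval", {
  const <- make_grid(5, c(16, 16, 16))
  wb <- wavelet_subbands(const)
  expect_named(wb, c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH"))
  details <- sapply(wb[-1], function(w) max(abs(w$data)))
  expect_lt(max(details), 1e-8)
  # low-pass taps sum to 1 under the stationary normalisation
  expect_lt(max(abs(wb$LLL$data - 5)), 1e-8)
  for (w in wb) expect_equal(dim(w$data), c(16L, 16L, 16L))

  set.seed(4)
  x <- make_grid(rnorm(16^3), c(16, 16, 16))
  wp <- wavelet_subbands(x, boundary = "periodic")
  e <- sum(sapply(wp, function(w) sum(w$data^2)))
  expect_lt(abs(e / sum(x$data^2) - 1), 1e-6)

  expect_error(wavelet_subbands(make_grid(1, c(3, 16, 16))), "filter length")
})

test_that("build_image_set emits the frozen 13-image contract deterministically", {
  set.seed(5)
  v <- make_grid(rnorm(12^3), c(12, 12, 12))
  s1 <- build_image_set(v)
  expect_named(s1, c("Intensities", "LoG-05", "LoG-15", "LoG-25", "LoG-35",
                     paste0("Wavelet-", c("LLL", "LLH", "LHL", "LHH",
                                          "HLL", "HLH", "HHL", "HHH"))))
  s2 <- build_image_set(v)
  expect_identical(lapply(s1, `[[`, "data"), lapply(s2, `[[`, "data"))

  # empty sigma list drops the LoG images; catalogue guards catch it later
  s0 <- build_image_set(v, sigmas = numeric(0))
  expect_length(s0, 9)
  expect_error(feature_catalogue(numeric(0)), "754")
})
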