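const_roi <- function(n = 3) {
  discretise(make_grid(4, c(n, n, n)), make_mask(rep(1, n^3), c(n, n, n)))
}

test_that("GLCM features match hand-enumerated and degenerate cases", {
  d <- const_roi()
  g <- glcm_features(d)
  expect_equal(unname(g[c("GLCM dissimilarity", "GLCM entropy")]), c(0, 0))

  # strip 1,2,1,2: three adjacent pairs, all dissimilar by 1
  vs <- make_grid(c(0, 31, 0, 31), c(4, 1, 1))
  ms <- make_mask(rep(1, 4), c(4, 1, 1))
  g2 <- glcm_features(discretise(vs, ms, 1L, 2L))
  expect_equal(unname(g2[c("GLCM dissimilarity", "GLCM contrast")]), c(1, 1))

  # maximum-entropy matrix: log2(16) bits
  u <- ichradiomics:::.glcm_stats(matrix(1 / 16, 4, 4))
  expect_equal(unname(u["GLCM entropy"]), 4)
})

test_that("GLRLM features: single runs, alternating patterns, monotonicity", {
  # single direction: strip of 6 equal levels is one run of length 6
  m <- oracle_glrlm_matrix(array(rep(1L, 6), c(6, 1, 1)), 1, c(1, 0, 0))
  expect_equal(m[1, 6], 1)
  expect_equal(sum(m), 1)
  expect_equal(ichradiomics:::.glrlm_stats(m, 6)[["GLRLM run percentage"]], 1 / 6)

  # alternating levels: every run has length 1 in every direction
  va <- make_grid(rep(c(0, 31), 3), c(6, 1, 1))
  da <- discretise(va, make_mask(rep(1, 6), c(6, 1, 1)), 1L, 2L)
  expect_equal(glrlm_features(da)[["GLRLM long run emphasis"]], 1)

  # constant cube has longer runs than the alternating pattern
  expect_gt(glrlm_features(const_roi())[["GLRLM long run emphasis"]],
            glrlm_features(da)[["GLRLM long run emphasis"]])
})

test_that("GLSZM features: single zone, hand-enumerated plates, singletons", {
  z <- glszm_features(const_roi())
  expect_equal(z[["GLSZM zone percentage"]], 1 / 27)

  # two 2x2x1 plates of level 1 separated by a level-2 slab: 3 zones
  lev <- array(0L, c(2, 2, 3))
  lev[, , 1] <- 1L; lev[, , 2] <- 2L; lev[, , 3] <- 1L
  zones <- ichradiomics:::cpp_glszm_zones(as.integer(lev), dim(lev))
  zones <- zones[order(zones[, 1], zones[, 2]), ]
  expect_equal(nrow(zones), 3)
  expect_equal(zones[, 1], c(1L, 1L, 2L))
  expect_equal(zones[, 2], c(4L, 4L, 4L))

  # all-singleton pattern (26-connectivity merges diagonal neighbours, so
  # use isolated voxels): small zone emphasis is exactly 1
  lev3 <- array(0L, c(5, 1, 1)); lev3[c(1, 3, 5)] <- c(1L, 2L, 1L)
  d3 <- structure(list(levels = lev3, Ng = 2L, Ng_effective = 2L,
                       bin_edges = 0:2, values = c(1, 2, 1),
                       spacing = c(1, 1, 1)), class = "discretised_roi")
  expect_equal(glszm_features(d3)[["GLSZM small zone emphasis"]], 1)
})

test_that("NGTDM features: zero on constants, hand table, coarseness ordering", {
  nf <- ngtdm_features(const_roi())
  expect_equal(unname(nf[c("NGTDM contrast", "NGTDM complexity")]), c(0, 0))

  # 3x3x1 grid, centre level 2 amid level 1: s_2 = 1, s_1 = 4/3 + 4/5
  lev <- array(1L, c(3, 3, 1)); lev[2, 2, 1] <- 2L
  st <- ichradiomics:::cpp_ngtdm(as.integer(lev), dim(lev), 2L)
  expect_equal(st[, 1], c(8, 1))
  expect_equal(st[2, 2], 1)
  expect_equal(st[1, 2], 4 * (1 / 3) + 4 * (1 / 5))

  # coarseness decreases as checkerboard frequency increases
  mk <- function(period) {
    idx <- as.matrix(expand.grid(1:8, 1:8, 1:8))
    lev <- array(as.integer(1 + (rowSums(floor((idx - 1) / period)) %% 2)),
                 c(8, 8, 8))
    structure(list(levels = lev, Ng = 2L, Ng_effective = 2L, bin_edges = 0:2,
                   values = as.numeric(lev), spacing = c(1, 1, 1)),
              class = "discretised_roi")
  }
  expect_gt(ngtdm_features(mk(4))[["NGTDM coarseness"]],
            ngtdm_features(mk(1))[["NGTDM coarseness"]])
})

test_that("texture families agree with naive brute-force builders on random ROIs", {
  for (seed in 1:12) {
    d <- random_roi(seed)
    lev <- d$levels; ng <- d$Ng
    expect_equal(unname(glcm_features(d)),
                 unname(oracle_glcm_features(lev, ng)), tolerance = 1e-10)
    expect_equal(unname(glrlm_features(d)),
                 unname(oracle_glrlm_features(lev, ng)), tolerance = 1e-10)
    expect_equal(unname(glszm_features(d)),
                 unname(oracle_glszm_features(lev, ng)), tolerance = 1e-10)
    expect_equal(unname(ngtdm_features(d)),
                 unname(oracle_ngtdm_features(lev, ng)), tolerance = 1e-10)
  }
})
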