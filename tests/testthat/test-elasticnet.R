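test_that("penalty limits: lasso null model and non-sparsifying ridge", {
  set.seed(51)
  n <- 300; p <- 10
  X <- matrix(rnorm(n * p), n, p)
  y <- rbinom(n, 1, 0.3)
  Xs <- scale(X)
  lmax <- max(abs(crossprod(Xs, y - mean(y)))) / n
  m <- fit_elastic_net(X, y, alpha = 1, lambda = lmax * 1.0001)
  expect_true(all(m$coefficients == 0))
  expect_equal(m$intercept, qlogis(mean(y)), tolerance = 1e-8)

  m0 <- fit_elastic_net(X, y, alpha = 0, lambda = 0.05)
  expect_true(all(m0$coefficients != 0))

  expect_error(fit_elastic_net(X, rep(1, n), 0.5, 0.1), "single class")
  expect_error(fit_elastic_net(X, y, 0.5, -1), "lambda")
})

test_that("a vanishing penalty recovers the maximum-likelihood fit", {
  set.seed(52)
  n <- 500; p <- 5
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  y <- rbinom(n, 1, plogis(0.8 * X[, 1] - 0.5 * X[, 2]))
  m <- fit_elastic_net(X, y, alpha = 0.5, lambda = 1e-8)
  mle <- glm(y ~ scale(X), family = binomial)
  expect_lt(max(abs(m$coefficients - coef(mle)[-1])), 1e-3)
})

test_that("probability predictions invert the link and respect monotonicity", {
  set.seed(53)
  n <- 200
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(n, 1, plogis(X[, 1]))
  m <- fit_elastic_net(X, y, alpha = 0.5, lambda = 0.01)
  pr <- predict_probability(m, X)
  lin <- m$intercept +
    sweep(sweep(X, 2, m$center, `-`), 2, m$scale, `/`) %*% m$coefficients
  expect_lt(max(abs(qlogis(pr) - lin)), 1e-12)
  # increasing a positive-coefficient feature never decreases the probability
  j <- which(m$coefficients > 0)[1]
  X2 <- X; X2[, j] <- X2[, j] + 1
  expect_true(all(predict_probability(m, X2) >= pr - 1e-12))
  expect_error(predict_probability(m, X[, 1:2]), "missing feature")
})

test_that("importance percentages reproduce printed model coefficients", {
  # the seven nonzero haematoma-expansion model coefficients
  b <- c("LoG-35 interquartile range" = -0.28305,
         "LoG-15 GLSZM grey level non-uniformity" = 0.10061,
         "Intensities GLSZM small zone emphasis" = -0.09417,
         "Intracerebral haemorrhage major axis length" = 0.06405,
         "LoG-25 mean absolute deviation" = -0.02980,
         "LoG-25 kurtosis" = 0.02967,
         "Intensities 10th percentile" = 0.01588)
  imp <- variable_importance(b)
  expect_equal(round(unname(imp[1]), 1), 45.9)
  expect_equal(round(unname(imp[3]), 1), 15.3)
  expect_equal(names(imp)[1], "LoG-35 interquartile range")
  expect_lt(abs(sum(imp) - 100), 0.05)
  expect_equal(unname(variable_importance(c(z = 0.7, w = 0))), 100)
  expect_error(variable_importance(c(0, 0)), "all coefficients")
})

test_that("the lasso active set shrinks as lambda grows", {
  set.seed(54)
  n <- 300; p <- 15
  X <- matrix(rnorm(n * p), n, p)
  y <- rbinom(n, 1, plogis(X[, 1] - X[, 2] + 0.5 * X[, 3]))
  Xs <- scale(X)
  lmax <- max(abs(crossprod(Xs, y - mean(y)))) / n
  path <- exp(seq(log(lmax), log(lmax * 1e-3), length.out = 20))
  sizes <- vapply(path, function(l)
    sum(fit_elastic_net(X, y, 1, l)$coefficients != 0), numeric(1))
  expect_true(all(diff(sizes) >= 0))  # path is decreasing in lambda
})

test_that("grid search is deterministic and calibrated on null data", {
  set.seed(55)
  X <- matrix(rnorm(300 * 20), 300, 20)
  y <- rbinom(300, 1, 0.5)
  g1 <- cv_grid_search(X, y, alphas = c(0, 0.5, 1), k = 5, seed = 99)
  g2 <- cv_grid_search(X, y, alphas = c(0, 0.5, 1), k = 5, seed = 99)
  expect_identical(g1$records, g2$records)
  expect_identical(g1$selected, g2$selected)
  expect_error(cv_grid_search(X[1:12, ], y[1:12], k = 10), "fewer than k")
})
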