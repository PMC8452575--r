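sim_batches <- function(seed = 31, n_per = 200, p = 20,
                        shift = c(0, 5, 5), scale = c(1, 1, 1)) {
  set.seed(seed)
  n <- 3 * n_per
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("f", seq_len(p))
  batch <- rep(1:3, each = n_per)
  age <- rnorm(n, 69, 13)
  gender <- sample(c("male", "female"), n, replace = TRUE)
  list(X = inject_batch_effects(X, batch, shift, scale), batch = batch,
       covars = data.frame(age = age, gender = gender))
}

test_that("slice-thickness batches follow the half-open intervals", {
  expect_equal(assign_batch(c(1, 1.99, 2, 3.99, 4, 5)),
               c(1L, 1L, 2L, 2L, 3L, 3L))
  expect_error(assign_batch(0), "positive")
})

test_that("an injected location shift is removed and covariates preserved", {
  s <- sim_batches(31, shift = c(0, 5, -5))
  pre <- mean(abs(colMeans(s$X[s$batch == 2, ]) - colMeans(s$X[s$batch == 1, ])))
  expect_gt(pre, 4)
  fit <- combat_fit(s$X, s$batch, s$covars)
  post <- mean(abs(colMeans(fit$harmonised[s$batch == 2, ]) -
                   colMeans(fit$harmonised[s$batch == 1, ])))
  expect_lt(post, 0.1)

  # batch mixing collapses after harmonisation
  expect_gt(batch_mixing_score(s$X, s$batch), 0.5)
  expect_lt(batch_mixing_score(fit$harmonised, s$batch),
            batch_mixing_score(s$X, s$batch))

  # covariate structure survives: age slope on a feature with a real age
  # effect is recovered within its confidence interval
  set.seed(32)
  s2 <- sim_batches(32, shift = c(0, 3, -3))
  X2 <- s2$X
  X2[, 1] <- X2[, 1] + 0.05 * s2$covars$age
  fit2 <- combat_fit(X2, s2$batch, s2$covars)
  sl <- summary(lm(fit2$harmonised[, 1] ~ s2$covars$age + s2$covars$gender))
  est <- sl$coefficients["s2$covars$age", 1:2]
  expect_lt(abs(est[1] - 0.05), 1.96 * est[2] + 1e-6)
})

test_that("train-then-apply semantics are strict and serialisable", {
  s <- sim_batches(33, shift = c(0, 5, -5))
  fit <- combat_fit(s$X, s$batch, s$covars)
  # applying to the training table reproduces the fit output
  ap <- combat_apply(fit$model, s$X, s$batch, s$covars)
  expect_lt(max(abs(ap - fit$harmonised)), 1e-10)
  # held-out subjects from the same batch system land near the pooled mean
  s_new <- sim_batches(34, n_per = 200, shift = c(0, 5, -5))
  ap_new <- combat_apply(fit$model, s_new$X, s_new$batch, s_new$covars)
  resid_shift <- mean(abs(colMeans(ap_new[s_new$batch == 2, ]) -
                          colMeans(ap_new[s_new$batch == 1, ])))
  expect_lt(resid_shift, 0.15)
  expect_error(combat_apply(fit$model, s$X, rep(4, nrow(s$X)), s$covars),
               "unseen batch")
  # JSON round trip preserves the adjustment exactly
  tf <- withr::local_tempfile(fileext = ".json")
  combat_model_to_json(fit$model, tf)
  m2 <- combat_model_from_json(tf)
  expect_lt(max(abs(combat_apply(m2, s$X, s$batch, s$covars) - ap)), 1e-10)
})

test_that("degenerate inputs: single batch is identity, constants rejected", {
  set.seed(35)
  X <- matrix(rnorm(100 * 5), 100, 5)
  f1 <- combat_fit(X, rep(1, 100), data.frame(age = rnorm(100, 69, 13)))
  expect_lt(max(abs(f1$harmonised - X)), 1e-6)

  Xc <- cbind(X, konst = 1)
  expect_error(combat_fit(Xc, rep(1:2, 50), NULL), "zero-variance")
  expect_error(combat_fit(X, c(1, rep(2, 99)), NULL), "singleton")

  # re-harmonising changes little and the map is contractive: once batch
  # effects are gone, only residual empirical-Bayes shrinkage of sampling
  # noise remains, and it decays with every pass
  s <- sim_batches(36, shift = c(0, 2, -2))
  h1 <- combat_fit(s$X, s$batch, s$covars)$harmonised
  h2 <- combat_fit(h1, s$batch, s$covars)$harmonised
  h3 <- combat_fit(h2, s$batch, s$covars)$harmonised
  d12 <- mean(abs(h2 - h1)) / stats::sd(h1)
  d23 <- mean(abs(h3 - h2)) / stats::sd(h2)
  expect_lt(d12, 0.05)
  expect_lt(d23, d12)
})

test_that("harmonisation agrees with the reference empirical-Bayes implementation", {
  s <- sim_batches(37, n_per = 50, p = 30, shift = c(0, 2, -1),
                   scale = c(1, 1.5, 0.8))
  mod <- stats::model.matrix(~ age + gender, data = s$covars)
  ref <- t(suppressMessages(sva::ComBat(dat = t(s$X), batch = s$batch,
                                        mod = mod, par.prior = TRUE)))
  ours <- combat_fit(s$X, s$batch, s$covars)$harmonised
  expect_lt(max(abs(ref - ours)), 1e-4)
})

test_that("batch mixing score behaves like a silhouette", {
  set.seed(38)
  X <- rbind(matrix(rnorm(100 * 5, 0), 100, 5),
             matrix(rnorm(100 * 5, 8), 100, 5),
             matrix(rnorm(100 * 5, -8), 100, 5))
  b <- rep(1:3, each = 100)
  expect_gt(batch_mixing_score(X, b), 0.5)
  expect_lt(abs(batch_mixing_score(X, sample(b))), 0.05)
  expect_error(batch_mixing_score(X, rep(1, 300)), ">= 2 batches")
})
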