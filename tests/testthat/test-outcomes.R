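test_that("outcome labels follow the clinical definitions", {
  expect_true(label_haematoma_expansion(10, 17))    # +7 mL
  expect_true(label_haematoma_expansion(9, 12.1))   # +34.4%
  expect_false(label_haematoma_expansion(10, 13))   # +3 mL, +30%
  expect_false(label_haematoma_expansion(100, 106)) # boundary: not strictly > 6
  expect_error(label_haematoma_expansion(0, 5), "zero baseline")
  expect_error(label_haematoma_expansion(-1, 5), "non-negative")

  expect_equal(label_poor_outcome(c(0, 3, 4, 6)), c(FALSE, FALSE, TRUE, TRUE))
  expect_error(label_poor_outcome(7), "0..6")

  expect_equal(ultra_early_growth(12, 2), 6)
  expect_equal(ultra_early_growth(0, 5), 0)
  expect_equal(ultra_early_growth(20.88, 1.73), 12.069, tolerance = 1e-3)
  expect_error(ultra_early_growth(5, 0), "positive")
})

test_that("matched split balances age and gender at the requested fraction", {
  set.seed(61)
  cohort <- data.frame(age = rnorm(1000, 69, 13),
                       gender = sample(c("male", "female"), 1000, TRUE))
  out <- rbinom(1000, 1, 0.3)
  sp <- matched_split(cohort, 0.7, seed = 61, outcome = out)
  expect_lt(abs(length(sp$train) / 1000 - 0.7), 0.02)
  expect_gt(sp$p_age, 0.05)
  expect_gt(sp$p_gender, 0.05)
  expect_setequal(c(sp$train, sp$test), 1:1000)
  sp2 <- matched_split(cohort, 0.7, seed = 61, outcome = out)
  expect_identical(sp$train, sp2$train)
  expect_error(matched_split(cohort[1:5, ], 0.7, 1), "too small")
})

test_that("AUC matches exhaustive pair counting and the worked example", {
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))$auc, 1.0)
  expect_equal(roc_auc(rep(0.4, 10), rep(c(0, 1), 5))$auc, 0.5)
  set.seed(62)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    sc <- round(runif(n), 1)  # rounding forces ties
    lb <- c(0, 1, rbinom(n - 2, 1, 0.5))
    expect_equal(roc_auc(sc, lb)$auc, oracle_auc(sc, lb))
  }
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
})

test_that("AUC confidence interval matches the reference DeLong implementation", {
  set.seed(63)
  sc <- rnorm(150); lb <- rbinom(150, 1, plogis(sc))
  r <- roc_auc(sc, lb)
  ref <- as.numeric(pROC::ci.auc(pROC::roc(lb, sc, quiet = TRUE),
                                 method = "delong"))
  expect_lt(abs(r$auc - ref[2]), 1e-10)
  expect_lt(max(abs(r$ci - ref[c(1, 3)])), 1e-6)
})

test_that("Youden threshold equals exhaustive search", {
  # perfectly separated scores: lowest candidate in the gap attains J = 1
  r <- roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(youden_threshold(r), 6.5)
  # degenerate all-ties scores: J = 0
  rt <- roc_auc(rep(1, 8), rep(c(0, 1), 4))
  expect_equal(max(rt$curve$sensitivity + rt$curve$specificity - 1), 0)
  set.seed(64)
  for (i in 1:50) {
    n <- sample(6:25, 1)
    sc <- round(rnorm(n), 1)
    lb <- c(0, 1, rbinom(n - 2, 1, 0.4))
    expect_equal(youden_threshold(roc_auc(sc, lb)), oracle_youden(sc, lb))
  }
})

test_that("metric report reproduces printed Wald intervals and is consistent", {
  # prevalence 137/521 -> 0.263 (0.225-0.301)
  lb <- c(rep(1, 137), rep(0, 384))
  sc <- lb
  mr <- metric_report(sc, lb, 0.5)
  expect_equal(round(mr$prevalence, 3), 0.263)
  expect_equal(round(mr$prevalence_ci, 3), c(0.225, 0.301))
  # sensitivity 87/137 = 0.635 -> CI (0.554-0.716)
  sc2 <- c(rep(1, 87), rep(0, 50), rep(0, 384))
  mr2 <- metric_report(sc2, lb, 0.5)
  expect_equal(round(mr2$sensitivity, 3), 0.635)
  expect_equal(round(mr2$sensitivity_ci, 3), c(0.554, 0.716))
  # internal consistency: PPV * (TP + FP) == sens * P
  cts <- mr2$counts
  expect_equal(mr2$ppv * (cts["tp"] + cts["fp"]),
               mr2$sensitivity * (cts["tp"] + cts["fn"]),
               ignore_attr = TRUE)
  # perfect classifier: all metrics 1, CIs clipped at 1
  mp <- metric_report(c(rep(1, 10), rep(0, 10)), c(rep(1, 10), rep(0, 10)), 0.5)
  expect_equal(c(mp$sensitivity, mp$specificity, mp$ppv, mp$npv),
               c(1, 1, 1, 1))
  expect_lte(max(mp$sensitivity_ci), 1)
  # empty PPV denominator reported as undefined, not 0
  mu <- metric_report(c(0.1, 0.2, 0.3, 0.4), c(0, 1, 0, 1), 0.9)
  expect_true(is.na(mu$ppv))
})

test_that("threshold analysis evaluates the F-beta family correctly", {
  sc <- c(1, 2, 3, 10, 11, 12); lb <- c(0, 0, 0, 1, 1, 1)
  ta <- threshold_analysis(sc, lb)
  row <- ta[ta$threshold == 6.5, ]
  expect_equal(c(row$f1, row$f05, row$f2), c(1, 1, 1))
  # PPV = 0.5, sens = 1: F1 = 2/3, F2 = 5/6
  sc2 <- c(0.9, 0.9, 0.1, 0.1); lb2 <- c(1, 0, 1, 0)
  ta2 <- threshold_analysis(sc2, lb2)
  r2 <- ta2[which.min(ta2$threshold), ]  # everything classified positive
  expect_equal(r2$sensitivity, 1)
  expect_equal(r2$f1, 2 / 3, tolerance = 1e-12)
  expect_equal(r2$f2, 5 / 6, tolerance = 1e-12)
})
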