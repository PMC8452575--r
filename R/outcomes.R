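# Outcome definitions, matched train/test split, and ROC / threshold
# evaluation with confidence intervals.

#' Haematoma expansion label
#'
#' Expansion is volumetric growth of more than 6 mL absolute or more than
#' 33% relative to baseline on the follow-up scan (strict inequalities).
#'
#' @param v0 baseline haematoma volume (mL), strictly positive.
#' @param v24 follow-up haematoma volume (mL), non-negative.
#' @return logical vector.
#' @export
label_haematoma_expansion <- function(v0, v24) {
  if (any(v0 < 0) || any(v24 < 0)) stop("volumes must be non-negative")
  if (any(v0 == 0)) stop("zero baseline volume: relative growth undefined")
  (v24 - v0) > 6 | (v24 - v0) / v0 > 0.33
}

#' Poor functional outcome label
#'
#' Modified Rankin scale 4-6 at day 90.
#'
#' @param mrs integer scores in 0..6 (NA allowed, propagated).
#' @return logical vector.
#' @export
label_poor_outcome <- function(mrs) {
  ok <- is.na(mrs) | (mrs %in% 0:6)
  if (!all(ok)) stop("mRS scores must be integers in 0..6")
  mrs >= 4
}

#' Ultra-early haematoma growth
#'
#' Baseline haematoma volume divided by the time from symptom onset to the
#' baseline scan.
#'
#' @param v0 baseline volume (mL).
#' @param t onset-to-scan time (hours), strictly positive.
#' @return growth rate in mL/h.
#' @export
ultra_early_growth <- function(v0, t) {
  if (any(t <= 0)) stop("onset-to-scan time must be positive")
  v0 / t
}

#' Age- and gender-matched stratified train/test split
#'
#' Subjects are assigned by a stratified draw within
#' gender x age-quintile (x outcome, when given) cells; the draw is
#' re-attempted (at most `max_attempts` times) until the sets are matched on
#' age (two-sided rank-sum p > .05) and gender (chi-square p > .05).
#'
#' @param cohort data.frame with `age` and `gender` columns.
#' @param train_fraction fraction assigned to training (default 0.7).
#' @param seed integer seed; the split is a pure function of cohort + seed.
#' @param outcome optional binary vector used as an extra stratification
#'   variable so prevalence is balanced too.
#' @param max_attempts acceptance-loop bound (default 100).
#' @return list with integer index vectors `train` and `test` and the
#'   achieved matching p-values.
#' @export
matched_split <- function(cohort, train_fraction = 0.7, seed = 1L,
                          outcome = NULL, max_attempts = 100L) {
  if (nrow(cohort) < 20) stop("matched_split: cohort too small (< 20)")
  if (anyNA(cohort$age) || anyNA(cohort$gender))
    stop("matched_split: age and gender must be present for all subjects")
  qs <- unique(stats::quantile(cohort$age, seq(0, 1, 0.2)))
  age_bin <- cut(cohort$age, breaks = qs, include.lowest = TRUE)
  cell <- interaction(cohort$gender, age_bin, drop = TRUE)
  if (!is.null(outcome)) cell <- interaction(cell, outcome, drop = TRUE)
  set.seed(seed)
  for (attempt in seq_len(max_attempts)) {
    train <- logical(nrow(cohort))
    for (lv in levels(cell)) {
      idx <- which(cell == lv)
      n_tr <- round(length(idx) * train_fraction)
      train[sample(idx, n_tr)] <- TRUE
    }
    if (sum(train) < 2 || sum(!train) < 2) next
    p_age <- suppressWarnings(
      stats::wilcox.test(cohort$age[train], cohort$age[!train],
                         exact = FALSE)$p.value)
    tab <- table(factor(train, c(FALSE, TRUE)), cohort$gender)
    p_gender <- if (ncol(tab) < 2) 1 else
      suppressWarnings(stats::chisq.test(tab)$p.value)
    if (p_age > 0.05 && p_gender > 0.05)
      return(list(train = which(train), test = which(!train),
                  p_age = p_age, p_gender = p_gender, attempts = attempt))
  }
  stop("matched_split: matching unattainable in ", max_attempts, " attempts")
}

# Mann-Whitney AUC with tie correction (average ranks).
.auc_rank <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("roc_auc: both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong variance of the AUC estimate.
.auc_delong_se <- function(scores, labels) {
  x <- scores[labels == 1]; y <- scores[labels == 0]
  m <- length(x); n <- length(y)
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  V10 <- vapply(x, function(xi) mean(psi(xi, y)), numeric(1))
  V01 <- vapply(y, function(yj) mean(psi(x, yj)), numeric(1))
  s10 <- if (m > 1) stats::var(V10) else 0
  s01 <- if (n > 1) stats::var(V01) else 0
  sqrt(s10 / m + s01 / n)
}

#' ROC curve, AUC and 95% confidence interval
#'
#' AUC uses the rank (Mann-Whitney) formulation with tie correction; the CI
#' uses the DeLong variance estimate with a normal approximation, clipped to
#' [0, 1]. Candidate thresholds are the unique scores and the midpoints
#' between consecutive unique scores; classification is positive at
#' `score >= threshold`.
#'
#' @param scores numeric classifier scores.
#' @param labels binary labels (0/1), both classes present.
#' @return object of class `roc_result`: `curve` (data.frame of threshold,
#'   sensitivity, specificity), `auc`, `ci` (length-2).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  auc <- .auc_rank(scores, labels)
  se <- .auc_delong_se(scores, labels)
  ci <- pmin(pmax(auc + c(-1, 1) * stats::qnorm(0.975) * se, 0), 1)
  u <- sort(unique(scores))
  thr <- sort(unique(c(u, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2)))
  P <- sum(labels == 1); N <- sum(labels == 0)
  sens <- vapply(thr, function(t) sum(scores >= t & labels == 1) / P, numeric(1))
  spec <- vapply(thr, function(t) sum(scores < t & labels == 0) / N, numeric(1))
  structure(list(curve = data.frame(threshold = thr, sensitivity = sens,
                                    specificity = spec),
                 auc = auc, ci = ci, scores = scores, labels = labels),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> AUC ", round(x$auc, 3), " (95% CI ",
      round(x$ci[1], 3), "-", round(x$ci[2], 3), ")\n", sep = "")
  invisible(x)
}

#' Youden-optimal threshold
#'
#' The candidate threshold maximising Youden's index
#' (sensitivity + specificity - 1); ties return the lowest such threshold.
#'
#' @param roc a `roc_result` from [roc_auc()].
#' @return scalar threshold.
#' @export
youden_threshold <- function(roc) {
  j <- roc$curve$sensitivity + roc$curve$specificity - 1
  # numerically tied maxima resolve to the lowest threshold
  roc$curve$threshold[which(j >= max(j) - 1e-12)[1]]
}

.wald_ci <- function(p, n) {
  if (n == 0) return(c(NA_real_, NA_real_))
  half <- 1.96 * sqrt(p * (1 - p) / n)
  pmin(pmax(p + c(-1, 1) * half, 0), 1)
}

#' Threshold performance report with 95% confidence intervals
#'
#' Confusion counts at `score >= threshold`; sensitivity, specificity, PPV,
#' NPV and prevalence as proportions with Wald 95% CIs
#' (`p +/- 1.96 sqrt(p(1-p)/n)`, n the metric's own denominator), clipped to
#' [0, 1]. Metrics with an empty denominator are reported as NA (undefined),
#' not 0. The AUC and its DeLong CI are included.
#'
#' @param scores classifier scores.
#' @param labels binary labels (0/1).
#' @param threshold decision threshold.
#' @return object of class `metric_report` (list of point estimates and CI
#'   pairs, plus the confusion counts).
#' @export
metric_report <- function(scores, labels, threshold) {
  labels <- as.numeric(labels)
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1); tn <- sum(!pred & labels == 0)
  P <- tp + fn; N <- fp + tn; n <- P + N
  roc <- roc_auc(scores, labels)
  sens <- tp / P; spec <- tn / N
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  prev <- P / n
  structure(list(
    threshold = threshold,
    auc = roc$auc, auc_ci = roc$ci,
    sensitivity = sens, sensitivity_ci = .wald_ci(sens, P),
    specificity = spec, specificity_ci = .wald_ci(spec, N),
    ppv = ppv, ppv_ci = if (is.na(ppv)) c(NA, NA) else .wald_ci(ppv, tp + fp),
    npv = npv, npv_ci = if (is.na(npv)) c(NA, NA) else .wald_ci(npv, tn + fn),
    prevalence = prev, prevalence_ci = .wald_ci(prev, n),
    counts = c(tp = tp, fp = fp, fn = fn, tn = tn)),
    class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  fmt <- function(p, ci) sprintf("%.3f (%.3f-%.3f)", p, ci[1], ci[2])
  cat("<metric_report> threshold ", signif(x$threshold, 4), "\n",
      "  AUC         ", fmt(x$auc, x$auc_ci), "\n",
      "  Sensitivity ", fmt(x$sensitivity, x$sensitivity_ci), "\n",
      "  Specificity ", fmt(x$specificity, x$specificity_ci), "\n",
      "  PPV         ", fmt(x$ppv, x$ppv_ci), "\n",
      "  NPV         ", fmt(x$npv, x$npv_ci), "\n",
      "  Prevalence  ", fmt(x$prevalence, x$prevalence_ci), "\n", sep = "")
  invisible(x)
}

#' Threshold analysis table
#'
#' Sensitivity, specificity, Youden's J and the F-beta family (F1, F0.5, F2;
#' `F_beta = (1 + beta^2) PPV sens / (beta^2 PPV + sens)`) over all candidate
#' thresholds. Cells whose denominator is empty are reported as NA.
#'
#' @param scores classifier scores.
#' @param labels binary labels (0/1).
#' @return data.frame with one row per candidate threshold.
#' @export
threshold_analysis <- function(scores, labels) {
  roc <- roc_auc(scores, labels)
  labels <- as.numeric(labels)
  out <- roc$curve
  out$youden_j <- out$sensitivity + out$specificity - 1
  fbeta <- function(ppv, sens, beta) {
    den <- beta^2 * ppv + sens
    ifelse(is.na(ppv) | den == 0, NA_real_,
           (1 + beta^2) * ppv * sens / den)
  }
  ppv <- vapply(out$threshold, function(t) {
    pp <- sum(scores >= t)
    if (pp == 0) NA_real_ else sum(scores >= t & labels == 1) / pp
  }, numeric(1))
  out$f1 <- fbeta(ppv, out$sensitivity, 1)
  out$f05 <- fbeta(ppv, out$sensitivity, 0.5)
  out$f2 <- fbeta(ppv, out$sensitivity, 2)
  out
}
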