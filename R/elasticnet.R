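# Elastic-net penalised logistic regression with cross-validated AUC
# hyperparameter selection. Penalised fits are delegated to glmnet; the
# surrounding standardisation, lambda-path construction, stratified
# cross-validation and AUC-based selection implement the study design.

.check_binary <- function(y) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("outcome must be coded 0/1")
  if (length(unique(y)) < 2) stop("outcome has a single class")
  y
}

.lambda_max <- function(Xs, y, alpha) {
  n <- nrow(Xs)
  max(abs(crossprod(Xs, y - mean(y)))) / n / max(alpha, 1e-3)
}

.lambda_path <- function(lmax, nlambda = 100L, min_ratio = 1e-4) {
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = nlambda))
}

#' Fit a penalised logistic model at fixed hyperparameters
#'
#' Minimises mean logistic log-loss plus
#' `lambda * (alpha * ||b||_1 + (1 - alpha)/2 * ||b||_2^2)` on standardised
#' features. Columns with zero standard deviation are excluded before
#' fitting. The stored scaling parameters make training predictions exactly
#' reproducible on raw inputs.
#'
#' @param X subjects x features numeric matrix (raw scale).
#' @param y binary outcome (0/1), both classes present.
#' @param alpha elastic-net blending weight in [0, 1].
#' @param lambda penalty strength (>= 0).
#' @param thresh coordinate-descent convergence tolerance.
#' @return object of class `elastic_net_model`.
#' @export
fit_elastic_net <- function(X, y, alpha, lambda, thresh = 1e-9) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- .check_binary(y)
  if (lambda < 0) stop("fit_elastic_net: lambda must be >= 0")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  keep <- scl > 0
  if (!any(keep)) stop("fit_elastic_net: all features have zero variance")
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, ctr[keep], `-`), 2,
              scl[keep], `/`)
  lmax <- .lambda_max(Xs, y, alpha)
  path <- sort(unique(c(.lambda_path(max(lmax, lambda * 1.001), 30L,
                                     min_ratio = 1e-4),
                        lambda)), decreasing = TRUE)
  path <- path[path >= lambda]
  fit <- glmnet::glmnet(Xs, y, family = "binomial", alpha = alpha,
                        lambda = path, standardize = FALSE, thresh = thresh)
  cf <- as.numeric(coef(fit, s = lambda, exact = TRUE, x = Xs, y = y))
  beta <- setNames(cf[-1], colnames(Xs))
  structure(
    list(alpha = alpha, lambda = lambda, intercept = cf[1],
         coefficients = beta, center = ctr[keep], scale = scl[keep],
         feature_names = colnames(Xs), dropped = colnames(X)[!keep],
         cv_meta = NULL),
    class = "elastic_net_model")
}

#' @export
print.elastic_net_model <- function(x, ...) {
  cat("<elastic_net_model> alpha=", x$alpha, " lambda=", signif(x$lambda, 4),
      "; ", sum(x$coefficients != 0), "/", length(x$coefficients),
      " nonzero coefficients\n", sep = "")
  invisible(x)
}

.stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    if (length(idx) < k)
      stop("cv_grid_search: class ", cl, " has fewer than k = ", k, " subjects")
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Exhaustive alpha-grid search with stratified k-fold CV by AUC
#'
#' For each alpha on the grid a lambda path (`nlambda` log-spaced values
#' spanning 4 decades below the data-driven maximum) is scored by mean
#' out-of-fold AUC under outcome-stratified k-fold cross-validation; the
#' winning `(alpha, lambda)` pair is refitted on the full training data.
#' Ties prefer the larger lambda, then the smaller alpha. Deterministic for
#' a fixed seed.
#'
#' @param X subjects x features matrix.
#' @param y binary outcome (0/1).
#' @param alphas alpha grid (default 0, 0.1, ..., 1).
#' @param k folds (default 10).
#' @param seed fold-assignment seed.
#' @param nlambda,lambda_min_ratio lambda-path resolution and extent.
#' @return object of class `grid_search_result`: per-alpha records
#'   (`best_lambda`, `cv_auc`, `cv_auc_sd`), the selected pair, and the
#'   refitted `elastic_net_model` (with `cv_meta` filled in).
#' @export
cv_grid_search <- function(X, y, alphas = seq(0, 1, by = 0.1), k = 10L,
                           seed = 1L, nlambda = 100L, lambda_min_ratio = 1e-4) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- .check_binary(y)
  fold <- .stratified_folds(y, k, seed)
  scl <- apply(X, 2, stats::sd)
  keep <- scl > 0
  Xk <- X[, keep, drop = FALSE]
  Xs_full <- scale(Xk)
  records <- data.frame(alpha = alphas, best_lambda = NA_real_,
                        cv_auc = NA_real_, cv_auc_sd = NA_real_)
  for (ai in seq_along(alphas)) {
    a <- alphas[ai]
    path <- .lambda_path(.lambda_max(Xs_full, y, a), nlambda, lambda_min_ratio)
    aucs <- matrix(NA_real_, k, length(path))
    for (f in seq_len(k)) {
      tr <- fold != f
      fit <- glmnet::glmnet(Xk[tr, , drop = FALSE], y[tr],
                            family = "binomial", alpha = a, lambda = path,
                            standardize = TRUE, thresh = 1e-7)
      pr <- predict(fit, Xk[!tr, , drop = FALSE], s = path,
                    type = "response")
      aucs[f, ] <- apply(pr, 2, function(s) .auc_rank(s, y[!tr]))
    }
    mean_auc <- colMeans(aucs)
    best <- which(mean_auc == max(mean_auc))[1]  # path is decreasing: first = largest lambda
    records$best_lambda[ai] <- path[best]
    records$cv_auc[ai] <- mean_auc[best]
    records$cv_auc_sd[ai] <- stats::sd(aucs[, best])
  }
  top <- which(records$cv_auc == max(records$cv_auc))
  if (length(top) > 1) {
    top <- top[order(-records$best_lambda[top], records$alpha[top])][1]
  }
  model <- fit_elastic_net(X, y, records$alpha[top], records$best_lambda[top])
  model$cv_meta <- list(folds = k, seed = seed, cv_auc = records$cv_auc[top],
                        cv_auc_sd = records$cv_auc_sd[top])
  structure(list(records = records,
                 selected = list(alpha = records$alpha[top],
                                 lambda = records$best_lambda[top],
                                 cv_auc = records$cv_auc[top]),
                 model = model),
            class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat("<grid_search_result> selected alpha=", x$selected$alpha,
      " lambda=", signif(x$selected$lambda, 4),
      " (CV AUC ", round(x$selected$cv_auc, 3), ")\n", sep = "")
  invisible(x)
}

#' Predict outcome probabilities from a fitted model
#'
#' Standardises raw inputs with the stored training parameters and applies
#' the logistic link.
#'
#' @param model an `elastic_net_model`.
#' @param X_raw matrix or data.frame containing the model's feature columns.
#' @return numeric vector of probabilities in [0, 1].
#' @export
predict_probability <- function(model, X_raw) {
  X <- as.matrix(X_raw)
  if (!is.null(colnames(X))) {
    missing <- setdiff(model$feature_names, colnames(X))
    if (length(missing))
      stop("predict_probability: missing feature columns: ",
           paste(head(missing, 5), collapse = "; "))
    X <- X[, model$feature_names, drop = FALSE]
  } else if (ncol(X) != length(model$feature_names)) {
    stop("predict_probability: wrong number of columns")
  }
  Xs <- sweep(sweep(X, 2, model$center, `-`), 2, model$scale, `/`)
  as.numeric(plogis(model$intercept + Xs %*% model$coefficients))
}

#' Variable importance as normalised absolute coefficients
#'
#' `importance_j = 100 * |b_j| / sum_k |b_k|` over the standardised-scale
#' coefficients, intercept excluded, for features with nonzero coefficients,
#' in descending order.
#'
#' @param model an `elastic_net_model`, or a named numeric vector of
#'   standardised coefficients (intercept excluded).
#' @return named numeric vector of importance percentages.
#' @export
variable_importance <- function(model) {
  b <- if (inherits(model, "elastic_net_model")) model$coefficients
       else model
  if (is.null(names(b))) names(b) <- paste0("f", seq_along(b))
  b <- setNames(as.numeric(b), names(b))
  tot <- sum(abs(b))
  if (tot == 0) stop("variable_importance: all coefficients are zero")
  imp <- 100 * abs(b) / tot
  sort(imp[imp > 0], decreasing = TRUE)
}
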