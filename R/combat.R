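# Empirical-Bayes location-scale batch harmonisation of feature tables,
# with strict train-then-apply semantics: parameters estimated on the
# training table are frozen in a serialisable model and re-used verbatim on
# new data.

#' Assign a slice-thickness batch
#'
#' Batches: (1) thickness < 2 mm; (2) 2 mm <= thickness < 4 mm;
#' (3) thickness >= 4 mm.
#'
#' @param slice_thickness_mm positive scalar or vector of thicknesses (mm).
#' @return integer batch index in \{1, 2, 3\}.
#' @export
assign_batch <- function(slice_thickness_mm) {
  if (any(!is.finite(slice_thickness_mm)) || any(slice_thickness_mm <= 0))
    stop("assign_batch: slice thickness must be positive")
  ifelse(slice_thickness_mm < 2, 1L, ifelse(slice_thickness_mm < 4, 2L, 3L))
}

.combat_design <- function(batch_f, covariates) {
  B <- stats::model.matrix(~ batch_f - 1)
  X <- NULL
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    X <- stats::model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
  }
  cbind(B, X)
}

# Conditional posterior iteration for one batch (parametric EB).
.combat_itsol <- function(z_b, g_hat, d_hat2, g_bar, t2, a_prior, b_prior,
                          tol = 1e-4, maxit = 100L) {
  n <- nrow(z_b)
  g_old <- g_hat
  d_old <- d_hat2
  for (it in seq_len(maxit)) {
    g_new <- if (t2 > 0) (t2 * n * g_hat + d_old * g_bar) / (t2 * n + d_old)
             else g_hat * 0 + g_bar
    sum2 <- colSums(sweep(z_b, 2, g_new, `-`)^2)
    d_new <- (0.5 * sum2 + b_prior) / (n / 2 + a_prior - 1)
    change <- max(abs(g_new - g_old) / (abs(g_old) + 1e-12),
                  abs(d_new - d_old) / (abs(d_old) + 1e-12))
    g_old <- g_new; d_old <- d_new
    if (change < tol) break
  }
  list(gamma_star = g_old, delta2_star = d_old)
}

#' Fit empirical-Bayes batch harmonisation on a training table
#'
#' Per feature: a location-scale model with batch means and (optional)
#' biological covariates is fitted by least squares; data are standardised
#' by the pooled residual scale; per-batch location and scale effects are
#' shrunk towards parametric priors (normal for locations, inverse-gamma for
#' squared scales) whose hyperparameters are estimated by the method of
#' moments; the conditional posterior estimates are iterated to convergence
#' (relative tolerance 1e-4, at most 100 iterations). Adjusted data restore
#' the grand intercept and covariate effects. With a single batch level
#' there is nothing to adjust and the table is returned unchanged (the
#' model records identity parameters).
#'
#' @param train numeric matrix or data.frame, subjects x features.
#' @param batches batch labels, one per subject (each level needs >= 2
#'   subjects).
#' @param covariates optional data.frame of biological covariates to
#'   preserve (typically age and gender).
#' @param eb use empirical-Bayes shrinkage (default TRUE).
#' @return list with `model` (a `combat_model`) and `harmonised` (matrix).
#' @export
combat_fit <- function(train, batches, covariates = NULL, eb = TRUE) {
  Y <- as.matrix(train)
  storage.mode(Y) <- "double"
  n <- nrow(Y); p <- ncol(Y)
  if (length(batches) != n) stop("combat_fit: batches length mismatch")
  batch_f <- factor(batches)
  levs <- levels(batch_f)
  counts <- table(batch_f)
  if (any(counts < 2)) stop("combat_fit: singleton batch level(s): ",
                            paste(names(counts)[counts < 2], collapse = ", "))
  sds <- apply(Y, 2, stats::sd)
  if (any(sds == 0))
    stop("combat_fit: zero-variance feature(s): ",
         paste(colnames(Y)[sds == 0], collapse = "; "))
  if (length(levs) == 1L) {
    model <- structure(list(trivial = TRUE, batch_levels = levs,
                            feature_names = colnames(Y),
                            covariate_names = colnames(as.data.frame(covariates))),
                       class = "combat_model")
    return(list(model = model, harmonised = Y))
  }
  D <- .combat_design(batch_f, covariates)
  n_cov <- ncol(D) - length(levs)
  beta <- solve(crossprod(D), crossprod(D, Y))
  resid <- Y - D %*% beta
  sigma2 <- colSums(resid^2) / n
  if (any(sigma2 <= 0)) stop("combat_fit: zero pooled residual variance")
  w <- as.numeric(counts[levs]) / n
  alpha <- as.numeric(w %*% beta[seq_along(levs), , drop = FALSE])
  cov_part <- if (n_cov > 0)
    D[, -(seq_along(levs)), drop = FALSE] %*%
      beta[-(seq_along(levs)), , drop = FALSE]
  else matrix(0, n, p)
  Z <- (Y - matrix(alpha, n, p, byrow = TRUE) - cov_part) /
    matrix(sqrt(sigma2), n, p, byrow = TRUE)
  gamma_star <- delta2_star <- matrix(NA_real_, length(levs), p)
  priors <- list()
  for (b in seq_along(levs)) {
    idx <- which(batch_f == levs[b])
    z_b <- Z[idx, , drop = FALSE]
    g_hat <- colMeans(z_b)
    d_hat2 <- apply(z_b, 2, stats::var)
    g_bar <- mean(g_hat); t2 <- stats::var(g_hat)
    m <- mean(d_hat2); s2 <- stats::var(d_hat2)
    if (eb && is.finite(s2) && s2 > 1e-12) {
      a_prior <- (2 * s2 + m^2) / s2
      b_prior <- (m * s2 + m^3) / s2
      sol <- .combat_itsol(z_b, g_hat, d_hat2, g_bar, t2, a_prior, b_prior)
      gamma_star[b, ] <- sol$gamma_star
      delta2_star[b, ] <- sol$delta2_star
      priors[[levs[b]]] <- list(gamma_bar = g_bar, tau2 = t2,
                                a = a_prior, b = b_prior)
    } else {
      gamma_star[b, ] <- g_hat
      delta2_star[b, ] <- d_hat2
      priors[[levs[b]]] <- list(gamma_bar = g_bar, tau2 = t2, a = NA, b = NA)
    }
  }
  model <- structure(
    list(trivial = FALSE, batch_levels = levs,
         feature_names = colnames(Y),
         covariate_names = colnames(as.data.frame(covariates)),
         alpha = alpha, beta_cov = if (n_cov > 0)
           beta[-(seq_along(levs)), , drop = FALSE] else NULL,
         sigma = sqrt(sigma2), gamma_star = gamma_star,
         delta_star = sqrt(delta2_star), priors = priors),
    class = "combat_model")
  list(model = model, harmonised = combat_apply(model, Y, batches, covariates))
}

#' Apply a fitted harmonisation model to new data
#'
#' Uses only the stored training parameters; applying the model to its own
#' training table reproduces the fit output. Subjects whose batch level was
#' not seen at fit time are rejected.
#'
#' @param model a `combat_model` from [combat_fit()].
#' @param new subjects x features matrix with the model's feature columns.
#' @param batches batch labels for the new subjects.
#' @param covariates covariates matching the fit design (same columns).
#' @return harmonised matrix.
#' @export
combat_apply <- function(model, new, batches, covariates = NULL) {
  Y <- as.matrix(new)
  storage.mode(Y) <- "double"
  if (!is.null(model$feature_names) && !is.null(colnames(Y)) &&
      !identical(colnames(Y), model$feature_names)) {
    if (!all(model$feature_names %in% colnames(Y)))
      stop("combat_apply: missing feature columns")
    Y <- Y[, model$feature_names, drop = FALSE]
  }
  bad <- setdiff(unique(as.character(batches)), model$batch_levels)
  if (length(bad))
    stop("combat_apply: unseen batch level(s): ", paste(bad, collapse = ", "))
  if (isTRUE(model$trivial)) return(Y)
  n <- nrow(Y); p <- ncol(Y)
  batch_idx <- match(as.character(batches), model$batch_levels)
  cov_part <- matrix(0, n, p)
  if (!is.null(model$beta_cov)) {
    covariates <- as.data.frame(covariates)
    X <- stats::model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
    if (ncol(X) != nrow(model$beta_cov))
      stop("combat_apply: covariate design mismatch")
    cov_part <- X %*% model$beta_cov
  }
  Z <- (Y - matrix(model$alpha, n, p, byrow = TRUE) - cov_part) /
    matrix(model$sigma, n, p, byrow = TRUE)
  G <- model$gamma_star[batch_idx, , drop = FALSE]
  Dl <- model$delta_star[batch_idx, , drop = FALSE]
  Zadj <- (Z - G) / Dl
  Zadj * matrix(model$sigma, n, p, byrow = TRUE) +
    matrix(model$alpha, n, p, byrow = TRUE) + cov_part
}

#' Serialise / restore a harmonisation model as JSON
#'
#' @param model a `combat_model`.
#' @param path output JSON path.
#' @return `path` invisibly ([combat_model_to_json()]); a `combat_model`
#'   ([combat_model_from_json()]).
#' @export
combat_model_to_json <- function(model, path) {
  obj <- unclass(model)
  obj$schema <- "ichradiomics/combat_model"
  obj$schema_version <- 1L
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' @rdname combat_model_to_json
#' @export
combat_model_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "ichradiomics/combat_model"))
    stop("combat_model_from_json: not a combat_model file")
  obj$schema <- NULL; obj$schema_version <- NULL
  for (f in c("gamma_star", "delta_star"))
    if (!is.null(obj[[f]])) obj[[f]] <- as.matrix(obj[[f]])
  if (!is.null(obj$beta_cov)) {
    obj$beta_cov <- matrix(as.numeric(obj$beta_cov),
                           ncol = length(obj$feature_names))
  }
  structure(obj, class = "combat_model")
}

#' Batch-mixing score (silhouette of batch labels)
#'
#' Mean silhouette coefficient of the batch labels computed on standardised
#' features (Euclidean distance). Values near 0 or below indicate well-mixed
#' batches; values towards 1 indicate batch clustering. Serves as the
#' quantitative counterpart of a before/after embedding plot.
#'
#' @param table subjects x features matrix.
#' @param batches batch labels (>= 2 levels).
#' @return scalar in [-1, 1].
#' @export
batch_mixing_score <- function(table, batches) {
  X <- as.matrix(table)
  b <- as.integer(factor(batches))
  if (length(unique(b)) < 2) stop("batch_mixing_score: need >= 2 batches")
  Xs <- scale(X)
  Xs[, !is.finite(colSums(Xs))] <- 0
  sil <- cluster::silhouette(b, stats::dist(Xs))
  mean(sil[, "sil_width"])
}
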