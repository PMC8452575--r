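# Iterative correlation-based redundancy elimination on training features.

#' Iterative correlation filter
#'
#' Repeatedly: compute pairwise absolute Pearson correlations among retained
#' features; if no pair exceeds `cutoff`, stop; otherwise take the pair with
#' the largest absolute correlation (ties broken by the lexicographically
#' first pair in catalogue order) and remove the member with the larger mean
#' absolute correlation to all other currently retained features (ties
#' remove the later-indexed member). Mean correlations are recomputed after
#' every removal. Zero-variance columns are dropped before filtering with a
#' warning. Decided by the training table only; apply the returned ids to
#' subset any test table.
#'
#' @param train subjects x features matrix or data.frame.
#' @param cutoff absolute correlation threshold (default 0.9).
#' @return character vector of retained feature ids, in catalogue order
#'   (column order of `train`).
#' @export
correlation_filter <- function(train, cutoff = 0.9) {
  X <- as.matrix(train)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (ncol(X) < 2) stop("correlation_filter: need at least 2 features")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("correlation_filter: dropping zero-variance feature(s): ",
            paste(colnames(X)[sds == 0], collapse = "; "))
    X <- X[, sds > 0, drop = FALSE]
    if (ncol(X) < 2) return(colnames(X))
  }
  C <- abs(stats::cor(X))
  keep <- seq_len(ncol(X))
  repeat {
    Ck <- C[keep, keep, drop = FALSE]
    diag(Ck) <- 0
    mx <- max(Ck)
    if (mx <= cutoff) break
    hit <- which(Ck == mx, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    a <- keep[hit[1, 1]]; b <- keep[hit[1, 2]]
    mean_abs <- function(j) mean(C[j, setdiff(keep, j)])
    drop_j <- if (mean_abs(a) > mean_abs(b)) a
              else if (mean_abs(b) > mean_abs(a)) b
              else max(a, b)
    keep <- setdiff(keep, drop_j)
    if (length(keep) < 2) break
  }
  colnames(X)[keep]
}
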