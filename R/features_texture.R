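# Grey-level texture families on a discretised ROI. Co-occurrence and
# run-length statistics use the 13 unique 3-D directions at distance 1;
# size-zone and neighbourhood grey-tone statistics use 26-connectivity.

.glcm_stats <- function(P) {
  ng <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P)
  mu_i <- sum(i * P); mu_j <- sum(j * P)
  var_i <- sum((i - mu_i)^2 * P); var_j <- sum((j - mu_j)^2 * P)
  pp <- P[P > 0]
  corr <- if (var_i > 0 && var_j > 0)
    sum((i - mu_i) * (j - mu_j) * P) / sqrt(var_i * var_j) else 1
  c("GLCM contrast" = sum((i - j)^2 * P),
    "GLCM dissimilarity" = sum(abs(i - j) * P),
    "GLCM entropy" = -sum(pp * log2(pp)),
    "GLCM correlation" = corr,
    "GLCM energy" = sum(P^2),
    "GLCM homogeneity" = sum(P / (1 + abs(i - j))),
    "GLCM inverse difference moment" = sum(P / (1 + (i - j)^2)),
    "GLCM cluster shade" = sum((i + j - mu_i - mu_j)^3 * P),
    "GLCM cluster prominence" = sum((i + j - mu_i - mu_j)^4 * P),
    "GLCM autocorrelation" = sum(i * j * P),
    "GLCM maximum probability" = max(P),
    "GLCM joint average" = mu_i)
}

#' Grey-level co-occurrence features
#'
#' Symmetric co-occurrence counts are formed for each of the 13 unique 3-D
#' offsets at distance 1, normalised per direction, averaged over directions
#' that contain at least one in-ROI pair, and summarised by 12 features.
#'
#' @param d a `discretised_roi` from [discretise()].
#' @return named numeric vector of 12 features.
#' @export
glcm_features <- function(d) {
  P <- cpp_glcm(as.integer(d$levels), dim(d$levels), d$Ng)
  if (sum(P) == 0) stop("glcm_features: no in-ROI voxel pairs at distance 1")
  .glcm_stats(P)
}

.glrlm_stats <- function(R, np) {
  # R: ng x maxrun count matrix for one direction
  nr <- sum(R)
  i <- row(R); r <- col(R)
  p <- R / nr
  mu_r <- sum(r * p)
  ri <- rowSums(R)
  c("GLRLM short run emphasis" = sum(R / r^2) / nr,
    "GLRLM long run emphasis" = sum(R * r^2) / nr,
    "GLRLM low grey level run emphasis" = sum(R / i^2) / nr,
    "GLRLM high grey level run emphasis" = sum(R * i^2) / nr,
    "GLRLM short run low grey level emphasis" = sum(R / (i^2 * r^2)) / nr,
    "GLRLM short run high grey level emphasis" = sum(R * i^2 / r^2) / nr,
    "GLRLM long run low grey level emphasis" = sum(R * r^2 / i^2) / nr,
    "GLRLM long run high grey level emphasis" = sum(R * i^2 * r^2) / nr,
    "GLRLM grey level non-uniformity" = sum(ri^2) / nr,
    "GLRLM run length variance" = sum(p * (r - mu_r)^2),
    "GLRLM run percentage" = nr / np)
}

#' Grey-level run-length features
#'
#' Run-length matrices are built per direction (13 unique directions);
#' each feature is computed per direction and averaged.
#'
#' @param d a `discretised_roi`.
#' @return named numeric vector of 11 features.
#' @export
glrlm_features <- function(d) {
  np <- sum(d$levels > 0)
  mats <- cpp_glrlm(as.integer(d$levels), dim(d$levels), d$Ng)
  vals <- lapply(mats, function(R) if (sum(R) > 0) .glrlm_stats(R, np) else NULL)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  if (!length(vals)) stop("glrlm_features: empty ROI")
  Reduce(`+`, vals) / length(vals)
}

#' Grey-level size-zone features
#'
#' Zones are 26-connected components of equal grey level; a single matrix is
#' formed (no directionality).
#'
#' @param d a `discretised_roi`.
#' @return named numeric vector of 10 features.
#' @export
glszm_features <- function(d) {
  np <- sum(d$levels > 0)
  zones <- cpp_glszm_zones(as.integer(d$levels), dim(d$levels))
  if (!nrow(zones)) stop("glszm_features: empty ROI")
  nz <- nrow(zones)
  i <- zones[, 1]; z <- zones[, 2]
  p <- rep(1 / nz, nz)
  gl_counts <- tapply(rep(1, nz), factor(i, levels = 1:d$Ng), sum, default = 0)
  zs_counts <- table(z)
  mu_i <- sum(i * p)
  c("GLSZM small zone emphasis" = mean(1 / z^2),
    "GLSZM large zone emphasis" = mean(z^2),
    "GLSZM grey level non-uniformity" = sum(gl_counts^2) / nz,
    "GLSZM zone size non-uniformity" = sum(as.numeric(zs_counts)^2) / nz,
    "GLSZM small zone low grey level emphasis" = mean(1 / (i^2 * z^2)),
    "GLSZM small zone high grey level emphasis" = mean(i^2 / z^2),
    "GLSZM large zone low grey level emphasis" = mean(z^2 / i^2),
    "GLSZM large zone high grey level emphasis" = mean(i^2 * z^2),
    "GLSZM grey level variance" = sum(p * (i - mu_i)^2),
    "GLSZM zone percentage" = nz / np)
}

#' Neighbourhood grey-tone difference features
#'
#' For each occupied level i, `s_i` sums the absolute difference between i
#' and the mean level of the in-ROI 26-neighbourhood over voxels of level i.
#' When all neighbourhood differences vanish, coarseness is reported as 1e6
#' (its denominator is zero) and the remaining features as 0.
#'
#' @param d a `discretised_roi`.
#' @return named numeric vector of 5 features (coarseness, contrast,
#'   busyness, complexity, strength).
#' @export
ngtdm_features <- function(d) {
  st <- cpp_ngtdm(as.integer(d$levels), dim(d$levels), d$Ng)
  n_i <- st[, 1]; s_i <- st[, 2]
  N <- sum(n_i)
  if (N == 0) stop("ngtdm_features: empty ROI")
  p_i <- n_i / N
  occ <- which(p_i > 0)
  ngp <- length(occ)
  lev <- occ
  pk <- p_i[occ]; sk <- s_i[occ]
  coars <- if (sum(pk * sk) > 0) 1 / sum(pk * sk) else 1e6
  if (ngp > 1) {
    dif2 <- outer(lev, lev, function(a, b) (a - b)^2)
    contrast <- sum(outer(pk, pk) * dif2) / (ngp * (ngp - 1)) * sum(sk) / N
    ipn <- lev * pk
    busy_den <- sum(abs(outer(ipn, ipn, `-`)))
    busy <- if (busy_den > 0) sum(pk * sk) / busy_den else 0
    num <- outer(pk * sk, pk * sk, `+`)
    den <- outer(pk, pk, `+`)
    complexity <- sum(abs(outer(lev, lev, `-`)) * num / den) / N
    strength <- if (sum(sk) > 0) sum(outer(pk, pk, `+`) * dif2) / sum(sk) else 0
  } else {
    contrast <- 0; busy <- 0; complexity <- 0; strength <- 0
  }
  c("NGTDM coarseness" = coars,
    "NGTDM contrast" = contrast,
    "NGTDM busyness" = busy,
    "NGTDM complexity" = complexity,
    "NGTDM strength" = strength)
}
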