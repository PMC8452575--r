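# ROI discretisation and first-order intensity statistics.

#' Discretise an ROI with a fixed bin number
#'
#' Fixed-bin-number discretisation over the ROI intensity range: level k
#' covers `[min + (k-1)w, min + kw)` with `w = range/Ng`; the maximum value
#' maps to level Ng. A constant ROI yields a single effective level.
#'
#' @param vol a [volume_grid] (any filtered image).
#' @param mask a [region_mask] sharing its geometry.
#' @param label ROI label (default 1, intracerebral haemorrhage).
#' @param Ng number of grey levels (default 32).
#' @return object of class `discretised_roi` with elements `levels` (3-D
#'   integer array, 0 outside the ROI), `Ng`, `Ng_effective`, `bin_edges`,
#'   `values` (raw ROI intensities) and `spacing`.
#' @export
discretise <- function(vol, mask, label = 1L, Ng = 32L) {
  if (!identical(dim(vol$data), dim(mask$labels)))
    stop("discretise: volume and mask shapes differ")
  if (Ng < 2) stop("discretise: Ng must be >= 2")
  inroi <- mask$labels == label
  if (!any(inroi)) stop("discretise: empty ROI for label ", label)
  vals <- vol$data[inroi]
  lev <- array(0L, dim(vol$data))
  rng <- range(vals)
  if (rng[2] > rng[1]) {
    w <- (rng[2] - rng[1]) / Ng
    lev[inroi] <- pmin(as.integer(floor((vals - rng[1]) / w)) + 1L, as.integer(Ng))
    edges <- rng[1] + w * (0:Ng)
  } else {
    lev[inroi] <- 1L
    edges <- c(rng[1], rng[1])
  }
  structure(
    list(levels = lev, Ng = as.integer(Ng),
         Ng_effective = length(unique(lev[inroi])),
         bin_edges = edges, values = vals, spacing = vol$spacing),
    class = "discretised_roi")
}

.fo_entropy_uniformity <- function(values, Ng) {
  rng <- range(values)
  if (rng[2] > rng[1]) {
    w <- (rng[2] - rng[1]) / Ng
    lev <- pmin(floor((values - rng[1]) / w) + 1, Ng)
  } else lev <- rep(1, length(values))
  p <- tabulate(lev, nbins = Ng)
  p <- p[p > 0] / length(values)
  c(entropy = -sum(p * log2(p)), uniformity = sum(p^2))
}

#' First-order intensity statistics of an ROI
#'
#' Conventions: population variance; Pearson (non-excess) kurtosis; mean
#' absolute deviation from the mean; robust MAD restricted to values within
#' the 10th-90th percentile band; percentiles by linear interpolation
#' between order statistics; entropy/uniformity on a fixed-bin-number
#' discretisation (Ng levels) of the ROI values. Skewness and kurtosis of a
#' constant ROI are reported as 0.
#'
#' @param values numeric vector of ROI voxel intensities (at least one).
#' @param Ng grey levels for the entropy/uniformity discretisation.
#' @return named numeric vector of 18 features.
#' @export
first_order_features <- function(values, Ng = 32L) {
  if (!length(values)) stop("first_order_features: empty input")
  n <- length(values)
  mu <- mean(values)
  m2 <- mean((values - mu)^2)
  m3 <- mean((values - mu)^3)
  m4 <- mean((values - mu)^4)
  q <- quantile(values, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE, type = 7)
  band <- values[values >= q[1] & values <= q[5]]
  eu <- .fo_entropy_uniformity(values, Ng)
  c("mean" = mu,
    "variance" = m2,
    "standard deviation" = sqrt(m2),
    "minimum" = min(values),
    "maximum" = max(values),
    "median" = q[3],
    "10th percentile" = q[1],
    "90th percentile" = q[5],
    "interquartile range" = q[4] - q[2],
    "range" = max(values) - min(values),
    "mean absolute deviation" = mean(abs(values - mu)),
    "robust mean absolute deviation" = mean(abs(band - mean(band))),
    "energy" = sum(values^2),
    "root mean square" = sqrt(mean(values^2)),
    "skewness" = if (m2 > 0) m3 / m2^1.5 else 0,
    "kurtosis" = if (m2 > 0) m4 / m2^2 else 0,
    "entropy" = unname(eu["entropy"]),
    "uniformity" = unname(eu["uniformity"]))
}
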