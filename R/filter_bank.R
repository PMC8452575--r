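# Filter bank: the 13 derived images (original + 4 LoG scales + 8 stationary
# wavelet subbands) that the feature catalogue is computed from.

.canonical_subbands <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")

.boundary_code <- function(boundary) {
  switch(boundary, reflect = 0L, periodic = 1L,
         stop("unknown boundary mode: ", boundary))
}

# Orthonormal analysis low-pass filters (unit energy, sum sqrt(2)).
.wavelet_filters <- function(name) {
  lo <- switch(name,
    coif1 = c(-0.015655728135791993, -0.07273261951252645, 0.38486484686485778,
              0.85257202021160039, 0.33789766245748182, -0.07273261951252645),
    db2 = c(-0.12940952255126037, 0.22414386804201339, 0.83651630373780794,
            0.48296291314453416),
    sym4 = c(-0.075765714789273325, -0.02963552764599851, 0.49761866763201545,
             0.80373875180591614, 0.29785779560527736, -0.099219543576847216,
             -0.012603967262037833, 0.032223100604042702),
    haar = c(0.70710678118654757, 0.70710678118654757),
    stop("unknown wavelet: ", name))
  n <- length(lo)
  hi <- (-1)^(seq_len(n) - 1) * rev(lo)
  # undecimated (stationary) normalisation: |L|^2 + |H|^2 = 1, sum(lo) = 1,
  # so the LLL subband of a constant equals that constant and the eight
  # subband energies sum to the input energy (periodic boundary).
  list(lo = lo / sqrt(2), hi = hi / sqrt(2))
}

.gauss_kernel <- function(sigma_vox) {
  r <- max(2L, ceiling(4 * sigma_vox))
  x <- seq(-r, r)
  g <- dnorm(x, sd = sigma_vox)
  g / sum(g)
}

# Sampled second derivative of a Gaussian, corrected to exact zero sum so a
# constant input maps to an exactly zero response.
.gauss_d2_kernel <- function(sigma_vox) {
  r <- max(2L, ceiling(4 * sigma_vox))
  x <- seq(-r, r)
  k <- (x^2 - sigma_vox^2) / sigma_vox^4 * dnorm(x, sd = sigma_vox)
  k - mean(k)
}

.conv_sep <- function(arr, kernels, boundary = "reflect") {
  b <- .boundary_code(boundary)
  d <- dim(arr)
  out <- as.numeric(arr)
  for (a in 1:3)
    out <- cpp_conv_axis(out, d, kernels[[a]], a - 1L, b)
  array(out, d)
}

#' Scale-normalised Laplacian-of-Gaussian filter
#'
#' Convolves the volume with a Gaussian of width `sigma_mm` and applies the
#' Laplacian, computed as the sum of separable second-derivative-of-Gaussian
#' responses along the three axes, multiplied by sigma^2 (scale
#' normalisation). Boundaries are handled by reflection.
#'
#' @param vol a [volume_grid] (expected at isotropic spacing).
#' @param sigma_mm positive Gaussian scale in mm.
#' @return a [volume_grid] with the filter response.
#' @export
log_filter <- function(vol, sigma_mm) {
  if (!is.numeric(sigma_mm) || length(sigma_mm) != 1L || sigma_mm <= 0)
    stop("log_filter: sigma_mm must be a positive scalar")
  sp <- vol$spacing
  g <- lapply(1:3, function(a) .gauss_kernel(sigma_mm / sp[a]))
  d2 <- lapply(1:3, function(a) .gauss_d2_kernel(sigma_mm / sp[a]) / sp[a]^2)
  acc <- array(0, dim(vol$data))
  for (a in 1:3) {
    ks <- g
    ks[[a]] <- d2[[a]]
    acc <- acc + .conv_sep(vol$data, ks)
  }
  volume_grid(sigma_mm^2 * acc, sp, vol$origin, vol$orientation)
}

#' Single-level stationary 3-D wavelet subbands
#'
#' Undecimated separable wavelet transform: every subband has the original
#' shape so ROI masks apply voxel-for-voxel. Subband name letter i gives the
#' filter (L = low-pass, H = high-pass) applied along array axis i.
#'
#' @param vol a [volume_grid].
#' @param wavelet one of `"coif1"` (default), `"db2"`, `"sym4"`, `"haar"`.
#' @param boundary `"reflect"` (default) or `"periodic"`. The periodic mode
#'   makes the eight subband energies sum exactly to the input energy
#'   (Parseval identity for the orthonormal pair).
#' @return named list of 8 [volume_grid] subbands (`LLL` ... `HHH`).
#' @export
wavelet_subbands <- function(vol, wavelet = "coif1", boundary = "reflect") {
  f <- .wavelet_filters(wavelet)
  if (any(dim(vol$data) < length(f$lo)))
    stop("wavelet_subbands: volume smaller than the filter length (",
         length(f$lo), ") on some axis")
  b <- .boundary_code(boundary)
  d <- dim(vol$data)
  x <- as.numeric(vol$data)
  ax1 <- list(L = cpp_conv_axis(x, d, f$lo, 0L, b),
              H = cpp_conv_axis(x, d, f$hi, 0L, b))
  out <- vector("list", 8)
  names(out) <- .canonical_subbands
  for (nm in .canonical_subbands) {
    lett <- strsplit(nm, "")[[1]]
    cur <- ax1[[lett[1]]]
    cur <- cpp_conv_axis(cur, d, if (lett[2] == "L") f$lo else f$hi, 1L, b)
    cur <- cpp_conv_axis(cur, d, if (lett[3] == "L") f$lo else f$hi, 2L, b)
    out[[nm]] <- volume_grid(array(cur, d), vol$spacing, vol$origin, vol$orientation)
  }
  out
}

.log_image_name <- function(sigma) sprintf("LoG-%02d", round(sigma * 10))

#' Build the canonical 13-image filtered set
#'
#' Produces, in frozen order, the resampled original (`Intensities`), one
#' Laplacian-of-Gaussian response per scale, and the eight stationary wavelet
#' subbands. This order is a contract shared with [feature_catalogue()].
#'
#' @param vol a [volume_grid] resampled to isotropic spacing.
#' @param sigmas LoG scales in mm; default `c(0.5, 1.5, 2.5, 3.5)`.
#' @param wavelet wavelet family passed to [wavelet_subbands()].
#' @return object of class `filtered_image_set`: named list of [volume_grid]s.
#' @export
build_image_set <- function(vol, sigmas = c(0.5, 1.5, 2.5, 3.5),
                            wavelet = "coif1") {
  imgs <- list(Intensities = vol)
  for (s in sigmas)
    imgs[[.log_image_name(s)]] <- log_filter(vol, s)
  wb <- wavelet_subbands(vol, wavelet = wavelet)
  for (nm in .canonical_subbands)
    imgs[[paste0("Wavelet-", nm)]] <- wb[[nm]]
  structure(imgs, class = "filtered_image_set")
}

#' @export
print.filtered_image_set <- function(x, ...) {
  cat("<filtered_image_set> ", length(x), " images: ",
      paste(names(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}
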