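# The frozen 754-entry feature catalogue and per-subject extraction.

.firstorder_names <- function() {
  c("mean", "variance", "standard deviation", "minimum", "maximum", "median",
    "10th percentile", "90th percentile", "interquartile range", "range",
    "mean absolute deviation", "robust mean absolute deviation", "energy",
    "root mean square", "skewness", "kurtosis", "entropy", "uniformity")
}

.texture_names <- function() {
  c(names(.glcm_stats(diag(2) / 2)),
    names(.glrlm_stats(matrix(1, 2, 2), 4)),
    c("GLSZM small zone emphasis", "GLSZM large zone emphasis",
      "GLSZM grey level non-uniformity", "GLSZM zone size non-uniformity",
      "GLSZM small zone low grey level emphasis",
      "GLSZM small zone high grey level emphasis",
      "GLSZM large zone low grey level emphasis",
      "GLSZM large zone high grey level emphasis",
      "GLSZM grey level variance", "GLSZM zone percentage"),
    c("NGTDM coarseness", "NGTDM contrast", "NGTDM busyness",
      "NGTDM complexity", "NGTDM strength"))
}

.shape_names <- function() {
  c("voxel count", "volume (voxel, mL)", "volume (mesh, mL)",
    "surface area (mm2)", "surface to volume ratio", "sphericity",
    "compactness 1", "compactness 2", "spherical disproportion",
    "maximum 3D diameter", "maximum 2D diameter (axial)",
    "maximum 2D diameter (coronal)", "maximum 2D diameter (sagittal)",
    "major axis length", "minor axis length", "least axis length",
    "elongation", "flatness", "bounding box extent x",
    "bounding box extent y", "bounding box extent z",
    "volume density (AABB)", "area density (AABB)",
    "equivalent sphere diameter")
}

.image_names <- function(sigmas = c(0.5, 1.5, 2.5, 3.5)) {
  c("Intensities", vapply(sigmas, .log_image_name, character(1)),
    paste0("Wavelet-", .canonical_subbands))
}

#' The feature catalogue
#'
#' Ordered list of feature identifiers: for each of the 13 derived images,
#' 18 first-order and 38 texture features (56 per image, 728 in total); then
#' 24 shape features of the haematoma mask; then perihaematomal oedema and
#' intraventricular haemorrhage volumes. With the default configuration the
#' catalogue has exactly 754 unique entries; the arithmetic
#' `13 * 56 + 24 + 2 == 754` is asserted at load.
#'
#' @param sigmas LoG scales (mm) used by the filter bank.
#' @param expected_total asserted catalogue size (default 754); pass `NULL`
#'   to allow non-standard filter configurations.
#' @return data.frame with columns `id`, `image`, `family`, `feature`.
#' @export
feature_catalogue <- function(sigmas = c(0.5, 1.5, 2.5, 3.5),
                              expected_total = 754L) {
  imgs <- .image_names(sigmas)
  fo <- .firstorder_names()
  tx <- .texture_names()
  per_image <- length(fo) + length(tx)
  rows <- list()
  for (im in imgs) {
    rows[[length(rows) + 1L]] <- data.frame(
      id = paste(im, c(fo, tx)),
      image = im,
      family = c(rep("first-order", length(fo)),
                 sub(" .*$", "", tx)),
      feature = c(fo, tx),
      stringsAsFactors = FALSE)
  }
  sh <- .shape_names()
  rows[[length(rows) + 1L]] <- data.frame(
    id = paste("Intracerebral haemorrhage", sh),
    image = "mask", family = "shape", feature = sh, stringsAsFactors = FALSE)
  rows[[length(rows) + 1L]] <- data.frame(
    id = c("Perihaematomal oedema volume (mL)",
           "Intraventricular haemorrhage volume (mL)"),
    image = "mask", family = "volume",
    feature = c("PHE volume", "IVH volume"), stringsAsFactors = FALSE)
  cat <- do.call(rbind, rows)
  if (anyDuplicated(cat$id)) stop("feature_catalogue: duplicate identifiers")
  expected <- length(imgs) * per_image + length(sh) + 2L
  if (nrow(cat) != expected)
    stop("feature_catalogue: catalogue arithmetic broken")
  if (!is.null(expected_total) && nrow(cat) != expected_total)
    stop("feature_catalogue: configuration yields ", nrow(cat),
         " features, expected ", expected_total,
         " (13 images x 56 + 24 shape + 2 volumes = 754)")
  attr(cat, "sigmas") <- sigmas
  cat
}

#' Extract the full feature vector for one subject
#'
#' Builds the 13-image filter bank from the (resampled) baseline volume,
#' computes first-order and texture features of the haematoma region on every
#' image (each filtered image is re-discretised independently, since filter
#' outputs are not in HU), shape features of the haematoma mask, and appends
#' the perihaematomal oedema and intraventricular haemorrhage volumes.
#'
#' @param vol baseline [volume_grid].
#' @param mask matching [region_mask].
#' @param clinical optional one-row data.frame / list with at least
#'   `slice_thickness_mm`; `age`, `gender`, `treatment` and `subject_id` are
#'   attached as attributes when present.
#' @param sigmas,Ng,wavelet extraction configuration.
#' @param resample resample inputs to 1 mm isotropic first (default TRUE;
#'   set to FALSE if the inputs are already isotropic).
#' @return named numeric vector aligned to [feature_catalogue()], with
#'   attributes `batch`, `age`, `gender`, `treatment`, `subject_id`.
#' @export
extract_subject <- function(vol, mask, clinical = NULL,
                            sigmas = c(0.5, 1.5, 2.5, 3.5), Ng = 32L,
                            wavelet = "coif1", resample = TRUE) {
  if (resample) {
    vol <- resample_isotropic(vol, 1.0, "intensity")
    mask <- resample_isotropic(mask, 1.0, "mask-label")
  }
  if (!identical(dim(vol$data), dim(mask$labels)))
    stop("extract_subject: volume and mask geometry differ")
  if (!any(mask$labels == 1L))
    stop("extract_subject: empty intracerebral haemorrhage mask; subject excluded")
  cat <- feature_catalogue(sigmas)
  imgs <- build_image_set(vol, sigmas = sigmas, wavelet = wavelet)
  inroi <- mask$labels == 1L
  vals <- numeric(0)
  for (nm in names(imgs)) {
    im <- imgs[[nm]]
    fo <- first_order_features(im$data[inroi], Ng = Ng)
    d <- discretise(im, mask, label = 1L, Ng = Ng)
    tx <- c(glcm_features(d), glrlm_features(d), glszm_features(d),
            ngtdm_features(d))
    v <- c(fo, tx)
    names(v) <- paste(nm, names(v))
    vals <- c(vals, v)
  }
  sh <- shape_features(mask, 1L)
  names(sh) <- paste("Intracerebral haemorrhage", names(sh))
  vols <- c("Perihaematomal oedema volume (mL)" = region_volume_ml(mask, 3L),
            "Intraventricular haemorrhage volume (mL)" = region_volume_ml(mask, 2L))
  vals <- c(vals, sh, vols)
  if (!identical(names(vals), cat$id))
    stop("extract_subject: extracted features do not match the catalogue")
  if (any(!is.finite(vals)))
    stop("extract_subject: non-finite feature values: ",
         paste(head(names(vals)[!is.finite(vals)], 5), collapse = "; "))
  if (!is.null(clinical)) {
    if (!is.null(clinical$slice_thickness_mm))
      attr(vals, "batch") <- assign_batch(clinical$slice_thickness_mm)
    for (f in c("age", "gender", "treatment", "subject_id"))
      if (!is.null(clinical[[f]])) attr(vals, f) <- clinical[[f]]
  }
  vals
}
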