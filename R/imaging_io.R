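#' Volume grid in physical (scanner) coordinates
#'
#' A `volume_grid` holds a 3-D scalar field in Hounsfield units together with
#' its per-axis voxel spacing (mm), the physical position of voxel (1,1,1)
#' and the anatomical orientation of the array axes.
#'
#' @param data 3-D numeric array of intensities (HU). All values must be
#'   finite: scans with non-finite voxels are rejected rather than imputed.
#' @param spacing numeric length-3, voxel size in mm per array axis; all
#'   components must be positive and finite.
#' @param origin numeric length-3, physical coordinates (mm) of the first
#'   voxel. Defaults to the coordinate origin.
#' @param orientation three-letter axis code (e.g. `"RAS"`).
#' @return an object of class `volume_grid`.
#' @export
volume_grid <- function(data, spacing, origin = c(0, 0, 0), orientation = "RAS") {
  data <- unclass(data)
  if (length(dim(data)) != 3L)
    stop("volume_grid: 'data' must have exactly 3 axes, got ", length(dim(data)))
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("volume_grid: 'spacing' must be 3 positive finite values")
  if (any(!is.finite(data)))
    stop("volume_grid: data contains non-finite voxel values; scan rejected")
  structure(
    list(data = data, spacing = as.numeric(spacing),
         origin = as.numeric(origin), orientation = orientation),
    class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("<volume_grid> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm, ", x$orientation, "\n", sep = "")
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$data)

.default_label_map <- c(background = 0, ich = 1, ivh = 2, phe = 3)

#' Region label mask sharing a volume's geometry
#'
#' Integer label field aligned voxel-for-voxel with a [volume_grid]. The
#' default label map is 0 = background, 1 = intracerebral haemorrhage,
#' 2 = intraventricular haemorrhage, 3 = perihaematomal oedema.
#'
#' @param labels 3-D integer array of region labels.
#' @param spacing,origin,orientation geometry, as in [volume_grid()].
#' @param label_map named integer vector mapping region names to label values.
#' @return an object of class `region_mask`.
#' @export
region_mask <- function(labels, spacing, origin = c(0, 0, 0),
                        orientation = "RAS", label_map = .default_label_map) {
  labels <- unclass(labels)
  if (length(dim(labels)) != 3L)
    stop("region_mask: 'labels' must have exactly 3 axes")
  if (any(!is.finite(labels)))
    stop("region_mask: non-finite label values")
  if (any(labels != round(labels)))
    stop("region_mask: labels must be integers")
  bad <- setdiff(unique(as.vector(labels)), label_map)
  if (length(bad))
    stop("region_mask: voxel values not in label_map: ", paste(bad, collapse = ", "))
  structure(
    list(labels = array(as.integer(labels), dim(labels)),
         spacing = as.numeric(spacing), origin = as.numeric(origin),
         orientation = orientation, label_map = label_map),
    class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat("<region_mask> ", paste(dim(x$labels), collapse = " x "),
      " voxels, labels {", paste(sort(unique(as.vector(x$labels))), collapse = ","),
      "}\n", sep = "")
  invisible(x)
}

.squeeze_to_3d <- function(arr, path) {
  d <- dim(arr)
  if (is.null(d) || length(d) < 3L)
    stop("read_volume: '", path, "' does not have 3 spatial dimensions (dim field)")
  if (length(d) > 3L) {
    extra <- d[-(1:3)]
    if (any(extra != 1L))
      stop("read_volume: '", path, "' has ", sum(d > 1L),
           " non-singleton dimensions (dim field); only 3-D volumes are supported")
    arr <- array(arr, d[1:3])
  }
  arr
}

#' Read a NIfTI volume as a volume_grid
#'
#' Decodes spacing and orientation from the NIfTI header; RNifti applies the
#' intensity rescaling slope/intercept on load. Trailing singleton dimensions
#' are squeezed. Files with non-finite voxels, more than three non-singleton
#' dimensions, or non-positive spacing are rejected with a message naming the
#' offending header field.
#'
#' @param path path to a NIfTI-1/NIfTI-2 file.
#' @return a [volume_grid].
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- attr(img, "pixdim")
  if (is.null(pd)) pd <- RNifti::pixdim(img)
  arr <- .squeeze_to_3d(as.array(img), path)
  sp <- pd[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("read_volume: '", path, "' has non-positive voxel spacing (pixdim field): ",
         paste(signif(sp, 4), collapse = " x "))
  orient <- tryCatch(RNifti::orientation(img), error = function(e) "RAS")
  org <- tryCatch({
    xf <- RNifti::xform(img)
    as.numeric(xf[1:3, 4])
  }, error = function(e) c(0, 0, 0))
  volume_grid(arr, sp, origin = org, orientation = orient)
}

#' Write a volume_grid to a NIfTI file
#'
#' @param vol a [volume_grid] or [region_mask].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI storage type; masks are written as integers.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, datatype = "auto") {
  arr <- if (inherits(vol, "region_mask")) vol$labels else vol$data
  if (datatype == "auto")
    datatype <- if (inherits(vol, "region_mask")) "int16" else "double"
  attr(arr, "pixdim") <- vol$spacing
  img <- RNifti::asNifti(arr, datatype = datatype)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI label mask as a region_mask
#'
#' @param path path to an integer-typed NIfTI file.
#' @param label_map named integer vector of permitted labels.
#' @return a [region_mask].
#' @export
read_mask <- function(path, label_map = .default_label_map) {
  vol <- read_volume(path)
  region_mask(round(vol$data), vol$spacing, vol$origin, vol$orientation,
              label_map = label_map)
}

.resample_geometry <- function(d, spacing, target_mm) {
  outdim <- pmax(1L, as.integer(ceiling(d * spacing / target_mm)))
  ratio <- target_mm / spacing
  list(outdim = outdim, ratio = ratio)
}

#' Resample a volume or mask to isotropic voxels
#'
#' Intensities are interpolated trilinearly onto a voxel-centre-aligned grid
#' whose physical extent covers the input extent (half-open on the far edge).
#' Label masks are resampled per label: each binary label indicator is
#' interpolated trilinearly and each output voxel takes the label with the
#' largest interpolated fraction (equivalent to thresholding at 0.5 when a
#' single label is locally present), which preserves the label set.
#'
#' @param vol a [volume_grid] or [region_mask].
#' @param target_mm target isotropic voxel size in mm (default 1).
#' @param mode `"intensity"` or `"mask-label"`; inferred from the input class
#'   by default.
#' @return resampled object of the same class.
#' @export
resample_isotropic <- function(vol, target_mm = 1.0,
                               mode = c("auto", "intensity", "mask-label")) {
  mode <- match.arg(mode)
  if (!is.numeric(target_mm) || length(target_mm) != 1L || target_mm <= 0)
    stop("resample_isotropic: target_mm must be a positive scalar")
  if (mode == "auto")
    mode <- if (inherits(vol, "region_mask")) "mask-label" else "intensity"
  if (mode == "intensity") {
    g <- .resample_geometry(dim(vol$data), vol$spacing, target_mm)
    out <- cpp_resample_trilinear(as.numeric(vol$data), dim(vol$data),
                                  g$ratio, g$outdim)
    volume_grid(array(out, g$outdim), rep(target_mm, 3), vol$origin, vol$orientation)
  } else {
    labs <- vol$labels
    g <- .resample_geometry(dim(labs), vol$spacing, target_mm)
    present <- sort(unique(as.vector(labs)))
    frac <- lapply(present, function(l)
      cpp_resample_trilinear(as.numeric(labs == l), dim(labs), g$ratio, g$outdim))
    best <- frac[[1]]
    out <- rep(present[1], length(best))
    if (length(present) > 1) {
      for (k in 2:length(present)) {
        take <- frac[[k]] > best
        out[take] <- present[k]
        best[take] <- frac[[k]][take]
      }
    }
    region_mask(array(out, g$outdim), rep(target_mm, 3), vol$origin,
                vol$orientation, label_map = vol$label_map)
  }
}

#' Region volume in millilitres
#'
#' @param mask a [region_mask].
#' @param label integer label present in the mask's `label_map`.
#' @return volume in mL (`voxel count * voxel volume / 1000`).
#' @export
region_volume_ml <- function(mask, label) {
  if (!label %in% mask$label_map)
    stop("region_volume_ml: unknown label ", label)
  sum(mask$labels == label) * prod(mask$spacing) / 1000
}
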