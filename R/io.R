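# NIfTI readers/writers (volumes, label maps, masks) and JSON serialization
# of fitted transform parameters. Voxel spacing is taken from the header;
# the axial slice axis must be the grid axis closest to the
# superior-inferior direction, and the affine must be orthogonal up to a
# tolerance (oblique acquisitions should be resampled upstream).

#' @noRd
check_affine <- function(img, path) {
  xf <- try(RNifti::xform(img), silent = TRUE)
  if (inherits(xf, "try-error") || is.null(xf)) return(invisible(NULL))
  R <- xf[1:3, 1:3]
  cn <- sqrt(colSums(R^2))
  if (any(cn == 0)) stop(sprintf("%s: degenerate affine (zero column)", path))
  Rn <- sweep(R, 2, cn, "/")
  if (any(apply(abs(Rn), 2, max) < 0.999))
    stop(sprintf("%s: affine is oblique beyond tolerance; resample to an axis-aligned grid first",
                 path))
  ax <- apply(abs(Rn), 2, which.max)
  if (ax[3] != 3L)
    stop(sprintf("%s: third grid axis is not the superior-inferior axis; reorient first", path))
  invisible(NULL)
}

#' Read a NIfTI volume
#'
#' @param path Path to a NIfTI-1/2 file.
#' @param mask_path Optional path to an aligned binary brain-mask NIfTI.
#' @return An [lf_volume()] with spacing from the header.
#' @export
read_volume <- function(path, mask_path = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  check_affine(img, path)
  data <- as.array(img)
  if (length(dim(data)) != 3L) stop(sprintf("%s: expected a 3-D volume", path))
  sp <- RNifti::pixdim(img)[1:3]
  mask <- NULL
  if (!is.null(mask_path)) {
    m <- as.array(RNifti::readNifti(mask_path))
    if (!identical(dim(m), dim(data)))
      stop("mask shape does not match the volume")
    if (!all(m %in% c(0, 1))) stop("mask must be binary")
    mask <- array(m > 0, dim = dim(m))
  }
  lf_volume(data, sp, mask)
}

#' Write a volume (and optionally its mask) as NIfTI
#'
#' @param volume An [lf_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param mask_path Optional output path for the mask.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, mask_path = NULL) {
  stopifnot(inherits(volume, "lf_volume"))
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing_mm
  RNifti::writeNifti(img, path)
  if (!is.null(mask_path) && !is.null(volume$mask)) {
    m <- RNifti::asNifti(array(as.integer(volume$mask), dim = dim(volume$mask)))
    RNifti::pixdim(m) <- volume$spacing_mm
    RNifti::writeNifti(m, mask_path)
  }
  invisible(path)
}

#' Read a NIfTI label map
#'
#' @param path Path to an integer-valued NIfTI segmentation.
#' @return A [label_map()]; non-integer data are rejected.
#' @export
read_label_map <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  check_affine(img, path)
  data <- as.array(img)
  if (any(data != round(data)))
    stop(sprintf("%s: label map contains non-integer values", path))
  label_map(data, RNifti::pixdim(img)[1:3])
}

#' Write a label map as NIfTI
#'
#' @param labels A [label_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(labels, path) {
  stopifnot(inherits(labels, "label_map"))
  img <- RNifti::asNifti(labels$data)
  RNifti::pixdim(img) <- labels$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Serialize fitted transform parameters to JSON
#'
#' @param params A [transform_params()].
#' @param path Output `.json` path.
#' @param metadata Optional named list (fit seed, objective, ...).
#' @return `path`, invisibly.
#' @export
write_transform_params <- function(params, path, metadata = list()) {
  stopifnot(inherits(params, "transform_params"))
  jsonlite::write_json(c(unclass(params), list(metadata = metadata)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read transform parameters from JSON
#'
#' @param path Path written by [write_transform_params()].
#' @return A [transform_params()] with attribute `metadata`.
#' @export
read_transform_params <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("noise1_amplitude", "blur_sigma_mm", "noise2_amplitude",
              "noise2_sigma_mm"))
    if (is.null(x[[f]])) stop(sprintf("%s: missing field '%s'", path, f))
  p <- transform_params(x$noise1_amplitude, x$blur_sigma_mm,
                        x$noise2_amplitude, x$noise2_sigma_mm)
  attr(p, "metadata") <- x$metadata
  p
}
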