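# Core containers: a volume is a 3-D intensity grid plus voxel spacing (mm)
# and an optional aligned binary brain mask; a label map is an aligned
# integer-valued segmentation (0 = non-lesion, 1..K lesion sub-labels).

#' Construct a 3-D MR volume
#'
#' The unit every image operation in the package consumes and produces:
#' a 3-D scalar grid in arbitrary normalized intensity units, its voxel edge
#' lengths in millimetres, and an optional aligned binary brain mask. Axial
#' slices run along the third array axis (inferior to superior).
#'
#' @param data Numeric 3-D array of intensities; must be finite everywhere.
#' @param spacing_mm Numeric length-3 vector of voxel edge lengths (mm),
#'   strictly positive.
#' @param mask Optional logical (or 0/1) array of the same shape marking
#'   brain voxels.
#' @return An object of class `lf_volume` with elements `data`, `spacing_mm`
#'   and `mask` (logical array or `NULL`).
#' @export
#' @examples
#' v <- lf_volume(array(1, c(4, 4, 2)), c(1, 1, 5))
lf_volume <- function(data, spacing_mm, mask = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array")
  if (!all(is.finite(data)))
    stop("`data` must be finite everywhere")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("`spacing_mm` must be three strictly positive numbers")
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(data)))
      stop("`mask` must have the same shape as `data`")
    if (!all(mask %in% c(0, 1)))
      stop("`mask` must be binary")
    mask <- array(as.logical(mask), dim = dim(data))
  }
  structure(list(data = data, spacing_mm = spacing_mm, mask = mask),
            class = "lf_volume")
}

#' @export
print.lf_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<lf_volume> %d x %d x %d voxels @ %.3g x %.3g x %.3g mm%s\n",
              d[1], d[2], d[3], x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3],
              if (is.null(x$mask)) "" else sprintf(", mask (%d voxels)", sum(x$mask))))
  invisible(x)
}

#' Construct an integer label map aligned to a volume
#'
#' @param data Integer-valued 3-D array; 0 marks non-lesion voxels, positive
#'   values lesion sub-labels.
#' @param spacing_mm Voxel edge lengths (mm).
#' @return An object of class `label_map`.
#' @export
label_map <- function(data, spacing_mm) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array")
  if (any(data != round(data)) || any(data < 0))
    stop("label map values must be non-negative integers")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("`spacing_mm` must be three strictly positive numbers")
  structure(list(data = array(as.integer(data), dim = dim(data)),
                 spacing_mm = spacing_mm),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %s voxels, labels: %s\n",
              paste(dim(x$data), collapse = " x "),
              paste(sort(unique(x$data[x$data > 0])), collapse = ", ")))
  invisible(x)
}

#' Target acquisition grid of the simulated low-field device
#'
#' Voxel spacing of the 64 mT scanner's whole-brain FLAIR protocol
#' (1.6 x 1.6 mm in plane, 5 mm slices); the default re-slicing target for
#' the low-field transform.
#'
#' @return Numeric length-3 vector of millimetre spacings.
#' @export
lf_target_spacing <- function() c(1.6, 1.6, 5)

#' Re-slice a volume to a target voxel spacing
#'
#' Resamples the intensity grid (tri-linearly) onto a new cell-centered grid
#' covering the same physical extent; the brain mask, if present, is
#' resampled alongside and re-binarized at 0.5. If the target equals the
#' input spacing the volume is returned unchanged.
#'
#' @param volume An [lf_volume()].
#' @param target_spacing_mm Target voxel spacing (mm); defaults to the
#'   low-field acquisition grid [lf_target_spacing()].
#' @return An [lf_volume()] on the target grid.
#' @export
reslice <- function(volume, target_spacing_mm = lf_target_spacing()) {
  stopifnot(inherits(volume, "lf_volume"))
  target_spacing_mm <- as.numeric(target_spacing_mm)
  if (length(target_spacing_mm) != 3L || any(!is.finite(target_spacing_mm)) ||
      any(target_spacing_mm <= 0))
    stop("target spacing must be three strictly positive numbers")
  sp <- volume$spacing_mm
  if (max(abs(target_spacing_mm - sp) / sp) < 1e-12) return(volume)
  extent <- dim(volume$data) * sp
  shape_out <- pmax(1L, as.integer(ceiling(extent / target_spacing_mm - 1e-9)))
  data_out <- resample_trilinear(volume$data, sp, target_spacing_mm, shape_out)
  mask_out <- NULL
  if (!is.null(volume$mask)) {
    m <- resample_trilinear(volume$mask + 0, sp, target_spacing_mm, shape_out)
    mask_out <- m >= 0.5
  }
  lf_volume(data_out, target_spacing_mm, mask_out)
}

#' Re-slice a label map to a target voxel spacing
#'
#' Nearest-neighbor resampling so labels remain integers.
#'
#' @param labels A [label_map()].
#' @param target_spacing_mm Target voxel spacing (mm).
#' @return A [label_map()] on the target grid.
#' @export
reslice_labels <- function(labels, target_spacing_mm = lf_target_spacing()) {
  stopifnot(inherits(labels, "label_map"))
  target_spacing_mm <- as.numeric(target_spacing_mm)
  if (any(target_spacing_mm <= 0)) stop("target spacing must be positive")
  sp <- labels$spacing_mm
  if (max(abs(target_spacing_mm - sp) / sp) < 1e-12) return(labels)
  extent <- dim(labels$data) * sp
  shape_out <- pmax(1L, as.integer(ceiling(extent / target_spacing_mm - 1e-9)))
  label_map(resample_nearest(labels$data, sp, target_spacing_mm, shape_out),
            target_spacing_mm)
}

#' Intensity-histogram moments of a volume
#'
#' Mean, standard deviation and skewness of the in-mask intensities; these
#' three moments are the histogram features matched when calibrating the
#' low-field transform. Population (divide-by-n) moments are used and
#' skewness is the standardized third central moment.
#'
#' @param volume An [lf_volume()] with a brain mask covering at least two
#'   voxels.
#' @return A list of class `histogram_moments` with elements `mean`, `sd`,
#'   `skewness`, `n` and `degenerate` (`TRUE` when the in-mask sd is 0, in
#'   which case skewness is reported as 0).
#' @export
histogram_moments <- function(volume) {
  stopifnot(inherits(volume, "lf_volume"))
  if (is.null(volume$mask)) stop("histogram moments require a brain mask")
  v <- volume$data[volume$mask]
  n <- length(v)
  if (n < 2L) stop("mask must cover at least 2 voxels")
  mu <- mean(v)
  s2 <- mean((v - mu)^2)
  s <- sqrt(s2)
  degenerate <- s == 0
  sk <- if (degenerate) 0 else mean((v - mu)^3) / s^3
  structure(list(mean = mu, sd = s, skewness = sk, n = n, degenerate = degenerate),
            class = "histogram_moments")
}

#' @export
print.histogram_moments <- function(x, ...) {
  cat(sprintf("<histogram_moments> mean %.4g, sd %.4g, skewness %.4g (n = %d%s)\n",
              x$mean, x$sd, x$skewness, x$n,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}
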