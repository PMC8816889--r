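# Lesion-contrast modulation: lesion intensities are scaled independently
# of the surrounding brain tissue, in steps from 100% (original) down to 0%
# (isointense), where isointensity means the mean lesion intensity equals
# the mean non-lesional in-mask intensity of the same axial slice. The
# within-lesion SNR (mean/sd) ranks lesions by homogeneity so contrast
# experiments can be restricted to the most homogeneous lesions, for which
# isointense detection must be driven by structure rather than intensity.

#' Specify a lesion contrast level
#'
#' @param scale_percent Overall lesion intensity scale in percent;
#'   100 = identity, 0 = isointense. The study design uses
#'   `c(100, 80, 60, 40, 20, 0)`.
#' @param per_label Optional named numeric vector mapping sub-label (as
#'   character) to its own scale, overriding `scale_percent` for those
#'   sub-labels.
#' @return An object of class `contrast_level`.
#' @export
contrast_level <- function(scale_percent, per_label = NULL) {
  stopifnot(length(scale_percent) == 1L, is.finite(scale_percent),
            scale_percent >= 0, scale_percent <= 100)
  if (!is.null(per_label)) {
    stopifnot(is.numeric(per_label), !is.null(names(per_label)),
              all(per_label >= 0), all(per_label <= 100))
  }
  structure(list(scale_percent = as.numeric(scale_percent),
                 per_label = per_label),
            class = "contrast_level")
}

#' Modulate lesion contrast toward isointensity
#'
#' Per axial slice and per lesion sub-label, lesion voxel intensities are
#' moved affinely toward the slice's non-lesional in-mask mean `m`:
#' `v' = m + (scale/100) * (v - m)`. This is the unique affine map that is
#' the identity at 100% and achieves exact isointensity (mean lesion
#' intensity equal to the slice's non-lesional mean) at 0%. Non-lesion
#' voxels are untouched.
#'
#' @param volume A masked [lf_volume()].
#' @param labels An aligned [label_map()].
#' @param level A [contrast_level()] (or a single number 0-100).
#' @return The modulated [lf_volume()].
#' @export
modulate_contrast <- function(volume, labels, level) {
  stopifnot(inherits(volume, "lf_volume"), inherits(labels, "label_map"))
  if (is.numeric(level)) level <- contrast_level(level)
  stopifnot(inherits(level, "contrast_level"))
  if (!identical(dim(volume$data), dim(labels$data)))
    stop("labels are not aligned with the volume")
  if (is.null(volume$mask)) stop("modulation requires a brain mask")
  if (level$scale_percent == 100 && is.null(level$per_label)) return(volume)
  x <- volume$data
  lab <- labels$data
  for (z in which(apply(lab > 0L, 3, any))) {
    sl <- x[, , z]
    lz <- lab[, , z]
    bg <- volume$mask[, , z] & lz == 0L
    if (!any(bg)) {
      warning(sprintf("slice %d has a lesion but no non-lesional in-mask pixels; skipped", z))
      next
    }
    m <- mean(sl[bg])
    for (l in unique(lz[lz > 0L])) {
      s <- level$scale_percent
      if (!is.null(level$per_label) && as.character(l) %in% names(level$per_label))
        s <- level$per_label[[as.character(l)]]
      idx <- lz == l
      sl[idx] <- m + (s / 100) * (sl[idx] - m)
    }
    x[, , z] <- sl
  }
  lf_volume(x, volume$spacing_mm, volume$mask)
}

#' Within-lesion signal-to-noise ratio (homogeneity)
#'
#' Mean over standard deviation (population) of the lesion voxel
#' intensities; higher values indicate more homogeneous lesions.
#'
#' @param volume An [lf_volume()].
#' @param labels An aligned [label_map()] with at least 2 lesion voxels.
#' @return Scalar SNR; `Inf` with attribute `homogeneous = TRUE` when the
#'   lesion is perfectly uniform.
#' @export
within_lesion_snr <- function(volume, labels) {
  stopifnot(inherits(volume, "lf_volume"), inherits(labels, "label_map"))
  if (!identical(dim(volume$data), dim(labels$data)))
    stop("labels are not aligned with the volume")
  v <- volume$data[labels$data > 0L]
  if (length(v) < 2L) stop("at least 2 lesion voxels are required")
  s <- sqrt(mean((v - mean(v))^2))
  if (s == 0) return(structure(Inf, homogeneous = TRUE))
  mean(v) / s
}

#' Select the most homogeneous lesions of a cohort
#'
#' Ranks patients by [within_lesion_snr()] (descending) and keeps the top
#' `ceiling(fraction * N)`; ties are broken stably by position in the input
#' cohort.
#'
#' @param cohort List of patients, each a list with components `volume` and
#'   `labels` (extra components are preserved).
#' @param fraction Fraction of the cohort to retain, in `(0, 1]`.
#' @return The retained sub-cohort (same structure, original order), with
#'   attribute `snr` giving every patient's SNR.
#' @export
select_homogeneous <- function(cohort, fraction = 0.5) {
  if (length(cohort) == 0L) stop("cohort is empty")
  stopifnot(fraction > 0, fraction <= 1)
  snr <- vapply(cohort, function(p)
    as.numeric(within_lesion_snr(p$volume, p$labels)), numeric(1))
  keep_n <- ceiling(fraction * length(cohort))
  ord <- order(-snr, seq_along(snr))
  keep <- sort(ord[seq_len(keep_n)])
  structure(cohort[keep], snr = snr, kept = keep)
}
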