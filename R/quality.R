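# Perceived-quality metric: gradient entropy. The [1 -1] finite-difference
# kernel is convolved with the slice along the in-plane horizontal axis
# ("valid" convolution, no padding), the absolute response is normalized to
# sum 1 over the slice, and its Shannon entropy (bits) is the score. Sharp
# images concentrate gradient mass at few edges (low entropy); blur and
# noise spread it (high entropy), so lower values track radiologists'
# perception of sharper, higher-quality images.

#' Gradient entropy of a 2-D slice
#'
#' @param image Numeric matrix (one axial slice).
#' @return Entropy in bits (scalar `>= 0`); a constant slice has no
#'   gradient mass and returns 0 with attribute `degenerate = TRUE`.
#' @export
#' @examples
#' gradient_entropy(matrix(rnorm(64), 8, 8))
gradient_entropy <- function(image) {
  if (!is.matrix(image) || length(image) < 1L)
    stop("`image` must be a non-empty matrix")
  if (!all(is.finite(image))) stop("`image` must be finite")
  if (ncol(image) < 2L)
    return(structure(0, degenerate = TRUE))
  g <- abs(image[, -1L, drop = FALSE] - image[, -ncol(image), drop = FALSE])
  s <- sum(g)
  if (s == 0)
    return(structure(0, degenerate = TRUE))
  h <- g[g > 0] / s
  -sum(h * log2(h))
}

#' Per-slice gradient entropy of a volume
#'
#' Computes gradient entropy for every axial slice that intersects the
#' brain mask and aggregates by the mean.
#'
#' @param volume A masked [lf_volume()].
#' @return A list of class `gradient_entropy_result`: `F` (mean over
#'   slices), `n_slices`, `per_slice_F` and `slice_indices` (1-based).
#' @export
volume_gradient_entropy <- function(volume) {
  stopifnot(inherits(volume, "lf_volume"))
  if (is.null(volume$mask) || !any(volume$mask))
    stop("volume must have a non-empty brain mask")
  zs <- which(apply(volume$mask, 3, any))
  per <- vapply(zs, function(z) as.numeric(gradient_entropy(volume$data[, , z])),
                numeric(1))
  structure(list(F = mean(per), n_slices = length(zs),
                 per_slice_F = per, slice_indices = zs),
            class = "gradient_entropy_result")
}

#' @export
print.gradient_entropy_result <- function(x, ...) {
  cat(sprintf("<gradient_entropy_result> F = %.4g bits over %d slices\n",
              x$F, x$n_slices))
  invisible(x)
}

#' Paired comparison of image-quality scores between two arms
#'
#' Paired two-sided t-test on per-image aggregate scores with a
#' paired-samples effect size (mean difference divided by the standard
#' deviation of the differences).
#'
#' @param a,b Numeric vectors of equal length (`>= 2`), one score per image.
#' @return List with `t_statistic`, `p_value`, `effect_size`, `mean_diff`,
#'   `n` and `degenerate` (`TRUE` when the differences have zero variance;
#'   then `t = 0, p = 1, effect = 0` for identical arms, or an infinite
#'   statistic for a constant nonzero shift).
#' @export
paired_quality_test <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (length(a) != length(b)) stop("`a` and `b` must have equal length")
  if (length(a) < 2L) stop("at least 2 pairs are required")
  d <- a - b
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    if (mean(d) == 0)
      return(list(t_statistic = 0, p_value = 1, effect_size = 0,
                  mean_diff = 0, n = length(d), degenerate = TRUE))
    return(list(t_statistic = sign(mean(d)) * Inf, p_value = 0,
                effect_size = sign(mean(d)) * Inf, mean_diff = mean(d),
                n = length(d), degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t_statistic = unname(tt$statistic), p_value = tt$p.value,
       effect_size = mean(d) / sd_d, mean_diff = mean(d),
       n = length(d), degenerate = FALSE)
}
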