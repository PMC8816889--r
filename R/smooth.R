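# Separable Gaussian smoothing and resampling primitives for 3-D grids.
# Kernels are truncated at 3.5 sigma and renormalized to unit sum; borders
# use zero padding, consistent with skull-stripped volumes whose background
# is exactly 0.

#' @noRd
gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 1e-8) return(1)
  r <- max(1L, as.integer(ceiling(3.5 * sigma)))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# Convolve a 3-D array along one axis with a symmetric kernel, zero padding.
#' @noRd
conv_axis <- function(a, k, axis) {
  if (length(k) == 1L) return(a * k)
  d <- dim(a)
  r <- (length(k) - 1L) %/% 2L
  perm <- c(axis, setdiff(1:3, axis))
  m <- aperm(a, perm)
  dm <- dim(m)
  dim(m) <- c(dm[1], prod(dm[-1]))
  out <- matrix(0, nrow = dm[1], ncol = ncol(m))
  n <- dm[1]
  for (t in seq_along(k)) {
    off <- t - r - 1L
    i_lo <- max(1L, 1L - off)
    i_hi <- min(n, n - off)
    if (i_lo > i_hi) next
    i_out <- i_lo:i_hi
    out[i_out, ] <- out[i_out, ] + k[t] * m[i_out + off, , drop = FALSE]
  }
  dim(out) <- dm
  aperm(out, order(perm))
}

# Separable 3-D Gaussian smoothing; sigma_vox is per-axis in voxel units.
#' @noRd
gaussian_smooth3 <- function(a, sigma_vox) {
  stopifnot(length(dim(a)) == 3L, length(sigma_vox) == 3L, all(sigma_vox >= 0))
  for (ax in 1:3) {
    if (sigma_vox[ax] > 1e-8) a <- conv_axis(a, gaussian_kernel_1d(sigma_vox[ax]), ax)
  }
  a
}

# 2-D Gaussian smoothing of a matrix (used by the slice feature extractor).
#' @noRd
gaussian_smooth2 <- function(m, sigma_px) {
  a <- array(m, dim = c(dim(m), 1L))
  gaussian_smooth3(a, c(sigma_px, sigma_px, 0))[, , 1L]
}

# Trilinear resampling of a 3-D array between cell-centered grids.
# Voxel i (0-based) has physical center (i + 0.5) * spacing.
#' @noRd
resample_trilinear <- function(a, spacing_in, spacing_out, shape_out) {
  d <- dim(a)
  idx <- lapply(1:3, function(ax) {
    x <- ((seq_len(shape_out[ax]) - 0.5) * spacing_out[ax]) / spacing_in[ax] - 0.5
    pmin(pmax(x, 0), d[ax] - 1)
  })
  i0 <- lapply(1:3, function(ax) pmin(floor(idx[[ax]]), d[[ax]] - 1))
  fr <- lapply(1:3, function(ax) idx[[ax]] - i0[[ax]])
  i1 <- lapply(1:3, function(ax) pmin(i0[[ax]] + 1, d[[ax]] - 1))
  iR <- lapply(1:3, function(ax) list(as.integer(i0[[ax]]) + 1L, as.integer(i1[[ax]]) + 1L))
  wR <- lapply(1:3, function(ax) list(1 - fr[[ax]], fr[[ax]]))
  out <- array(0, dim = shape_out)
  for (cx in 1:2) for (cy in 1:2) for (cz in 1:2) {
    w <- outer(outer(wR[[1]][[cx]], wR[[2]][[cy]]), wR[[3]][[cz]])
    out <- out + w * a[iR[[1]][[cx]], iR[[2]][[cy]], iR[[3]][[cz]], drop = FALSE]
  }
  out
}

# Nearest-neighbor resampling (labels must remain integers).
#' @noRd
resample_nearest <- function(a, spacing_in, spacing_out, shape_out) {
  d <- dim(a)
  idx <- lapply(1:3, function(ax) {
    x <- ((seq_len(shape_out[ax]) - 0.5) * spacing_out[ax]) / spacing_in[ax] - 0.5
    as.integer(pmin(pmax(round(x), 0), d[ax] - 1)) + 1L
  })
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}
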