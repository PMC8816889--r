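# High-field -> low-field domain transformation: after re-slicing to the
# low-field grid, image quality is degraded by a four-parameter cascade --
# (1) white noise pre-smoothed with a fixed 0.5-voxel Gaussian, scaled by
# `noise1_amplitude` and added within the brain mask; (2) a 3-D Gaussian
# blur of parameterized width `blur_sigma_mm`; (3) a second noise field
# smoothed with `noise2_sigma_mm` and scaled by `noise2_amplitude`.
# The parameters are calibrated by matching intensity-histogram moments
# (mean, sd, skewness) of simulated images against real low-field targets.

#' Degradation parameters of the low-field transform
#'
#' @param noise1_amplitude Amplitude of the first (pre-blur) noise field;
#'   `>= 0`.
#' @param blur_sigma_mm Standard deviation (mm) of the main 3-D Gaussian
#'   smoothing; `>= 0`. Converted per axis to voxel units via the spacing.
#' @param noise2_amplitude Amplitude of the second (post-blur) noise field;
#'   `>= 0`.
#' @param noise2_sigma_mm Smoothing kernel standard deviation (mm) of the
#'   second noise filter; `>= 0`.
#' @return An object of class `transform_params`.
#' @export
#' @examples
#' transform_params(0.3, 1.8, 0.15, 1.2)
transform_params <- function(noise1_amplitude, blur_sigma_mm,
                             noise2_amplitude, noise2_sigma_mm) {
  p <- c(noise1_amplitude = noise1_amplitude, blur_sigma_mm = blur_sigma_mm,
         noise2_amplitude = noise2_amplitude, noise2_sigma_mm = noise2_sigma_mm)
  if (any(!is.finite(p)) || any(p < 0))
    stop("all transform parameters must be finite and >= 0")
  structure(as.list(p), class = "transform_params")
}

#' @export
print.transform_params <- function(x, ...) {
  cat(sprintf(paste0("<transform_params> noise1 %.4g, blur %.4g mm, ",
                     "noise2 %.4g (sigma %.4g mm)\n"),
              x$noise1_amplitude, x$blur_sigma_mm,
              x$noise2_amplitude, x$noise2_sigma_mm))
  invisible(x)
}

# Fixed std (voxel units) of the first noise field's pre-smoothing.
#' @noRd
NOISE1_PRESMOOTH_SIGMA_VOX <- 0.5

#' Apply the low-field degradation cascade to a volume
#'
#' The input must already be on the low-field grid (see [reslice()]) and
#' carry a brain mask: the pipeline is defined on skull-stripped images and
#' both noise fields are added within the mask only, so the background stays
#' exactly 0 (the output is re-masked after blurring for the same reason).
#' Noise fields are zero-mean unit-variance Gaussian white noise; the first
#' is pre-smoothed with a fixed 0.5-voxel-std 3-D Gaussian kernel.
#'
#' @param volume An [lf_volume()] with mask, on the target grid.
#' @param params A [transform_params()].
#' @param seed Integer seed for the two noise fields.
#' @return A degraded [lf_volume()] of the same shape, spacing and mask.
#' @export
apply_lf_transform <- function(volume, params, seed) {
  stopifnot(inherits(volume, "lf_volume"), inherits(params, "transform_params"))
  if (is.null(volume$mask))
    stop("apply_lf_transform requires a brain mask (skull-stripped input)")
  d <- dim(volume$data)
  sp <- volume$spacing_mm
  e1 <- with_seed(derive_seed(seed, "lf-noise1"),
                  array(stats::rnorm(prod(d)), dim = d))
  n1 <- gaussian_smooth3(e1, rep(NOISE1_PRESMOOTH_SIGMA_VOX, 3))
  x <- volume$data + params$noise1_amplitude * n1 * volume$mask
  if (params$blur_sigma_mm > 0)
    x <- gaussian_smooth3(x, params$blur_sigma_mm / sp)
  e2 <- with_seed(derive_seed(seed, "lf-noise2"),
                  array(stats::rnorm(prod(d)), dim = d))
  n2 <- gaussian_smooth3(e2, params$noise2_sigma_mm / sp)
  x <- x + params$noise2_amplitude * n2 * volume$mask
  x <- x * volume$mask
  lf_volume(x, sp, volume$mask)
}

# Standardized moment differences between a simulated volume's (averaged)
# moments and the target's: mean and sd differences are divided by the
# target sd so the objective is invariant to global intensity rescaling;
# skewness is already dimensionless.
#' @noRd
standardized_moment_diff <- function(m_sim, m_tgt) {
  c(mean = (m_sim[1] - m_tgt$mean) / m_tgt$sd,
    sd   = (m_sim[2] - m_tgt$sd) / m_tgt$sd,
    skew = m_sim[3] - m_tgt$skewness)
}

# Rescale a (mean, sd, skew) triple to the unit-in-mask-mean convention
# under which all fitted volumes are compared.
#' @noRd
normalize_moments <- function(mom) c(1, mom[2] / mom[1], mom[3])

#' Fit the low-field transform parameters by histogram-moment matching
#'
#' Minimizes, over the four degradation parameters, the mean across training
#' pairs of the summed squared standardized differences of the first three
#' intensity-histogram moments (mean, standard deviation, skewness) between
#' `apply_lf_transform(hf, theta)` and the real low-field target. The
#' simulated moments are averaged over a fixed set of seeded noise
#' realizations (common random numbers), which makes the objective
#' deterministic in `theta`. Because the degraded image is linear in the two
#' noise fields once the smoothing widths are fixed, its moments are exact
#' polynomials in the amplitude pair given the cached realizations: the fit
#' therefore runs a derivative-free simplex search over the two smoothing
#' widths only, solving for the amplitudes at every evaluation by bounded
#' quasi-Newton minimization of the closed-form inner objective. Every
#' volume entering the comparison -- the high-field input, the low-field
#' target and each simulated image -- is normalized to unit in-mask mean,
#' removing arbitrary scanner scaling (the blur's bleed across the brain
#' edge slightly lowers a simulated image's raw mean, so normalizing inputs
#' alone would bias the fit); the matched quantities are therefore the
#' scale-free moments (coefficient of variation and skewness).
#'
#' @param pairs List of pairs; each element a list with components `hf` (an
#'   [lf_volume()] already re-sliced to the low-field grid, with mask) and
#'   `lf` (the target [lf_volume()] with mask).
#' @param fit_config Optional list overriding fit defaults:
#'   `n_realizations` (noise realizations averaged per objective evaluation,
#'   default 4), `grid_blur` / `grid_sigma2` (coarse search grids, mm, over
#'   the two smoothing widths preceding the simplex polish), `n_starts`
#'   (number of best grid points polished, default 1), `seed` (default 1),
#'   `maxit` (polish Nelder-Mead iterations, default 40), `reltol` (default
#'   1e-6), `upper` (parameter upper bounds in the order amplitude1, blur,
#'   amplitude2, sigma2; default `c(1, 4, 1, 4)`).
#' @return A list of class `transform_fit`: `params` (fitted
#'   [transform_params()]), `objective` (final value), `trace` (best
#'   objective after each accepted outer evaluation; monotone
#'   non-increasing), `improved` (`FALSE` with a warning when no start
#'   improved on its initial point), `moment_diffs` (per-pair standardized
#'   differences at the optimum) and the effective `config`.
#' @export
fit_transform_params <- function(pairs, fit_config = list()) {
  if (length(pairs) < 1L) stop("at least one (hf, lf) pair is required")
  cfg <- utils::modifyList(
    list(n_realizations = 4L, n_starts = 1L, seed = 1L,
         grid_blur = c(0.6, 1.2, 1.8, 2.4, 3.0),
         grid_sigma2 = c(0.5, 1.25, 2.0, 2.75),
         maxit = 40L, reltol = 1e-6, upper = c(1, 4, 1, 4)),
    fit_config)
  norm_unit_mean <- function(v) {
    if (is.null(v$mask)) stop("fitting requires masked volumes")
    lf_volume(v$data / mean(v$data[v$mask]), v$spacing_mm, v$mask)
  }
  pairs <- lapply(pairs, function(p) {
    stopifnot(inherits(p$hf, "lf_volume"), inherits(p$lf, "lf_volume"))
    if (!identical(dim(p$hf$data), dim(p$lf$data)))
      stop("each hf volume must be re-sliced to its lf target's grid")
    list(hf = norm_unit_mean(p$hf), lf = norm_unit_mean(p$lf))
  })
  m_tgt <- lapply(pairs, function(p) histogram_moments(p$lf))
  R <- cfg$n_realizations
  # cached unit-variance noise realizations, shared across all evaluations
  fields <- lapply(seq_along(pairs), function(p) {
    d <- dim(pairs[[p]]$hf$data)
    msk <- pairs[[p]]$hf$mask
    lapply(seq_len(R), function(r) {
      e1 <- with_seed(derive_seed(cfg$seed, paste0("fit-e1-", p, "-", r)),
                      array(stats::rnorm(prod(d)), dim = d))
      e2 <- with_seed(derive_seed(cfg$seed, paste0("fit-e2-", p, "-", r)),
                      array(stats::rnorm(prod(d)), dim = d))
      list(n1m = gaussian_smooth3(e1, rep(NOISE1_PRESMOOTH_SIGMA_VOX, 3)) * msk,
           e2 = e2)
    })
  })

  # Moments of Z = A + a1 X + a2 Y over the mask as polynomials in (a1, a2):
  # precompute centered cross-moment sums up to order 3 for each realization.
  component_stats <- function(A, X, Y, msk) {
    a <- A[msk]; x <- X[msk]; y <- Y[msk]
    ma <- mean(a); mx <- mean(x); my <- mean(y)
    a <- a - ma; x <- x - mx; y <- y - my
    list(ma = ma, mx = mx, my = my,
         s2 = c(aa = mean(a * a), xx = mean(x * x), yy = mean(y * y),
                ax = mean(a * x), ay = mean(a * y), xy = mean(x * y)),
         s3 = c(aaa = mean(a^3), xxx = mean(x^3), yyy = mean(y^3),
                aax = mean(a * a * x), aay = mean(a * a * y),
                axx = mean(a * x * x), ayy = mean(a * y * y),
                xxy = mean(x * x * y), xyy = mean(x * y * y),
                axy = mean(a * x * y)))
  }
  moments_from_stats <- function(st, a1, a2) {
    s2 <- st$s2; s3 <- st$s3
    m <- st$ma + a1 * st$mx + a2 * st$my
    m2 <- s2["aa"] + a1^2 * s2["xx"] + a2^2 * s2["yy"] +
      2 * a1 * s2["ax"] + 2 * a2 * s2["ay"] + 2 * a1 * a2 * s2["xy"]
    m3 <- s3["aaa"] + a1^3 * s3["xxx"] + a2^3 * s3["yyy"] +
      3 * a1 * s3["aax"] + 3 * a2 * s3["aay"] +
      3 * a1^2 * s3["axx"] + 3 * a2^2 * s3["ayy"] +
      3 * a1^2 * a2 * s3["xxy"] + 3 * a1 * a2^2 * s3["xyy"] +
      6 * a1 * a2 * s3["axy"]
    sd <- sqrt(max(m2, 0))
    skew <- if (sd > 0) m3 / sd^3 else 0
    c(unname(m), sd, unname(skew))
  }

  # given smoothing widths, cache component stats and return the inner
  # objective as a function of the amplitude pair
  inner_objective <- function(blur_mm, sigma2_mm) {
    stats_pr <- lapply(seq_along(pairs), function(p) {
      v <- pairs[[p]]$hf
      msk <- v$mask
      sig_b <- blur_mm / v$spacing_mm
      sig_2 <- sigma2_mm / v$spacing_mm
      A <- if (blur_mm > 0) gaussian_smooth3(v$data, sig_b) else v$data
      lapply(fields[[p]], function(f) {
        X <- if (blur_mm > 0) gaussian_smooth3(f$n1m, sig_b) else f$n1m
        Y <- gaussian_smooth3(f$e2, sig_2)
        component_stats(A, X, Y, msk)
      })
    })
    function(amps) {
      mean(vapply(seq_along(pairs), function(p) {
        mom <- Reduce(`+`, lapply(stats_pr[[p]], function(st)
          normalize_moments(moments_from_stats(st, amps[1], amps[2])))) / R
        sum(standardized_moment_diff(mom, m_tgt[[p]])^2)
      }, numeric(1)))
    }
  }

  solve_amplitudes <- function(obj) {
    best <- NULL
    for (a0 in list(c(0.1, 0.1), c(0.4, 0.05), c(0.05, 0.3))) {
      o <- stats::optim(a0, obj, method = "L-BFGS-B",
                        lower = c(0, 0), upper = cfg$upper[c(1, 3)],
                        control = list(factr = 1e9))
      if (is.null(best) || o$value < best$value) best <- o
    }
    best
  }

  trace_env <- new.env(); trace_env$vals <- numeric(0)
  outer_fn <- function(phi) {
    w <- pmin(phi^2, cfg$upper[c(2, 4)])
    pen <- 10 * sum(pmax(phi^2 - cfg$upper[c(2, 4)], 0))
    sol <- solve_amplitudes(inner_objective(w[1], w[2]))
    val <- sol$value + pen
    trace_env$vals <- c(trace_env$vals, val)
    attr(val, "amps") <- sol$par
    val
  }

  # coarse grid over the two smoothing widths, then simplex polish from the
  # best grid point(s)
  grid <- expand.grid(blur = cfg$grid_blur, sigma2 = cfg$grid_sigma2)
  grid_vals <- vapply(seq_len(nrow(grid)),
                      function(i) as.numeric(outer_fn(sqrt(as.numeric(grid[i, ])))),
                      numeric(1))
  ord <- order(grid_vals)
  best <- list(par = sqrt(as.numeric(grid[ord[1], ])), value = grid_vals[ord[1]])
  improved <- FALSE
  for (k in seq_len(min(cfg$n_starts, nrow(grid)))) {
    w0 <- as.numeric(grid[ord[k], ])
    opt <- stats::optim(sqrt(w0), function(p) as.numeric(outer_fn(p)),
                        method = "Nelder-Mead",
                        control = list(maxit = cfg$maxit, reltol = cfg$reltol))
    if (opt$value < grid_vals[ord[k]] - 1e-12) improved <- TRUE
    if (opt$value < best$value) best <- opt
  }
  if (!improved)
    warning("optimizer failed to improve on the coarse-grid optimum; returning it")

  w_hat <- pmin(best$par^2, cfg$upper[c(2, 4)])
  sol <- solve_amplitudes(inner_objective(w_hat[1], w_hat[2]))
  params <- transform_params(sol$par[1], w_hat[1], sol$par[2], w_hat[2])
  # report the achieved moment differences with the realization-averaged
  # simulated moments (the quantities the objective matched)
  moment_diffs <- lapply(seq_along(pairs), function(p) {
    pr <- params
    mom <- Reduce(`+`, lapply(seq_len(R), function(r) {
      v <- pairs[[p]]$hf
      sig_b <- pr$blur_sigma_mm / v$spacing_mm
      A <- if (pr$blur_sigma_mm > 0) gaussian_smooth3(v$data, sig_b) else v$data
      Z <- (A + pr$noise1_amplitude *
              (if (pr$blur_sigma_mm > 0)
                 gaussian_smooth3(fields[[p]][[r]]$n1m, sig_b)
               else fields[[p]][[r]]$n1m) +
              pr$noise2_amplitude *
                gaussian_smooth3(fields[[p]][[r]]$e2,
                                 pr$noise2_sigma_mm / v$spacing_mm)) * v$mask
      mm <- histogram_moments(lf_volume(Z, v$spacing_mm, v$mask))
      normalize_moments(c(mm$mean, mm$sd, mm$skewness))
    })) / R
    standardized_moment_diff(mom, m_tgt[[p]])
  })
  structure(list(params = params,
                 objective = sol$value,
                 trace = cummin(trace_env$vals),
                 improved = improved,
                 moment_diffs = moment_diffs,
                 config = cfg),
            class = "transform_fit")
}

#' @export
print.transform_fit <- function(x, ...) {
  cat(sprintf("<transform_fit> objective %.4g after %d evaluations%s\n",
              x$objective, length(x$trace),
              if (x$improved) "" else " (no improvement, flagged)"))
  print(x$params)
  invisible(x)
}
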