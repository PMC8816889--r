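test_that("transform parameters are validated", {
  expect_error(transform_params(-0.1, 1, 0, 1), ">= 0")
  expect_error(transform_params(0.1, NA, 0, 1), ">= 0")
  p <- transform_params(0.3, 1.8, 0.15, 1.2)
  expect_s3_class(p, "transform_params")
})

test_that("identity parameters leave a masked volume unchanged", {
  ph <- tiny_phantom(seed = 1)
  out <- apply_lf_transform(ph$volume, transform_params(0, 0, 0, 0), 42)
  expect_identical(out$data, ph$volume$data)
})

test_that("the transform requires a brain mask and is seed-deterministic", {
  ph <- tiny_phantom(seed = 1)
  nomask <- lf_volume(ph$volume$data, ph$volume$spacing_mm)
  th <- transform_params(0.3, 1.5, 0.1, 1)
  expect_error(apply_lf_transform(nomask, th, 1), "mask")
  a <- apply_lf_transform(ph$volume, th, 7)
  b <- apply_lf_transform(ph$volume, th, 7)
  d <- apply_lf_transform(ph$volume, th, 8)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, d$data))
  expect_true(all(a$data[!ph$mask] == 0))
})

test_that("first noise field variance matches the smoothed-white-noise law", {
  # Monte-Carlo estimate of var(amplitude * smooth_0.5(eps)) over seeds
  # against the separable kernel sum-of-squares prediction, interior voxels.
  d <- c(24, 24, 24)
  amp <- 0.7
  k <- lofisim:::gaussian_kernel_1d(0.5)
  predicted <- amp^2 * sum(k^2)^3
  core <- 5:20
  vals <- vapply(1:50, function(s) {
    e <- withr::with_seed(s, array(rnorm(prod(d)), dim = d))
    sm <- lofisim:::gaussian_smooth3(e, c(0.5, 0.5, 0.5))
    stats::var(as.vector(amp * sm[core, core, core]))
  }, numeric(1))
  expect_lt(abs(mean(vals) - predicted) / predicted, 0.05)
})

test_that("moment matching is invariant to global intensity rescaling", {
  ph <- tiny_phantom(seed = 3, grid = c(48, 48, 16))
  th <- transform_params(0.4, 1.8, 0.2, 1.2)
  hf <- reslice(ph$volume)
  lf <- apply_lf_transform(hf, th, 5)
  pair1 <- list(list(hf = hf, lf = lf))
  pair2 <- list(list(hf = lf_volume(2 * hf$data, hf$spacing_mm, hf$mask),
                     lf = lf_volume(2 * lf$data, lf$spacing_mm, lf$mask)))
  cfg <- list(seed = 2, grid_blur = c(1, 2), grid_sigma2 = c(1),
              maxit = 4, n_realizations = 2)
  f1 <- suppressWarnings(fit_transform_params(pair1, cfg))
  f2 <- suppressWarnings(fit_transform_params(pair2, cfg))
  expect_equal(f1$objective, f2$objective, tolerance = 1e-8)
  expect_equal(unclass(f1$params), unclass(f2$params), tolerance = 1e-6)
})

test_that("fit self-consistency: objective is near zero at the generator", {
  ph <- tiny_phantom(seed = 4, grid = c(64, 64, 24))
  th <- transform_params(0.4, 1.8, 0.2, 1.2)
  hf <- reslice(ph$volume)
  pairs <- list(list(hf = hf, lf = apply_lf_transform(hf, th, 6)))
  fit <- suppressWarnings(fit_transform_params(
    pairs, list(seed = 3, grid_blur = c(1.2, 1.8, 2.4), grid_sigma2 = c(0.8, 1.6),
                maxit = 20, n_realizations = 3)))
  # residual at the optimum is at the noise-realization floor
  expect_lt(fit$objective, 5e-3)
  expect_true(all(diff(fit$trace) <= 1e-12))   # monotone non-increasing
})

test_that("an unimprovable fit is flagged, never silent", {
  ph <- tiny_phantom(seed = 5, grid = c(48, 48, 16))
  hf <- reslice(ph$volume)
  pairs <- list(list(hf = hf, lf = apply_lf_transform(
    hf, transform_params(0.3, 1.5, 0.1, 1), 2)))
  expect_warning(
    fit_transform_params(pairs, list(seed = 1, grid_blur = 1.5,
                                     grid_sigma2 = 1, maxit = 0,
                                     n_realizations = 2)),
    "failed to improve")
})
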