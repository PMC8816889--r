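test_that("gradient entropy handles degenerate and uniform-gradient slices", {
  expect_equal(as.numeric(gradient_entropy(matrix(5, 8, 8))), 0)
  expect_true(attr(gradient_entropy(matrix(5, 8, 8)), "degenerate"))
  # ramp with 16 equal-magnitude gradients: uniform distribution entropy
  ramp <- matrix(seq(0, 16), nrow = 1)
  expect_equal(as.numeric(gradient_entropy(ramp)), log2(16), tolerance = 1e-12)
  expect_error(gradient_entropy(matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("gradient entropy equals the literal two-equation evaluation", {
  for (s in 1:5) {
    img <- withr::with_seed(s, matrix(rnorm(12 * 9), 12, 9))
    expect_equal(as.numeric(gradient_entropy(img)), brute_gradient_entropy(img),
                 tolerance = 1e-12)
  }
})

test_that("gradient entropy is invariant to intensity scale and shift", {
  img <- withr::with_seed(8, matrix(rnorm(100), 10, 10))
  f <- as.numeric(gradient_entropy(img))
  expect_identical(as.numeric(gradient_entropy(3.7 * img)), f)
  expect_equal(as.numeric(gradient_entropy(img + 11)), f, tolerance = 1e-9)
})

test_that("volume gradient entropy averages in-mask slices", {
  ph <- tiny_phantom(seed = 2)
  res <- volume_gradient_entropy(ph$volume)
  expect_equal(res$F, mean(res$per_slice_F))
  expect_equal(res$n_slices, length(res$per_slice_F))
  # single-slice volume: aggregate equals that slice's entropy
  sl <- ph$volume$data[, , 12]
  one <- lf_volume(array(sl, c(dim(sl), 1)), ph$volume$spacing_mm,
                   array(ph$mask[, , 12], c(dim(sl), 1)))
  expect_equal(volume_gradient_entropy(one)$F,
               as.numeric(gradient_entropy(ph$volume$data[, , 12])))
  # duplicating every slice leaves the mean unchanged
  dup <- lf_volume(ph$volume$data[, , rep(1:24, each = 2)],
                   ph$volume$spacing_mm, ph$mask[, , rep(1:24, each = 2)])
  expect_equal(volume_gradient_entropy(dup)$F, res$F, tolerance = 1e-12)
  expect_error(volume_gradient_entropy(lf_volume(ph$volume$data,
                                                 ph$volume$spacing_mm)),
               "mask")
})

test_that("low-field degradation increases gradient entropy of a phantom", {
  ph <- tiny_phantom(seed = 6)
  hf_F <- volume_gradient_entropy(ph$volume)$F
  lf <- generate_paired_lf_target(ph$volume,
                                  transform_params(0.4, 1.8, 0.2, 1.2), 3)
  expect_gt(volume_gradient_entropy(lf)$F, hf_F)
})

test_that("paired quality test matches the closed-form paired t", {
  a <- c(7.4, 7.9, 7.1)
  b <- c(5.8, 6.1, 5.6)
  res <- paired_quality_test(a, b)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(3))
  expect_equal(res$t_statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$effect_size, mean(d) / sd(d), tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pt(-abs(t_hand), df = 2), tolerance = 1e-12)
})

test_that("paired quality test flags degenerate differences", {
  a <- c(1, 2, 3)
  same <- paired_quality_test(a, a)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$effect_size, 0)
  shift <- paired_quality_test(a + 2, a)
  expect_true(shift$degenerate)
  expect_equal(shift$p_value, 0)
  expect_error(paired_quality_test(1:3, 1:4), "equal length")
})

test_that("constant shifts change t but preserve effect-size ordering", {
  set.seed(31)
  a <- rnorm(10, 7, 0.5)
  b1 <- a - rnorm(10, 1.5, 0.2)   # large separation
  b2 <- a - rnorm(10, 0.2, 0.2)   # small separation
  e_big <- abs(paired_quality_test(a, b1)$effect_size)
  e_small <- abs(paired_quality_test(a, b2)$effect_size)
  expect_gt(e_big, e_small)
  e_big_shift <- abs(paired_quality_test(a, b1 + 0.3)$effect_size)
  e_small_shift <- abs(paired_quality_test(a, b2 + 0.3)$effect_size)
  expect_gt(e_big_shift, e_small_shift)
})
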