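test_that("phantom generation is deterministic and mask-exact", {
  ph1 <- tiny_phantom(seed = 5)
  ph2 <- tiny_phantom(seed = 5)
  expect_identical(ph1$volume$data, ph2$volume$data)
  expect_identical(ph1$labels$data, ph2$labels$data)
  # every nonzero voxel lies inside the brain mask; background exactly 0
  expect_true(all(ph1$volume$data[!ph1$mask] == 0))
  expect_true(all(ph1$labels$data[!ph1$mask] == 0L))
})

test_that("a lesion-free spec yields an identically zero label map", {
  ph <- generate_phantom(phantom_spec(grid_shape = c(32, 32, 16),
                                      spacing_mm = c(2, 2, 4), seed = 2))
  expect_true(all(ph$labels$data == 0L))
  expect_gt(sum(ph$mask), 0)
})

test_that("achieved lesion area is within one pixel area of the request", {
  for (area in c(0.5, 4, 12)) {
    ph <- tiny_phantom(seed = 3, area_cm2 = area, grid = c(96, 96, 24),
                       spacing = c(1, 1, 3))
    per_slice <- apply(ph$labels$data > 0L, 3, sum)
    achieved <- max(per_slice) * 1 * 1 / 100        # cm^2 at 1 mm pixels
    expect_lte(abs(achieved - area), 0.01 + 1e-12)  # one 1 mm^2 pixel
  }
})

test_that("lesion sub-labels form concentric shells with distinct intensities", {
  ph <- tiny_phantom(seed = 7, area_cm2 = 8, contrast = c(2.2, 1.6),
                     noise_sd = 0)
  lab <- ph$labels$data
  expect_setequal(sort(unique(lab[lab > 0L])), c(1L, 2L))
  v1 <- mean(ph$volume$data[lab == 1L])
  v2 <- mean(ph$volume$data[lab == 2L])
  expect_gt(v1, v2)          # core brighter than rim
  expect_gt(v2, 1)           # rim hyperintense vs normalized tissue
})

test_that("impossible lesion requests are rejected with informative errors", {
  expect_error(phantom_spec(grid_shape = c(32, 32, 16), spacing_mm = c(2, 2, 4),
                            lesion_specs = list(lesion_spec(c(32, 32, 32), 0.01))),
               "below one in-plane pixel area")
  sp <- phantom_spec(grid_shape = c(64, 64, 24), spacing_mm = c(1, 1, 3),
                     lesion_specs = list(lesion_spec(c(2, 2, 36), 4)))
  expect_error(generate_phantom(sp), "outside the brain mask")
})

test_that("isointense lesions with mass effect still alter structure", {
  base <- generate_phantom(phantom_spec(
    grid_shape = c(64, 64, 24), spacing_mm = c(1, 1, 3), noise_sd = 0, seed = 9))
  iso <- tiny_phantom(seed = 9, contrast = 1.0, deform = 3, noise_sd = 0)
  diff_vox <- sum(base$volume$data != iso$volume$data)
  expect_gt(diff_vox, 0)
  # and the difference is not confined to the lesion voxels themselves
  expect_gt(diff_vox, sum(iso$labels$data > 0L))
})

test_that("paired low-field targets degrade through the identity cleanly", {
  ph <- tiny_phantom(seed = 11)
  ident <- transform_params(0, 0, 0, 0)
  tgt <- generate_paired_lf_target(ph$volume, ident, seed = 1)
  manual <- reslice(ph$volume)
  expect_equal(tgt$data, manual$data * manual$mask)
  expect_identical(dim(tgt$data), dim(manual$data))
})

test_that("different noise seeds share histogram-moment expectations", {
  ph <- tiny_phantom(seed = 13)
  th <- transform_params(0.4, 1.8, 0.2, 1.2)
  mom <- t(vapply(1:20, function(s) {
    m <- histogram_moments(generate_paired_lf_target(ph$volume, th, s))
    c(m$mean, m$sd, m$skewness)
  }, numeric(3)))
  # per-seed moments scatter tightly around the Monte-Carlo mean
  expect_lt(stats::sd(mom[, 2]) / mean(mom[, 2]), 0.05)
  expect_lt(max(abs(mom[, 1] - mean(mom[, 1]))) / mean(mom[, 1]), 0.02)
})

test_that("cohort generation is deterministic and patient-exclusive by id", {
  co1 <- generate_cohort(3, 2, seed = 21, grid_shape = c(64, 64, 24),
                         spacing_mm = c(1, 1, 3))
  co2 <- generate_cohort(3, 2, seed = 21, grid_shape = c(64, 64, 24),
                         spacing_mm = c(1, 1, 3))
  expect_identical(lapply(co1, function(p) p$volume$data),
                   lapply(co2, function(p) p$volume$data))
  ids <- vapply(co1, `[[`, character(1), "patient_id")
  expect_false(anyDuplicated(ids) > 0)
  expect_equal(vapply(co1, `[[`, logical(1), "lesional"),
               c(TRUE, TRUE, TRUE, FALSE, FALSE))
})
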