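test_that("contrast scale 100 is the bit-exact identity", {
  ph <- tiny_phantom(seed = 1)
  out <- modulate_contrast(ph$volume, ph$labels, contrast_level(100))
  expect_identical(out$data, ph$volume$data)
})

test_that("contrast scale 0 achieves exact per-slice isointensity", {
  ph <- tiny_phantom(seed = 2)
  out <- modulate_contrast(ph$volume, ph$labels, 0)
  for (z in which(apply(ph$labels$data > 0L, 3, any))) {
    lz <- ph$labels$data[, , z]
    sl <- out$data[, , z]
    bg <- ph$mask[, , z] & lz == 0L
    expect_lt(abs(mean(sl[lz > 0L]) - mean(sl[bg])), 1e-9)
  }
})

test_that("intermediate scaling follows the affine-toward-slice-mean formula", {
  # uniform lesion of intensity 2 in a slice whose non-lesional mean is 1
  d <- array(1, c(10, 10, 3))
  lab <- array(0L, c(10, 10, 3)); lab[4:5, 4:5, 2] <- 1L
  d[lab == 1L] <- 2
  msk <- array(TRUE, c(10, 10, 3))
  v <- lf_volume(d, c(1, 1, 1), msk)
  out <- modulate_contrast(v, label_map(lab, c(1, 1, 1)), 50)
  expect_equal(unique(out$data[lab == 1L]), 1.5)
  # non-lesion voxels bit-identical
  expect_identical(out$data[lab == 0L], d[lab == 0L])
})

test_that("lesion-background contrast is monotone in the scale", {
  ph <- tiny_phantom(seed = 3)
  gaps <- vapply(c(100, 80, 60, 40, 20, 0), function(s) {
    out <- modulate_contrast(ph$volume, ph$labels, s)
    z <- which.max(apply(ph$labels$data > 0L, 3, sum))
    lz <- ph$labels$data[, , z]; bg <- ph$mask[, , z] & lz == 0L
    abs(mean(out$data[, , z][lz > 0L]) - mean(out$data[, , z][bg]))
  }, numeric(1))
  expect_true(all(diff(gaps) <= 1e-12))
})

test_that("per-sub-label scales override the global scale", {
  ph <- tiny_phantom(seed = 4, contrast = c(2.2, 1.6), noise_sd = 0)
  out <- modulate_contrast(ph$volume, ph$labels,
                           contrast_level(100, per_label = c(`1` = 0)))
  z <- which.max(apply(ph$labels$data > 0L, 3, sum))
  lz <- ph$labels$data[, , z]
  bg <- ph$mask[, , z] & lz == 0L
  m <- mean(out$data[, , z][bg])
  expect_lt(abs(mean(out$data[, , z][lz == 1L]) - m), 1e-9)  # core isointense
  expect_gt(mean(out$data[, , z][lz == 2L]), m + 0.1)        # rim untouched
})

test_that("within-lesion SNR matches hand computation and flags uniformity", {
  d <- array(0, c(4, 2, 2)); d[1:4] <- c(2, 2, 4, 4)
  lab <- array(0L, c(4, 2, 2)); lab[1:4] <- 1L
  v <- lf_volume(d, c(1, 1, 1))
  expect_equal(within_lesion_snr(v, label_map(lab, c(1, 1, 1))), 3)
  d2 <- array(0, c(4, 2, 2)); d2[1:4] <- 5
  snr2 <- within_lesion_snr(lf_volume(d2, c(1, 1, 1)), label_map(lab, c(1, 1, 1)))
  expect_identical(as.numeric(snr2), Inf)
  expect_true(attr(snr2, "homogeneous"))
  # adding high-variance voxels strictly decreases SNR
  d3 <- array(0, c(4, 2, 2)); d3[1:8] <- c(2, 2, 4, 4, 9, 0.1, 8, 0.2)
  lab3 <- array(0L, c(4, 2, 2)); lab3[1:8] <- 1L
  expect_lt(within_lesion_snr(lf_volume(d3, c(1, 1, 1)),
                              label_map(lab3, c(1, 1, 1))), 3)
})

test_that("homogeneity selection ranks by SNR with stable ties", {
  mk <- function(vals) {
    d <- array(0, c(4, 2, 2)); d[seq_along(vals)] <- vals
    lab <- array(0L, c(4, 2, 2)); lab[seq_along(vals)] <- 1L
    list(volume = lf_volume(d, c(1, 1, 1)), labels = label_map(lab, c(1, 1, 1)))
  }
  cohort <- list(mk(c(1, 3)), mk(c(2, 2.5)), mk(c(3, 3.3)), mk(c(4, 4.1)))
  kept <- select_homogeneous(cohort, 0.5)
  expect_identical(attr(kept, "kept"), c(3L, 4L))
  expect_length(select_homogeneous(cohort, 1.0), 4L)
  expect_error(select_homogeneous(list(), 0.5), "empty")
  # fraction 0.5 over an even cohort keeps exactly half
  cohort8 <- c(cohort, cohort)
  expect_length(select_homogeneous(cohort8, 0.5), 4L)
})
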