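test_that("slice labels follow the at-least-one-lesion-pixel rule", {
  ph <- tiny_phantom(seed = 1, z_extent = 3)
  recs <- extract_slices(ph$volume, ph$labels, "P1", "HF")
  tab <- slice_table(recs)
  # oracle: direct per-slice pixel counting on the label array
  for (i in seq_len(nrow(tab))) {
    z <- tab$slice_index[i] + 1L
    n_lesion <- sum(ph$labels$data[, , z] > 0L)
    expect_identical(tab$label[i], as.integer(n_lesion > 0L))
    expect_equal(tab$lesion_area_cm2[i], n_lesion * 0.01)
  }
  expect_equal(sum(tab$label), 3)    # z extent of the lesion
  # records exist exactly for slices intersecting the mask
  expect_identical(tab$slice_index + 1L, which(apply(ph$mask, 3, any)))
})

test_that("a single lesion pixel at low-field spacing gives area 0.0256 cm2", {
  d <- array(1, c(16, 16, 3))
  msk <- array(TRUE, c(16, 16, 3))
  lab <- array(0L, c(16, 16, 3)); lab[8, 8, 2] <- 1L
  recs <- extract_slices(lf_volume(d, c(1.6, 1.6, 5), msk),
                         label_map(lab, c(1.6, 1.6, 5)), "P1", "simLF")
  tab <- slice_table(recs)
  expect_equal(tab$lesion_area_cm2[tab$label == 1L], 0.0256)
  expect_equal(tab$lesion_area_cm2[tab$label == 0L], c(0, 0))
  expect_equal(tab$lesion_contrast[tab$label == 0L], c(0, 0))
})

test_that("per-slice areas integrate to the 3-D lesion volume", {
  ph <- tiny_phantom(seed = 5, area_cm2 = 6, z_extent = 5)
  tab <- slice_table(extract_slices(ph$volume, ph$labels, "P1", "HF"))
  vol_from_slices <- sum(tab$lesion_area_cm2) * 0.3        # 3 mm = 0.3 cm
  vol_direct <- sum(ph$labels$data > 0L) * (0.1 * 0.1 * 0.3)
  expect_equal(vol_from_slices, vol_direct, tolerance = 1e-12)
})

test_that("patient splits are seeded, disjoint and correctly sized", {
  ids <- sprintf("p%02d", 1:20)
  s1 <- split_by_patient(ids, 0.9, seed = 3)
  s2 <- split_by_patient(ids, 0.9, seed = 3)
  expect_identical(s1, s2)
  expect_length(s1$train_patients, 18L)
  expect_length(s1$test_patients, 2L)
  expect_length(intersect(s1$train_patients, s1$test_patients), 0L)
  expect_setequal(c(s1$train_patients, s1$test_patients), ids)
  s3 <- split_by_patient(c("a", "b"), 0.5, seed = 1)
  expect_length(s3$train_patients, 1L)
  expect_length(s3$test_patients, 1L)
  expect_error(split_by_patient("only", 0.5, 1), "at least 2")
  expect_error(split_by_patient(c("a", "a", "b"), 0.5, 1), "unique")
})

test_that("flip augmentation is a seeded involution that never touches tests", {
  recs <- toy_record_set(3, 3, seed = 2)
  aug1 <- augment_flip(recs, seed = 9)
  aug2 <- augment_flip(recs, seed = 9)
  expect_identical(lapply(aug1, `[[`, "pixels"), lapply(aug2, `[[`, "pixels"))
  flipped <- vapply(aug1, function(r) isTRUE(r$flipped), logical(1))
  expect_true(any(flipped))
  # flipping a flipped record restores the original pixels
  for (i in which(flipped)) {
    again <- aug1[[i]]$pixels[, rev(seq_len(ncol(aug1[[i]]$pixels)))]
    expect_identical(again, recs[[i]]$pixels)
    expect_identical(aug1[[i]]$label, recs[[i]]$label)
    expect_identical(aug1[[i]]$lesion_area_cm2, recs[[i]]$lesion_area_cm2)
  }
  test_recs <- toy_record_set(1, 1, seed = 3, split = "test")
  expect_error(augment_flip(test_recs, 1), "test records")
})

test_that("split assignment enforces full patient coverage", {
  recs <- toy_record_set(2, 2, seed = 4)
  ids <- vapply(recs, `[[`, character(1), "patient_id")
  man <- split_by_patient(ids, 0.5, seed = 2)
  out <- assign_split(recs, man)
  expect_true(all(vapply(out, `[[`, character(1), "split") %in%
                    c("train", "test")))
  bad <- structure(list(train_patients = "zzz", test_patients = "yyy",
                        ratio = 0.5, seed = 1L), class = "split_manifest")
  expect_error(assign_split(recs, bad), "neither split")
})

test_that("misaligned volume and labels are rejected", {
  ph <- tiny_phantom(seed = 6)
  lab <- label_map(array(0L, c(10, 10, 4)), c(1, 1, 3))
  expect_error(extract_slices(ph$volume, lab, "P1", "HF"), "misaligned")
})
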