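test_that("AUC matches pairwise enumeration, including tie handling", {
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.1))$auc, 0.75)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))$auc, 1)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.5, 4))$auc, 0.5)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")
  enumerate_auc <- function(y, s) {
    pos <- s[y == 1]; neg <- s[y == 0]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  for (i in 1:20) {
    y <- withr::with_seed(i, rbinom(20, 1, 0.4))
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    s <- withr::with_seed(100 + i, round(runif(20), 2))   # forces some ties
    expect_equal(roc_auc(y, s)$auc, enumerate_auc(y, s), tolerance = 1e-12)
  }
})

test_that("ROC points rise monotonically from the origin", {
  y <- withr::with_seed(2, rbinom(30, 1, 0.5))
  s <- withr::with_seed(3, runif(30))
  pts <- roc_auc(y, s)$roc_points
  expect_equal(pts$fpr[1], 0)
  expect_equal(pts$tpr[1], 0)
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
  expect_equal(pts$fpr[nrow(pts)], 1)
  expect_equal(pts$tpr[nrow(pts)], 1)
})

test_that("F1 follows the precision/recall formula with degenerate flags", {
  expect_equal(f1_score(c(1, 1, 0), c(1, 1, 0)), 1)
  # TP=3, FP=1, FN=1 -> P = R = 0.75
  expect_equal(as.numeric(f1_score(c(1, 1, 1, 1, 0), c(1, 1, 1, 0, 1))), 0.75)
  all_neg <- f1_score(c(1, 0, 1), c(0, 0, 0))
  expect_equal(as.numeric(all_neg), 0)
  expect_true(attr(all_neg, "degenerate"))
})

test_that("null-model F1 matches its closed form at two prevalences", {
  for (prev in c(0.3, 0.5)) {
    n <- 400L
    labels <- rep(c(1L, 0L), times = c(round(prev * n), n - round(prev * n)))
    res <- null_model_f1(labels, trials = 1000L, seed = 7)
    closed <- 2 * (prev * 0.5) / (prev + 0.5)
    expect_lt(abs(res$mean - closed), 3 * res$sd)
    expect_gt(res$sd, 0)
  }
})

test_that("null-model F1 spread shrinks with the number of slices", {
  lab_small <- rep(c(1L, 0L), times = c(30, 70))
  lab_big <- rep(c(1L, 0L), times = c(120, 280))
  sd_small <- null_model_f1(lab_small, 400L, seed = 1)$sd
  sd_big <- null_model_f1(lab_big, 400L, seed = 2)$sd
  expect_lt(sd_big, sd_small)
})

test_that("DeLong test agrees with brute-force structural components", {
  y <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  sa <- c(0.91, 0.64, 0.83, 0.45, 0.52, 0.13, 0.28, 0.71, 0.09, 0.33)
  sb <- c(0.88, 0.55, 0.61, 0.50, 0.49, 0.21, 0.30, 0.66, 0.12, 0.41)
  res <- delong_test(y, sa, sb)
  expect_equal(res$z, brute_delong(y, sa, sb), tolerance = 1e-8)
  ident <- delong_test(y, sa, sa)
  expect_equal(ident$z, 0)
  expect_equal(ident$p_value, 1)
  expect_error(delong_test(y, sa, sb[-1]), "same length")
})

test_that("DeLong test agrees with the reference implementation", {
  skip_if_not_installed("pROC")
  y <- withr::with_seed(5, rbinom(40, 1, 0.5))
  sa <- withr::with_seed(6, y + rnorm(40))
  sb <- withr::with_seed(7, 0.8 * y + rnorm(40))
  res <- delong_test(y, sa, sb)
  ref <- pROC::roc.test(pROC::roc(y, sa, quiet = TRUE),
                        pROC::roc(y, sb, quiet = TRUE),
                        method = "delong", paired = TRUE)
  expect_equal(res$z, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
  resu <- delong_test_unpaired(y, sa, y, sb)
  refu <- suppressWarnings(
    pROC::roc.test(pROC::roc(y, sa, quiet = TRUE),
                   pROC::roc(y, sb, quiet = TRUE),
                   method = "delong", paired = FALSE))
  expect_equal(resu$z, unname(refu$statistic), tolerance = 1e-10)
})

test_that("sensitivity regression recovers a known generative model", {
  set.seed(17)
  n <- 600
  area <- runif(n, 0, 2)
  contrast <- rnorm(n)
  detected <- rbinom(n, 1, plogis(-1 + 2 * area))
  res <- sensitivity_regression(detected, area, contrast)
  expect_gt(res$coef["area"], 0)
  expect_lt(res$p_value["area"], 0.01)
  expect_gt(res$p_value["contrast"], 0.05)
  expect_error(sensitivity_regression(detected[1:20], rep(1, 20), rep(2, 20)),
               "constant")
})

test_that("separated regressions fall back to a flagged penalized fit", {
  n <- 60
  area <- c(rep(0, 30), rep(2, 30))
  detected <- as.integer(area > 1)
  contrast <- withr::with_seed(9, rnorm(n))
  res <- sensitivity_regression(detected, area, contrast)
  expect_true(res$separation)
  expect_true(all(is.finite(res$z)))
  expect_gt(res$coef["area"], 0)
})

test_that("sensitivity-ratio curve reduces to known endpoints", {
  det <- c(1, 1, 0, 1, 0, 1)
  area <- c(0.5, 0.8, 1.5, 3, 6, 12)
  same <- sensitivity_ratio_curve(det, area, det, area,
                                  size_thresholds_cm2 = c(1, 4, Inf))
  expect_true(all(same$ratio == 1))
  # LF misses everything below 1 cm^2; HF detects them
  lf_det <- c(0, 0, 0, 1, 0, 1)
  cur <- sensitivity_ratio_curve(det, area, lf_det, area,
                                 size_thresholds_cm2 = c(1, Inf))
  expect_equal(cur$ratio[1], 0)
  expect_equal(cur$ratio[2], mean(lf_det) / mean(det))
  expect_false(cur$stable[1])                     # < 5 qualifying slices
  # zero HF sensitivity in a bin is flagged as NA
  cur2 <- sensitivity_ratio_curve(c(0, 0), c(0.5, 0.6), c(1, 1), c(0.5, 0.6),
                                  size_thresholds_cm2 = 1)
  expect_true(is.na(cur2$ratio))
})

test_that("sliding-window classification matches brute-force averaging", {
  scores <- c(0.1, 0.2, 0.9, 0.8, 0.7, 0.1, 0.05, 0.3, 0.2, 0.6)
  res <- patient_classify(scores, slice_thickness_mm = 5, window_mm = 15,
                          threshold = 0.5)
  expect_identical(res$window_slices, 3L)          # ~1.5 cm at 5 mm slices
  brute <- vapply(seq_along(scores), function(i)
    mean(scores[max(1, i - 1):min(length(scores), i + 1)]), numeric(1))
  expect_equal(res$windowed_trace, brute, tolerance = 1e-12)
  expect_true(res$decision)
  expect_true(patient_classify(rep(1, 4), 5, threshold = 1)$decision)
  expect_identical(patient_classify(scores, 3, 15)$window_slices, 5L)
  expect_identical(patient_classify(scores, 20, 15)$window_slices, 1L)
})

test_that("patient threshold maximizes training accuracy, ties upward", {
  thr <- choose_patient_threshold(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(as.numeric(thr), 0.8)
  expect_equal(attr(thr, "accuracy"), 1)
  deg <- choose_patient_threshold(c(0.5, 0.5), c(1, 0))
  expect_true(attr(deg, "degenerate"))
  # accuracy at the returned threshold is maximal over all observed scores
  ms <- c(0.95, 0.7, 0.65, 0.4, 0.3, 0.25)
  y <- c(1, 1, 0, 1, 0, 0)
  thr2 <- choose_patient_threshold(ms, y)
  accs <- vapply(sort(unique(ms)), function(t) mean((ms >= t) == y), numeric(1))
  expect_equal(attr(thr2, "accuracy"), max(accs))
})
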