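# Statistical harness: ROC/AUC (Mann-Whitney with midrank ties), F1,
# 1000-trial random-chance null model, DeLong tests for correlated (same
# slices) and independent (different slice grids) ROC curves, logistic
# regression of detection sensitivity on lesion size and intensity with
# Wald tests, sensitivity-ratio-versus-size curves, and sliding-window
# per-patient classification with an empirically maximized threshold.

#' ROC curve and AUC
#'
#' AUC is computed as the Mann-Whitney statistic (rank-based, midranks for
#' ties), which equals the trapezoidal area under the ROC curve over all
#' score thresholds.
#'
#' @param labels Binary vector (0/1); both classes must be present.
#' @param scores Numeric scores, higher = more lesion-like.
#' @return List with `auc` and `roc_points` (data frame of threshold, fpr,
#'   tpr).
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(scores), all(labels %in% 0:1))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- data.frame(threshold = c(Inf, thr),
                    fpr = c(0, vapply(thr, function(t)
                      mean(scores[labels == 0L] >= t), numeric(1))),
                    tpr = c(0, vapply(thr, function(t)
                      mean(scores[labels == 1L] >= t), numeric(1))))
  list(auc = auc, roc_points = pts)
}

#' F1 score
#'
#' Harmonic mean of precision and recall; 0 (flagged degenerate) when
#' precision + recall is 0 or no positive predictions exist.
#'
#' @param labels Binary ground truth.
#' @param predictions Binary predictions.
#' @return Scalar F1 in `[0, 1]`.
#' @export
f1_score <- function(labels, predictions) {
  labels <- as.integer(labels); predictions <- as.integer(predictions)
  stopifnot(length(labels) == length(predictions),
            all(labels %in% 0:1), all(predictions %in% 0:1))
  tp <- sum(labels == 1L & predictions == 1L)
  fp <- sum(labels == 0L & predictions == 1L)
  fn <- sum(labels == 1L & predictions == 0L)
  if (tp == 0L && (fp > 0L || fn > 0L)) return(structure(0, degenerate = TRUE))
  if (tp + fp == 0L || tp + fn == 0L) return(structure(0, degenerate = TRUE))
  p <- tp / (tp + fp); r <- tp / (tp + fn)
  2 * p * r / (p + r)
}

#' Random-chance null model for F1
#'
#' Per trial, predictions are drawn uniformly at random (probability 0.5
#' per slice, irrespective of prevalence) and the F1 against the true
#' labels is recorded; the mean and sd over trials benchmark chance-level
#' performance.
#'
#' @param labels Binary ground truth.
#' @param trials Number of trials (study design: 1000).
#' @param seed Integer seed.
#' @return List with `mean`, `sd` and `trials`.
#' @export
null_model_f1 <- function(labels, trials = 1000L, seed = 1L) {
  labels <- as.integer(labels)
  stopifnot(trials >= 1L, all(labels %in% 0:1))
  f1s <- with_seed(derive_seed(seed, "null-model"), {
    vapply(seq_len(trials), function(i)
      as.numeric(f1_score(labels, stats::runif(length(labels)) < 0.5)),
      numeric(1))
  })
  list(mean = mean(f1s), sd = stats::sd(f1s), trials = trials)
}

# Structural components of one ROC arm via midranks (fast DeLong).
#' @noRd
delong_components <- function(pos, neg) {
  m <- length(pos); n <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  auc <- (sum(r_all[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  list(auc = auc, v10 = v10, v01 = v01)
}

#' DeLong test for two correlated ROC curves
#'
#' Compares the AUCs of two score vectors computed on the identical slices
#' (paired design) using the structural-components covariance estimator;
#' two-sided normal p-value.
#'
#' @param labels Binary ground truth.
#' @param scores_a,scores_b Paired score vectors on the same slices.
#' @return List with `auc_a`, `auc_b`, `z`, `p_value` and `var_diff`.
#' @export
delong_test <- function(labels, scores_a, scores_b) {
  labels <- as.integer(labels)
  if (length(scores_a) != length(scores_b) || length(labels) != length(scores_a))
    stop("paired scores must have the same length as labels")
  pos <- labels == 1L; neg <- labels == 0L
  if (!any(pos) || !any(neg)) stop("both classes must be present")
  ca <- delong_components(scores_a[pos], scores_a[neg])
  cb <- delong_components(scores_b[pos], scores_b[neg])
  m <- sum(pos); n <- sum(neg)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
              (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- ca$auc - cb$auc
  if (var_diff <= 0) {
    z <- 0; p <- 1
  } else {
    z <- d / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = ca$auc, auc_b = cb$auc, z = z, p_value = p, var_diff = var_diff)
}

#' DeLong comparison of AUCs from two independent test sets
#'
#' For arms evaluated on different slice grids (e.g. high-field versus
#' simulated low-field), the structural-component variances are summed
#' without a covariance term.
#'
#' @param labels_a,scores_a First arm's labels and scores.
#' @param labels_b,scores_b Second arm's labels and scores.
#' @return List with `auc_a`, `auc_b`, `z`, `p_value` and `var_diff`.
#' @export
delong_test_unpaired <- function(labels_a, scores_a, labels_b, scores_b) {
  one <- function(labels, scores) {
    labels <- as.integer(labels)
    pos <- labels == 1L; neg <- labels == 0L
    if (!any(pos) || !any(neg)) stop("both classes must be present")
    cc <- delong_components(scores[pos], scores[neg])
    list(auc = cc$auc,
         var = stats::var(cc$v10) / sum(pos) + stats::var(cc$v01) / sum(neg))
  }
  a <- one(labels_a, scores_a); b <- one(labels_b, scores_b)
  var_diff <- a$var + b$var
  if (var_diff <= 0) return(list(auc_a = a$auc, auc_b = b$auc, z = 0,
                                 p_value = 1, var_diff = var_diff))
  z <- (a$auc - b$auc) / sqrt(var_diff)
  list(auc_a = a$auc, auc_b = b$auc, z = z,
       p_value = 2 * stats::pnorm(-abs(z)), var_diff = var_diff)
}

#' Youden-optimal score threshold
#'
#' The observed score maximizing TPR - FPR; used as the operating point
#' that converts scores into detection decisions for the sensitivity
#' analyses. Chosen on training data only.
#'
#' @param labels Binary ground truth.
#' @param scores Numeric scores.
#' @return Scalar threshold (decision rule: `score >= threshold`).
#' @export
youden_threshold <- function(labels, scores) {
  labels <- as.integer(labels)
  stopifnot(any(labels == 1L), any(labels == 0L))
  cand <- sort(unique(scores))
  j <- vapply(cand, function(t)
    mean(scores[labels == 1L] >= t) - mean(scores[labels == 0L] >= t),
    numeric(1))
  cand[which.max(j)]
}

#' Logistic regression of detection sensitivity on lesion size and intensity
#'
#' Fits `detected ~ area + contrast` on positive slices by maximum
#' likelihood and reports Wald z statistics and two-sided p-values per
#' covariate. On (quasi-)perfect separation the fit is flagged and redone
#' with a small L2 (ridge) penalty, with standard errors from the
#' penalized Fisher information.
#'
#' @param detected Binary vector: was the positive slice detected.
#' @param area_cm2 Per-slice lesion area covariate.
#' @param contrast Per-slice lesion contrast covariate.
#' @return List of class `sensitivity_regression` with `coef`, `se`, `z`,
#'   `p_value` (named: intercept, area, contrast), `separation` flag and
#'   `n`.
#' @export
sensitivity_regression <- function(detected, area_cm2, contrast) {
  detected <- as.integer(detected)
  stopifnot(length(area_cm2) == length(detected),
            length(contrast) == length(detected))
  if (length(detected) < 10L) stop("at least 10 positive slices are required")
  if (stats::var(area_cm2) == 0 && stats::var(contrast) == 0)
    stop("both covariates are constant")
  if (length(unique(detected)) < 2L)
    stop("detection outcome is constant; the sensitivity regression is undefined")
  df <- data.frame(y = detected, area = area_cm2, contrast = contrast)
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ area + contrast, family = stats::binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (!separation &&
      any(fit$fitted.values < 1e-7 | fit$fitted.values > 1 - 1e-7))
    separation <- TRUE
  if (separation) {
    # ridge-penalized Newton fallback with SEs from penalized information
    X <- cbind(1, df$area, df$contrast)
    lambda <- 1e-2
    w <- numeric(3)
    for (it in 1:50) {
      eta <- drop(X %*% w); p <- stats::plogis(eta)
      g <- drop(crossprod(X, p - df$y)) + lambda * c(0, w[-1])
      H <- crossprod(X, X * (p * (1 - p))) + diag(c(1e-6, lambda, lambda))
      step <- solve(H, g)
      w <- w - step
      if (max(abs(step)) < 1e-10) break
    }
    eta <- drop(X %*% w); p <- stats::plogis(eta)
    H <- crossprod(X, X * (p * (1 - p))) + diag(c(1e-6, lambda, lambda))
    se <- sqrt(diag(solve(H)))
    co <- w
  } else {
    sm <- summary(fit)$coefficients
    co <- sm[, "Estimate"]; se <- sm[, "Std. Error"]
  }
  z <- co / se
  pv <- 2 * stats::pnorm(-abs(z))
  nm <- c("intercept", "area", "contrast")
  structure(list(coef = stats::setNames(co, nm), se = stats::setNames(se, nm),
                 z = stats::setNames(z, nm), p_value = stats::setNames(pv, nm),
                 separation = separation, n = length(detected)),
            class = "sensitivity_regression")
}

#' @export
print.sensitivity_regression <- function(x, ...) {
  cat(sprintf("<sensitivity_regression> n = %d%s\n", x$n,
              if (x$separation) " (separation; penalized fit)" else ""))
  print(data.frame(coef = x$coef, se = x$se, z = x$z, p = x$p_value))
  invisible(x)
}

#' Sensitivity ratio as a function of lesion-size threshold
#'
#' For each size threshold `t`, the ratio of the low-field arm's detection
#' sensitivity to the high-field arm's over all positive slices with lesion
#' area below `t`. Thresholds where either arm has fewer than 5 qualifying
#' slices are flagged unstable; a threshold with zero high-field
#' sensitivity yields an `NA` ratio, flagged.
#'
#' @param hf_detected,hf_area Detection outcomes and areas of the
#'   high-field arm's positive slices.
#' @param lf_detected,lf_area Same for the simulated low-field arm.
#' @param size_thresholds_cm2 Increasing vector of area thresholds.
#' @return Data frame with threshold, per-arm sensitivity and counts,
#'   `ratio` and `stable`.
#' @export
sensitivity_ratio_curve <- function(hf_detected, hf_area, lf_detected, lf_area,
                                    size_thresholds_cm2 = c(1, 2, 4, 8, 16, Inf)) {
  stopifnot(length(hf_detected) == length(hf_area),
            length(lf_detected) == length(lf_area))
  rows <- lapply(size_thresholds_cm2, function(t) {
    hi <- hf_area < t; li <- lf_area < t
    n_hf <- sum(hi); n_lf <- sum(li)
    sens_hf <- if (n_hf > 0) mean(hf_detected[hi]) else NA_real_
    sens_lf <- if (n_lf > 0) mean(lf_detected[li]) else NA_real_
    ratio <- if (!is.na(sens_hf) && sens_hf > 0 && !is.na(sens_lf))
      sens_lf / sens_hf else NA_real_
    data.frame(threshold_cm2 = t, sens_hf = sens_hf, sens_lf = sens_lf,
               n_hf = n_hf, n_lf = n_lf, ratio = ratio,
               stable = n_hf >= 5L && n_lf >= 5L)
  })
  do.call(rbind, rows)
}

#' Sliding-window patient-level classification
#'
#' A moving mean over adjacent axial slice scores (window of approximately
#' 1.5 cm along z; 3 slices at the 5 mm low-field thickness) with truncated
#' edges; the patient is called positive iff the maximum windowed score
#' reaches the threshold.
#'
#' @param scores Per-slice scores ordered by z (inferior to superior).
#' @param slice_thickness_mm Slice thickness (mm).
#' @param window_mm Window length (mm), default 15.
#' @param threshold Decision threshold (see [choose_patient_threshold()]).
#' @return List with `windowed_trace`, `max_score`, `window_slices` and
#'   `decision` (logical).
#' @export
patient_classify <- function(scores, slice_thickness_mm, window_mm = 15,
                             threshold = 0.5) {
  stopifnot(length(scores) >= 1L, slice_thickness_mm > 0, window_mm > 0)
  w <- max(1L, as.integer(round(window_mm / slice_thickness_mm)))
  n <- length(scores)
  half_lo <- (w - 1L) %/% 2L
  half_hi <- w - 1L - half_lo
  trace <- vapply(seq_len(n), function(i)
    mean(scores[max(1L, i - half_lo):min(n, i + half_hi)]), numeric(1))
  mx <- max(trace)
  list(windowed_trace = trace, max_score = mx, window_slices = w,
       decision = mx >= threshold)
}

#' Empirically maximize the patient-level threshold on training patients
#'
#' Scans the finite set of observed maximum windowed scores and returns the
#' threshold maximizing patient-level accuracy; ties are broken toward the
#' higher threshold (favoring specificity). If every trace maximum is
#' identical the midpoint fallback (that value) is returned with a
#' degenerate flag.
#'
#' @param max_scores Per-patient maximum windowed scores (training set).
#' @param labels Binary per-patient ground truth.
#' @return Scalar threshold with attributes `accuracy` and `degenerate`.
#' @export
choose_patient_threshold <- function(max_scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(max_scores) == length(labels),
            any(labels == 1L), any(labels == 0L))
  if (length(unique(max_scores)) == 1L)
    return(structure(max_scores[1],
                     accuracy = mean((max_scores >= max_scores[1]) == labels),
                     degenerate = TRUE))
  cand <- sort(unique(max_scores))
  acc <- vapply(cand, function(t) mean((max_scores >= t) == labels), numeric(1))
  best <- max(acc)
  thr <- max(cand[acc == best])   # ties toward the higher threshold
  structure(thr, accuracy = best, degenerate = FALSE)
}
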