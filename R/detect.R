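# Pluggable slice classifier. The default baseline extracts physically
# scaled features from each slice (intensity quantiles of the z-scored
# in-mask histogram, smoothed bright-blob area in cm^2, left-right
# asymmetry, gradient entropy) and trains a seeded mini-batch SGD logistic
# regression on standardized features. The features are horizontal-flip
# invariant by construction, so the detector respects the training-time
# flip augmentation exactly. A DenseNet-121 configuration carrying the
# full-scale hyperparameters can be constructed, but training it requires a
# user-registered deep-learning backend (see [register_classifier_backend()]).

#' Classifier specification
#'
#' @param backbone `"baseline_features"` (default; feature-based SGD
#'   logistic regression) or `"densenet121"` (requires an external backend;
#'   its defaults follow the full-scale training recipe: 100 epochs,
#'   learning rate 0.002 with decay, batch size 32).
#' @param input_size Pixels per side slices are resized to by pixel-based
#'   backbones; metadata for the baseline.
#' @param epochs,batch_size,learning_rate Training hyperparameters.
#' @param decay Multiplicative learning-rate decay per epoch denominator
#'   (`lr_e = learning_rate / (1 + decay * e)`).
#' @param l2 L2 weight penalty of the baseline.
#' @param seed Integer seed for shuffling and initialization.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(backbone = c("baseline_features", "densenet121"),
                            input_size = 64L,
                            epochs = NULL, batch_size = NULL,
                            learning_rate = NULL, decay = 0.05,
                            l2 = 1e-4, seed = 1L) {
  backbone <- match.arg(backbone)
  defaults <- if (backbone == "densenet121")
    list(epochs = 100L, batch_size = 32L, learning_rate = 0.002)
  else
    list(epochs = 40L, batch_size = 32L, learning_rate = 0.1)
  spec <- list(backbone = backbone, input_size = as.integer(input_size),
               epochs = as.integer(epochs %||% defaults$epochs),
               batch_size = as.integer(batch_size %||% defaults$batch_size),
               learning_rate = learning_rate %||% defaults$learning_rate,
               decay = decay, l2 = l2, seed = as.integer(seed))
  stopifnot(spec$epochs >= 1L, spec$batch_size >= 1L, spec$learning_rate > 0)
  structure(spec, class = "classifier_spec")
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.classifier_spec <- function(x, ...) {
  cat(sprintf("<classifier_spec> %s: %d epochs, batch %d, lr %.3g, seed %d\n",
              x$backbone, x$epochs, x$batch_size, x$learning_rate, x$seed))
  invisible(x)
}

# Registry for external training backends (e.g. a deep-learning bridge).
.lofisim_backends <- new.env(parent = emptyenv())

#' Register a training backend for a classifier backbone
#'
#' @param backbone Backbone name (e.g. `"densenet121"`).
#' @param fn Function `(records, spec) -> model` where the model implements
#'   `predict_scores()`.
#' @export
register_classifier_backend <- function(backbone, fn) {
  stopifnot(is.character(backbone), is.function(fn))
  assign(backbone, fn, envir = .lofisim_backends)
  invisible(NULL)
}

#' Feature vector of one slice record
#'
#' Features are scale-aware (areas in cm^2 via the record's pixel spacing)
#' and invariant to horizontal flips and to global intensity scaling or
#' shifts of the slice.
#'
#' @param record A `slice_record`.
#' @return Named numeric vector.
#' @export
slice_features <- function(record) {
  px <- record$pixels
  msk <- record$mask
  v <- px[msk]
  n <- length(v)
  pix_area <- record$spacing_mm[1] * record$spacing_mm[2] / 100
  mu <- mean(v)
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) s <- 1
  z <- (px - mu) / s
  z[!msk] <- 0
  q <- stats::quantile((v - mu) / s, c(0.75, 0.9, 0.95, 0.99), names = FALSE)
  sigma_px <- max(1, 2 / record$spacing_mm[1])   # ~2 mm smoothing
  sz <- gaussian_smooth2(z, sigma_px)
  sz[!msk] <- 0
  # left-right mirror about the mask bounding-box midline
  cols <- range(which(apply(msk, 2, any)))
  sub <- z[, cols[1]:cols[2], drop = FALSE]
  subm <- msk[, cols[1]:cols[2], drop = FALSE]
  fl <- sub[, rev(seq_len(ncol(sub))), drop = FALSE]
  flm <- subm[, rev(seq_len(ncol(subm))), drop = FALSE]
  both <- subm & flm
  asym <- abs(sub - fl)
  asym_sm <- gaussian_smooth2(asym * both, sigma_px)
  c(log_mask_area = log(n * pix_area),
    q75 = q[1], q90 = q[2], q95 = q[3], q99 = q[4],
    zmax = max(z[msk]),
    frac_z1.5 = mean(z[msk] > 1.5),
    frac_z2.5 = mean(z[msk] > 2.5),
    smooth_zmax = max(sz[msk]),
    blob_area_cm2 = sum(sz[msk] > 1.2) * pix_area,
    blob_area_hi_cm2 = sum(sz[msk] > 2) * pix_area,
    asym_mean = if (any(both)) mean(asym[both]) else 0,
    asym_max = max(asym_sm),
    asym_area_cm2 = sum(asym_sm > 1) * pix_area,
    grad_entropy = as.numeric(gradient_entropy(px)))
}

#' @noRd
feature_matrix <- function(records) {
  t(vapply(records, slice_features, slice_features(records[[1]])))
}

#' Train a slice classifier
#'
#' The baseline backbone standardizes the training feature matrix and runs
#' seeded mini-batch SGD on the logistic loss with L2 penalty and a
#' decaying learning rate, logging the full-batch loss once per epoch.
#'
#' @param records Training `slice_record`s (train split only; both classes
#'   must be present).
#' @param spec A [classifier_spec()].
#' @return A model of class `lf_classifier` with `weights`, `center`,
#'   `scale`, `spec` and `log` (data frame of per-epoch loss).
#' @export
train_classifier <- function(records, spec = classifier_spec()) {
  stopifnot(inherits(spec, "classifier_spec"))
  if (any(vapply(records, function(r) identical(r$split, "test"), logical(1))))
    stop("training set contains test records (leakage)")
  y <- vapply(records, `[[`, integer(1), "label")
  if (length(unique(y)) < 2L)
    stop("training set must contain both classes")
  if (spec$backbone != "baseline_features") {
    fn <- mget(spec$backbone, envir = .lofisim_backends, ifnotfound = list(NULL))[[1]]
    if (is.null(fn))
      stop(sprintf("backbone '%s' requires a registered backend; see register_classifier_backend()",
                   spec$backbone))
    return(fn(records, spec))
  }
  X <- feature_matrix(records)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  Xs <- cbind(`(Intercept)` = 1, Xs)
  n <- nrow(Xs); p <- ncol(Xs)
  w <- numeric(p)
  loss <- numeric(spec$epochs)
  with_seed(derive_seed(spec$seed, "sgd"), {
    for (e in seq_len(spec$epochs)) {
      lr <- spec$learning_rate / (1 + spec$decay * (e - 1))
      ord <- sample.int(n)
      for (b in split(ord, ceiling(seq_along(ord) / spec$batch_size))) {
        eta <- drop(Xs[b, , drop = FALSE] %*% w)
        pr <- stats::plogis(eta)
        grad <- drop(crossprod(Xs[b, , drop = FALSE], pr - y[b])) / length(b) +
          spec$l2 * c(0, w[-1])
        w <- w - lr * grad
      }
      eta <- drop(Xs %*% w)
      loss[e] <- mean(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta)
    }
  })
  structure(list(weights = w, center = ctr, scale = scl, spec = spec,
                 log = data.frame(epoch = seq_len(spec$epochs), loss = loss)),
            class = "lf_classifier")
}

#' @export
print.lf_classifier <- function(x, ...) {
  cat(sprintf("<lf_classifier> %s, %d features, final loss %.4g\n",
              x$spec$backbone, length(x$weights) - 1L,
              x$log$loss[nrow(x$log)]))
  invisible(x)
}

#' Score slice records with a trained classifier
#'
#' @param model An `lf_classifier`.
#' @param records `slice_record`s, preprocessed identically to training.
#' @return Numeric vector of scores in `[0, 1]`, one per record and in the
#'   same order.
#' @export
predict_scores <- function(model, records) {
  stopifnot(inherits(model, "lf_classifier"))
  X <- feature_matrix(records)
  if (ncol(X) != length(model$center))
    stop("feature shape mismatch between model and records")
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  unname(stats::plogis(drop(cbind(1, Xs) %*% model$weights)))
}
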