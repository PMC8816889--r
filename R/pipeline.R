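# End-to-end simulated trial: generate a phantom cohort, build the
# high-field (HF) and simulated low-field (simLF) arms, make
# patient-exclusive splits, train one classifier per arm with identical
# hyperparameters and seed, and evaluate slice-level detection (AUC, F1,
# null model, cross-arm DeLong), size/intensity sensitivity (logistic
# regression with Wald tests, sensitivity-ratio-versus-size curve), the
# lesion-contrast ladder (separate classifiers at each contrast scale,
# restricted to the most homogeneous lesions), image quality (gradient
# entropy per arm), and sliding-window patient-level classification on a
# clean held-out cohort.

# Build both arms' slice records for one patient.
#' @noRd
patient_records <- function(p, true_params, seed) {
  hf <- extract_slices(p$volume, p$labels, p$patient_id, "HF")
  vol_lf <- reslice(p$volume)
  lab_lf <- reslice_labels(p$labels)
  deg <- apply_lf_transform(vol_lf, true_params,
                            derive_seed(seed, paste0("lf-", p$patient_id)))
  lf <- extract_slices(deg, lab_lf, p$patient_id, "simLF")
  list(hf = hf, lf = lf, lf_volume = deg)
}

# Stratified patient-exclusive split: lesional and control patients are
# split separately at the same ratio so both classes appear in both sets.
#' @noRd
stratified_split <- function(cohort, ratio, seed) {
  ids_les <- vapply(Filter(function(p) p$lesional, cohort), `[[`,
                    character(1), "patient_id")
  ids_ctl <- vapply(Filter(function(p) !p$lesional, cohort), `[[`,
                    character(1), "patient_id")
  s1 <- split_by_patient(ids_les, ratio, derive_seed(seed, "split-lesional"))
  s2 <- split_by_patient(ids_ctl, ratio, derive_seed(seed, "split-control"))
  structure(list(train_patients = sort(c(s1$train_patients, s2$train_patients)),
                 test_patients = sort(c(s1$test_patients, s2$test_patients)),
                 ratio = ratio, seed = as.integer(seed)),
            class = "split_manifest")
}

# Train one arm's classifier and score train/test records.
#' @noRd
train_and_score <- function(records, manifest, spec, seed) {
  records <- assign_split(records, manifest)
  train <- Filter(function(r) r$split == "train", records)
  test <- Filter(function(r) r$split == "test", records)
  stopifnot(!any(vapply(train, `[[`, character(1), "patient_id") %in%
                   vapply(test, `[[`, character(1), "patient_id")))
  train_aug <- augment_flip(train, derive_seed(seed, "augment"))
  model <- train_classifier(train_aug, spec)
  list(model = model,
       train = train, test = test,
       train_scores = predict_scores(model, train),
       test_scores = predict_scores(model, test))
}

# Slice-level evaluation of one arm at the training-derived operating point.
#' @noRd
arm_slice_eval <- function(arm, seed) {
  y_tr <- vapply(arm$train, `[[`, integer(1), "label")
  y_te <- vapply(arm$test, `[[`, integer(1), "label")
  thr <- youden_threshold(y_tr, arm$train_scores)
  pred <- as.integer(arm$test_scores >= thr)
  roc <- roc_auc(y_te, arm$test_scores)
  list(auc = roc$auc, roc_points = roc$roc_points,
       f1 = as.numeric(f1_score(y_te, pred)),
       null_f1 = null_model_f1(y_te, 1000L, derive_seed(seed, "null")),
       threshold = thr, labels = y_te, scores = arm$test_scores,
       predictions = pred,
       detected = pred,
       area = vapply(arm$test, `[[`, numeric(1), "lesion_area_cm2"),
       contrast = vapply(arm$test, `[[`, numeric(1), "lesion_contrast"))
}

# Patient-level traces for a set of patients under one arm's model.
#' @noRd
patient_traces <- function(model, per_patient_records, thickness_mm, window_mm) {
  lapply(per_patient_records, function(recs) {
    recs <- recs[order(vapply(recs, `[[`, integer(1), "slice_index"))]
    sc <- predict_scores(model, recs)
    patient_classify(sc, thickness_mm, window_mm, threshold = Inf)
  })
}

#' Run a two-arm simulated low-field trial on a phantom cohort
#'
#' @param seed Top-level trial seed; every randomized stage derives its own
#'   stream from it.
#' @param n_lesional,n_control Cohort sizes (default 30 + 30).
#' @param true_params Ground-truth degradation [transform_params()] used to
#'   build the simulated low-field arm.
#' @param split_ratio Patient-exclusive train fraction (stratified by
#'   lesional status).
#' @param classifier A [classifier_spec()]; the same spec and seed are used
#'   for both arms so differences isolate image quality.
#' @param contrast_scales Lesion-intensity scales (percent) of the contrast
#'   ladder; `NULL` skips the ladder.
#' @param homogeneity_fraction Fraction of lesional patients (ranked by
#'   within-lesion SNR) retained for the ladder.
#' @param ladder_ratio Train fraction of the ladder's own stratified split.
#' @param size_thresholds_cm2 Thresholds of the sensitivity-ratio curve.
#' @param small_area_cm2 Area below which a positive slice counts as
#'   "small" in the summary ratio.
#' @param patient_eval Logical: run the clean patient-level evaluation
#'   cohort (6 lesional with 6-20 cm^2 lesions + 6 controls).
#' @param window_mm Sliding-window length (mm) for patient classification.
#' @param grid_shape,spacing_mm Phantom grid of the high-field arm.
#' @param area_range_cm2 Lesion-size range of the cohort.
#' @param verbose Print stage progress.
#' @return A list of class `lf_trial`; see the elements `slice` (per-arm
#'   AUC/F1/null/threshold), `delong`, `regression`, `ratio_curve`,
#'   `ratio_small`, `ratio_all`, `ladder` (per-scale AUC), `quality`
#'   (per-arm gradient entropy and paired test) and `patient_level`.
#' @export
run_lf_trial <- function(seed = 1L,
                         n_lesional = 30L, n_control = 30L,
                         true_params = transform_params(0.4, 1.8, 0.2, 1.2),
                         split_ratio = 0.8,
                         classifier = classifier_spec(seed = 7L),
                         contrast_scales = c(100, 80, 60, 40, 20, 0),
                         homogeneity_fraction = 0.5,
                         ladder_ratio = 0.7,
                         size_thresholds_cm2 = c(1, 2, 4, 8, 16, Inf),
                         small_area_cm2 = 1,
                         patient_eval = TRUE,
                         window_mm = 15,
                         grid_shape = c(96, 96, 36),
                         spacing_mm = c(1, 1, 3),
                         area_range_cm2 = c(0.5, 20),
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))

  say("generating cohort of %d + %d patients", n_lesional, n_control)
  cohort <- generate_cohort(n_lesional, n_control,
                            seed = derive_seed(seed, "trial-cohort"),
                            grid_shape = grid_shape, spacing_mm = spacing_mm,
                            area_range_cm2 = area_range_cm2)
  say("building HF and simLF arms")
  built <- lapply(cohort, patient_records, true_params = true_params, seed = seed)
  hf_records <- do.call(c, lapply(built, `[[`, "hf"))
  lf_records <- do.call(c, lapply(built, `[[`, "lf"))

  manifest <- stratified_split(cohort, split_ratio, seed)

  say("training classifiers")
  arm_hf <- train_and_score(hf_records, manifest, classifier, seed)
  arm_lf <- train_and_score(lf_records, manifest, classifier, seed)

  ev_hf <- arm_slice_eval(arm_hf, derive_seed(seed, "eval-hf"))
  ev_lf <- arm_slice_eval(arm_lf, derive_seed(seed, "eval-lf"))
  dl <- delong_test_unpaired(ev_hf$labels, arm_hf$test_scores,
                             ev_lf$labels, arm_lf$test_scores)

  pos_hf <- ev_hf$labels == 1L
  pos_lf <- ev_lf$labels == 1L
  try_regression <- function(pos, ev) {
    if (sum(pos) < 10L) return(NULL)
    tryCatch(sensitivity_regression(ev$detected[pos], ev$area[pos],
                                    ev$contrast[pos]),
             error = function(e) NULL)
  }
  reg_hf <- try_regression(pos_hf, ev_hf)
  reg_lf <- try_regression(pos_lf, ev_lf)
  curve <- sensitivity_ratio_curve(ev_hf$detected[pos_hf], ev_hf$area[pos_hf],
                                   ev_lf$detected[pos_lf], ev_lf$area[pos_lf],
                                   size_thresholds_cm2)
  sens_hf_all <- mean(ev_hf$detected[pos_hf])
  sens_lf_all <- mean(ev_lf$detected[pos_lf])
  small_hf <- pos_hf & ev_hf$area < small_area_cm2
  small_lf <- pos_lf & ev_lf$area < small_area_cm2
  ratio_small <- if (sum(small_hf) > 0 && mean(ev_hf$detected[small_hf]) > 0)
    mean(ev_lf$detected[small_lf]) / mean(ev_hf$detected[small_hf]) else NA_real_

  say("image-quality comparison")
  ge_hf <- vapply(cohort, function(p) volume_gradient_entropy(p$volume)$F,
                  numeric(1))
  ge_lf <- vapply(built, function(b) volume_gradient_entropy(b$lf_volume)$F,
                  numeric(1))
  quality <- list(hf_mean = mean(ge_hf), hf_sd = stats::sd(ge_hf),
                  lf_mean = mean(ge_lf), lf_sd = stats::sd(ge_lf),
                  paired = paired_quality_test(ge_lf, ge_hf))

  ladder <- NULL
  if (!is.null(contrast_scales)) {
    say("contrast ladder over scales %s", paste(contrast_scales, collapse = ", "))
    ladder <- contrast_ladder(cohort, true_params, classifier, seed,
                              contrast_scales, homogeneity_fraction,
                              ladder_ratio)
  }

  patient_level <- NULL
  if (patient_eval) {
    say("clean patient-level evaluation cohort")
    patient_level <- patient_level_eval(arm_hf, arm_lf, manifest, cohort,
                                        built, true_params, seed, window_mm,
                                        grid_shape, spacing_mm)
  }

  structure(list(
    seed = seed,
    cohort_table = data.frame(
      patient_id = vapply(cohort, `[[`, character(1), "patient_id"),
      lesional = vapply(cohort, `[[`, logical(1), "lesional"),
      area_cm2 = vapply(cohort, `[[`, numeric(1), "area_cm2")),
    manifest = manifest,
    n_slices = c(hf_train = length(arm_hf$train), hf_test = length(arm_hf$test),
                 lf_train = length(arm_lf$train), lf_test = length(arm_lf$test)),
    slice = list(hf = ev_hf, lf = ev_lf),
    delong = dl,
    regression = list(hf = reg_hf, lf = reg_lf),
    ratio_curve = curve,
    ratio_small = ratio_small,
    ratio_all = sens_lf_all / sens_hf_all,
    sens_all = c(hf = sens_hf_all, lf = sens_lf_all),
    quality = quality,
    ladder = ladder,
    patient_level = patient_level,
    true_params = true_params,
    classifier = classifier),
    class = "lf_trial")
}

# Contrast ladder: separate classifiers per lesion-intensity scale on the
# most homogeneous lesional patients plus all controls; modulation happens
# on the HF volume before low-field degradation.
#' @noRd
contrast_ladder <- function(cohort, true_params, classifier, seed,
                            scales, homogeneity_fraction, ladder_ratio) {
  lesional <- Filter(function(p) p$lesional, cohort)
  controls <- Filter(function(p) !p$lesional, cohort)
  keep <- select_homogeneous(lesional, homogeneity_fraction)
  sub <- c(keep, controls)
  manifest <- stratified_split(sub, ladder_ratio, derive_seed(seed, "ladder"))
  # control records are scale-invariant; build them once
  ctl_records <- do.call(c, lapply(controls, function(p)
    patient_records(p, true_params, seed)$lf))
  out <- t(vapply(scales, function(s) {
    les_records <- do.call(c, lapply(keep, function(p) {
      vol <- modulate_contrast(p$volume, p$labels, contrast_level(s))
      deg <- apply_lf_transform(reslice(vol), true_params,
                                derive_seed(seed, paste0("lf-", p$patient_id)))
      extract_slices(deg, reslice_labels(p$labels), p$patient_id, "simLF")
    }))
    arm <- train_and_score(c(les_records, ctl_records), manifest, classifier, seed)
    c(roc_auc(vapply(arm$test, `[[`, integer(1), "label"), arm$test_scores)$auc,
      length(arm$test))
  }, numeric(2)))
  data.frame(scale_percent = scales, auc = out[, 1], n_test = as.integer(out[, 2]))
}

# Clean patient-level cohort: 6 lesional patients with large (6-20 cm^2)
# high-contrast lesions plus 6 controls, scored by the already-trained arm
# models at the threshold maximizing accuracy on the training patients.
#' @noRd
patient_level_eval <- function(arm_hf, arm_lf, manifest, cohort, built,
                               true_params, seed, window_mm,
                               grid_shape, spacing_mm) {
  clean <- generate_cohort(6L, 6L, seed = derive_seed(seed, "clean-cohort"),
                           grid_shape = grid_shape, spacing_mm = spacing_mm,
                           area_range_cm2 = c(6, 20))
  clean_built <- lapply(clean, patient_records, true_params = true_params,
                        seed = derive_seed(seed, "clean"))
  one_arm <- function(arm, key, thickness) {
    train_ids <- manifest$train_patients
    by_patient <- split(seq_along(arm$train),
                        vapply(arm$train, `[[`, character(1), "patient_id"))
    tr_traces <- lapply(by_patient, function(ix) {
      recs <- arm$train[ix]
      ord <- order(vapply(recs, `[[`, integer(1), "slice_index"))
      patient_classify(arm$train_scores[ix][ord], thickness, window_mm, Inf)
    })
    tr_labels <- vapply(names(tr_traces), function(id)
      cohort[[which(vapply(cohort, `[[`, character(1), "patient_id") == id)]]$lesional,
      logical(1))
    thr <- choose_patient_threshold(
      vapply(tr_traces, `[[`, numeric(1), "max_score"), as.integer(tr_labels))
    test_recs <- lapply(clean_built, `[[`, key)
    traces <- patient_traces(arm$model, test_recs, thickness, window_mm)
    decisions <- vapply(traces, function(t) t$max_score >= thr, logical(1))
    truth <- vapply(clean, `[[`, logical(1), "lesional")
    list(threshold = as.numeric(thr),
         threshold_accuracy = attr(thr, "accuracy"),
         decisions = decisions, truth = truth,
         max_scores = vapply(traces, `[[`, numeric(1), "max_score"),
         traces = traces,
         sensitivity = mean(decisions[truth]),
         specificity = mean(!decisions[!truth]))
  }
  list(hf = one_arm(arm_hf, "hf", spacing_mm[3]),
       lf = one_arm(arm_lf, "lf", lf_target_spacing()[3]),
       patient_ids = vapply(clean, `[[`, character(1), "patient_id"))
}

#' @export
print.lf_trial <- function(x, ...) {
  cat("<lf_trial>\n")
  cat(sprintf("  slices: %s\n", paste(names(x$n_slices), x$n_slices,
                                      collapse = ", ", sep = "=")))
  cat(sprintf("  AUC: HF %.3f, simLF %.3f (DeLong p = %.3g)\n",
              x$slice$hf$auc, x$slice$lf$auc, x$delong$p_value))
  cat(sprintf("  F1: HF %.3f, simLF %.3f (null %.3f +/- %.3f)\n",
              x$slice$hf$f1, x$slice$lf$f1,
              x$slice$lf$null_f1$mean, x$slice$lf$null_f1$sd))
  cat(sprintf("  gradient entropy: HF %.2f, simLF %.2f\n",
              x$quality$hf_mean, x$quality$lf_mean))
  cat(sprintf("  sensitivity ratio: all %.3f, small lesions %.3f\n",
              x$ratio_all, x$ratio_small))
  if (!is.null(x$ladder)) {
    cat("  contrast ladder AUC:",
        paste(sprintf("%d%%=%.3f", x$ladder$scale_percent, x$ladder$auc),
              collapse = " "), "\n")
  }
  if (!is.null(x$patient_level)) {
    cat(sprintf("  patient-level: HF sens %.0f%% spec %.0f%%; simLF sens %.0f%% spec %.0f%%\n",
                100 * x$patient_level$hf$sensitivity,
                100 * x$patient_level$hf$specificity,
                100 * x$patient_level$lf$sensitivity,
                100 * x$patient_level$lf$specificity))
  }
  invisible(x)
}

#' Run a configured pipeline and write its reports to a directory
#'
#' Thin orchestration wrapper: runs [run_lf_trial()] under a configuration
#' list (or JSON/YAML file) and serializes the evaluation report (JSON
#' summary plus CSV tables of per-slice scores, ROC points, the
#' sensitivity-ratio curve, the contrast ladder and per-patient decisions).
#'
#' @param config A named list of [run_lf_trial()] arguments, or a path to a
#'   JSON/YAML file holding one. `seed` and classifier fields are honoured;
#'   `true_params` may be given as four named numbers.
#' @param out_dir Output directory (created if needed).
#' @return The `lf_trial` object, invisibly; files are written under
#'   `out_dir`.
#' @export
run_pipeline <- function(config = list(), out_dir = "lofisim_run") {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading YAML configs requires the 'yaml' package")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.null(config$true_params) && !inherits(config$true_params, "transform_params"))
    config$true_params <- do.call(transform_params, as.list(config$true_params))
  if (!is.null(config$classifier) && !inherits(config$classifier, "classifier_spec"))
    config$classifier <- do.call(classifier_spec, as.list(config$classifier))
  trial <- do.call(run_lf_trial, config)
  write_trial_report(trial, out_dir)
  invisible(trial)
}

#' Serialize an `lf_trial` report
#'
#' @param trial An `lf_trial` from [run_lf_trial()].
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_trial_report <- function(trial, out_dir) {
  stopifnot(inherits(trial, "lf_trial"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summ <- list(
    seed = trial$seed,
    auc = list(hf = trial$slice$hf$auc, simlf = trial$slice$lf$auc),
    f1 = list(hf = trial$slice$hf$f1, simlf = trial$slice$lf$f1),
    null_f1 = trial$slice$lf$null_f1,
    delong = trial$delong,
    gradient_entropy = list(hf = trial$quality$hf_mean,
                            simlf = trial$quality$lf_mean,
                            paired_p = trial$quality$paired$p_value,
                            effect_size = trial$quality$paired$effect_size),
    sensitivity_ratio = list(all = trial$ratio_all, small = trial$ratio_small),
    regression = lapply(trial$regression, function(r)
      list(coef = as.list(r$coef), z = as.list(r$z), p = as.list(r$p_value))),
    true_params = unclass(trial$true_params))
  if (!is.null(trial$patient_level))
    summ$patient_level <- list(
      hf = list(sensitivity = trial$patient_level$hf$sensitivity,
                specificity = trial$patient_level$hf$specificity),
      simlf = list(sensitivity = trial$patient_level$lf$sensitivity,
                   specificity = trial$patient_level$lf$specificity))
  jsonlite::write_json(summ, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(trial$ratio_curve, file.path(out_dir, "sensitivity_ratio.csv"),
                   row.names = FALSE)
  if (!is.null(trial$ladder))
    utils::write.csv(trial$ladder, file.path(out_dir, "contrast_ladder.csv"),
                     row.names = FALSE)
  for (arm in c("hf", "lf")) {
    ev <- trial$slice[[arm]]
    utils::write.csv(data.frame(label = ev$labels, predicted = ev$predictions,
                                area_cm2 = ev$area, contrast = ev$contrast),
                     file.path(out_dir, sprintf("slices_%s.csv", arm)),
                     row.names = FALSE)
    utils::write.csv(ev$roc_points,
                     file.path(out_dir, sprintf("roc_%s.csv", arm)),
                     row.names = FALSE)
  }
  utils::write.csv(trial$cohort_table, file.path(out_dir, "cohort.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}
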