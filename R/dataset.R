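# Slice-level classification datasets: one record per axial slice
# intersecting the brain mask, labeled "lesion present" if at least one
# ground-truth lesion pixel lies in the slice, with per-slice covariates
# (lesion area in cm^2 on the slice's own grid, lesion contrast) for the
# sensitivity analyses. Splits are patient-exclusive; augmentation is a
# seeded horizontal flip restricted to training records.

#' Extract slice records from a volume and its lesion segmentation
#'
#' @param volume A masked [lf_volume()].
#' @param labels An aligned [label_map()] (all zeros for controls).
#' @param patient_id Patient identifier string.
#' @param arm `"HF"` or `"simLF"`.
#' @return A list of `slice_record` objects, one per axial slice with at
#'   least one in-mask pixel. Each record holds `patient_id`,
#'   `slice_index` (0-based from inferior), `pixels`, `mask`,
#'   `spacing_mm` (in-plane + slice thickness), `label` (0/1),
#'   `lesion_area_cm2` (lesion pixel count times in-plane pixel area),
#'   `lesion_contrast` (mean lesion minus mean non-lesional intensity,
#'   divided by the non-lesional sd; 0 when no lesion), `arm` and `split`
#'   (`NA` until assigned).
#' @export
extract_slices <- function(volume, labels, patient_id, arm = c("HF", "simLF")) {
  stopifnot(inherits(volume, "lf_volume"), inherits(labels, "label_map"))
  arm <- match.arg(arm)
  if (!identical(dim(volume$data), dim(labels$data)))
    stop("volume and labels have misaligned shapes")
  if (is.null(volume$mask)) stop("volume must carry a brain mask")
  pix_area_cm2 <- volume$spacing_mm[1] * volume$spacing_mm[2] / 100
  out <- list()
  for (z in seq_len(dim(volume$data)[3])) {
    msk <- volume$mask[, , z]
    if (!any(msk)) next
    sl <- volume$data[, , z]
    lz <- labels$data[, , z]
    n_lesion <- sum(lz > 0L)
    contrast <- 0
    if (n_lesion > 0L) {
      bg <- msk & lz == 0L
      if (any(bg)) {
        sd_bg <- stats::sd(sl[bg])
        if (is.finite(sd_bg) && sd_bg > 0)
          contrast <- (mean(sl[lz > 0L]) - mean(sl[bg])) / sd_bg
      }
    }
    out[[length(out) + 1L]] <- structure(
      list(patient_id = patient_id, slice_index = z - 1L,
           pixels = sl, mask = msk, spacing_mm = volume$spacing_mm,
           label = as.integer(n_lesion > 0L),
           lesion_area_cm2 = n_lesion * pix_area_cm2,
           lesion_contrast = contrast, arm = arm, split = NA_character_),
      class = "slice_record")
  }
  out
}

#' Patient-exclusive train/test split
#'
#' Seeded permutation of patient IDs assigning `floor(ratio * N)` patients
#' (at least 1, at most N-1) to training; no patient appears in both sets.
#'
#' @param cohort_ids Character vector of patient IDs (`>= 2`).
#' @param ratio Target train fraction in `(0, 1)`; the study design uses
#'   an approximate 9:1 split.
#' @param seed Integer seed.
#' @return A list of class `split_manifest` with `train_patients`,
#'   `test_patients`, `ratio` and `seed`.
#' @export
split_by_patient <- function(cohort_ids, ratio = 0.9, seed = 1L) {
  cohort_ids <- as.character(cohort_ids)
  if (anyDuplicated(cohort_ids)) stop("patient IDs must be unique")
  n <- length(cohort_ids)
  if (n < 2L) stop("at least 2 patients are required to split")
  stopifnot(ratio > 0, ratio < 1)
  n_train <- min(max(floor(ratio * n), 1L), n - 1L)
  perm <- with_seed(derive_seed(seed, "patient-split"), sample(cohort_ids))
  structure(list(train_patients = sort(perm[seq_len(n_train)]),
                 test_patients = sort(perm[(n_train + 1L):n]),
                 ratio = ratio, seed = as.integer(seed)),
            class = "split_manifest")
}

#' @export
print.split_manifest <- function(x, ...) {
  cat(sprintf("<split_manifest> %d train / %d test patients (ratio %.2f, seed %d)\n",
              length(x$train_patients), length(x$test_patients), x$ratio, x$seed))
  invisible(x)
}

#' Assign split labels to slice records
#'
#' @param records List of `slice_record`s.
#' @param manifest A [split_by_patient()] manifest.
#' @return The records with `split` set to `"train"` or `"test"`; errors if
#'   a record's patient appears in neither set.
#' @export
assign_split <- function(records, manifest) {
  stopifnot(inherits(manifest, "split_manifest"))
  lapply(records, function(r) {
    if (r$patient_id %in% manifest$train_patients) r$split <- "train"
    else if (r$patient_id %in% manifest$test_patients) r$split <- "test"
    else stop(sprintf("patient %s is in neither split", r$patient_id))
    r
  })
}

#' Random horizontal-flip augmentation of training records
#'
#' Each record is flipped left-right with probability 0.5 (seeded), the
#' on-the-fly per-epoch semantics of training-time augmentation. Labels and
#' covariates are unchanged. Applying this to test records is a leakage
#' error.
#'
#' @param records Training `slice_record`s.
#' @param seed Integer seed.
#' @return The records, some with mirrored `pixels`/`mask` and
#'   `flipped = TRUE`.
#' @export
augment_flip <- function(records, seed = 1L) {
  if (any(vapply(records, function(r) identical(r$split, "test"), logical(1))))
    stop("augmentation must never touch test records")
  flips <- with_seed(derive_seed(seed, "flip"),
                     stats::runif(length(records)) < 0.5)
  mapply(function(r, fl) {
    if (fl) {
      r$pixels <- r$pixels[, rev(seq_len(ncol(r$pixels))), drop = FALSE]
      r$mask <- r$mask[, rev(seq_len(ncol(r$mask))), drop = FALSE]
      r$flipped <- TRUE
    }
    r
  }, records, flips, SIMPLIFY = FALSE)
}

#' Covariate table of a slice dataset
#'
#' @param records List of `slice_record`s.
#' @return A data frame with one row per record (patient_id, slice_index,
#'   label, lesion_area_cm2, lesion_contrast, arm, split).
#' @export
slice_table <- function(records) {
  data.frame(patient_id = vapply(records, `[[`, character(1), "patient_id"),
             slice_index = vapply(records, `[[`, integer(1), "slice_index"),
             label = vapply(records, `[[`, integer(1), "label"),
             lesion_area_cm2 = vapply(records, `[[`, numeric(1), "lesion_area_cm2"),
             lesion_contrast = vapply(records, `[[`, numeric(1), "lesion_contrast"),
             arm = vapply(records, `[[`, character(1), "arm"),
             split = vapply(records, `[[`, character(1), "split"),
             stringsAsFactors = FALSE)
}
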