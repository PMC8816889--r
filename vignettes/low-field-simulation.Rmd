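---
title: "Simulated clinical trials for low-field MRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated clinical trials for low-field MRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Portable 64 mT MRI scanners trade image quality for accessibility: lower
signal-to-noise, coarser resolution (here 1.6 x 1.6 x 5 mm), and reduced
tissue contrast relative to clinical 3 T systems. Before such a device is
deployed, one wants to know *which* pathology it can be expected to detect.
`lofisim` implements a simulated-trial answer: degrade high-field FLAIR
volumes to low-field quality with an empirically calibrated transform, train
identical slice classifiers on both arms, and compare detection as a
function of lesion size, intensity and contrast. Because the real paired
scans and large public cohorts such a study draws on cannot ship with a
package, `lofisim` includes a seeded synthetic phantom generator that plays
the role of the patient cohorts at desk scale, so the entire pipeline is
reproducible from a single integer seed.

## The degradation model

A high-field volume is first re-sliced to the low-field acquisition grid
(tri-linear interpolation on cell-centered grids covering the same physical
extent; `lf_target_spacing()` returns the 1.6 x 1.6 x 5 mm default). After
re-slicing, resolution matches the device but the signal-to-noise ratio is
still far too high, so a four-parameter cascade is applied by
`apply_lf_transform()`:

1. a white-noise field is smoothed with a fixed 0.5-voxel-std 3-D Gaussian
   kernel, scaled by `noise1_amplitude`, and added within the brain mask;
2. the image is smoothed with a 3-D Gaussian of parameterized std
   `blur_sigma_mm` (specified in millimetres and converted per axis, so the
   blur stays physically meaningful on the anisotropic grid);
3. a second noise field, smoothed with a parameterized kernel
   `noise2_sigma_mm` and scaled by `noise2_amplitude`, is added.

Noise enters only inside the brain mask and the result is re-masked, because
the pipeline is defined on skull-stripped images whose background is exactly
zero. Both noise fields are zero-mean unit-variance Gaussian before
smoothing: thermal magnitude noise at moderate SNR is approximately
Gaussian, and nothing in the calibration data constrains the distribution
beyond its first moments. Tissue-contrast changes with field strength,
eddy-current and permanent-magnet artifacts are deliberately *not* modelled;
the contrast-modulation experiment below probes the consequences of the
first omission.

## Calibrating the transform

`fit_transform_params()` chooses the four parameters by minimizing, over
training pairs of (re-sliced high-field, real low-field) volumes, the mean
of the squared standardized differences of the first three
intensity-histogram moments — mean, standard deviation, skewness — between
the simulated and the real low-field image. Design choices a user should
know:

* **Normalization.** Every volume entering the comparison, including each
  simulated image, is normalized to unit in-mask mean. This removes
  arbitrary scanner scaling, and it matters that the *simulated* image is
  re-normalized too: the blur bleeds intensity across the brain edge and
  lowers the raw mean by a few percent, which would otherwise bias the fit
  toward weaker blurs. The objective is invariant to rescaling both members
  of a pair.
* **Stochasticity.** Moments are averaged over a fixed number (default 4) of
  seeded noise realizations, using common random numbers across parameter
  values, so the objective is a deterministic function of the parameters.
* **Optimization.** The degraded image is *linear* in the two noise fields
  once the smoothing widths are fixed, so its moments are closed-form
  polynomials in the amplitudes given the cached realizations. The fit
  exploits this: a coarse grid plus Nelder-Mead polish searches the two
  smoothing widths, and at every evaluation the amplitude pair is solved by
  bounded quasi-Newton on the exact inner objective. Mean and sd
  differences are standardized by the target's sd; skewness is already
  dimensionless; the three terms carry equal weight.
* **Flags.** A fit that cannot improve on the coarse-grid optimum returns
  with a warning, never silently; the objective trace of accepted iterates
  is monotone non-increasing.

### What the three moments can and cannot identify

This is the package's most important limitation and is worth stating
plainly. The two noise stages enter the final image as independent smooth
Gaussian fields; the three matched moments see them only through their
*summed variance contribution*, because symmetric noise affects sd and
(dilutes) skewness through total variance alone. The blur width is
identified — it reshapes the signal histogram of each training volume in a
structure-dependent way — and so is the total noise level, but the split
between `noise1_amplitude` and `(noise2_amplitude, noise2_sigma_mm)` lies
on a ridge of near-equal objective: parameter-recovery experiments recover
`blur_sigma_mm` to within ~10% while the individual amplitudes land
anywhere on the ridge. For the package's purpose this is benign — every
point on the ridge produces statistically equivalent simulated images — but
the individual amplitude values should not be interpreted. A second floor
is estimation noise: a single real low-field volume of ~3 x 10^4 brain
voxels (fewer effective samples after smoothing-induced correlation)
determines its own skewness only to about +/-0.02, so standardized moment
residuals below ~10^-2 cannot be expected at desk-scale volume sizes.

## Gradient entropy as perceived quality

Image quality is scored per axial slice by the Shannon entropy of the
normalized absolute response to the `[1 -1]` finite-difference kernel,
applied along the in-plane horizontal axis exactly as the metric is
defined ("valid" convolution, so borders create no artificial gradients):

F = -sum h log2 h,  h = |[1 -1] * g| / sum |[1 -1] * g|.

Sharp images concentrate gradient mass at few edges (low entropy); blur and
noise spread it (high entropy), so lower F tracks radiologists' perception
of quality. Conventions chosen here: a constant slice returns 0 (the
entropy limit as the gradient mass concentrates), per-volume scores average
the slices intersecting the brain mask, and `paired_quality_test()`
compares arms with a paired t-test and a paired-samples effect size (mean
difference over the sd of differences). Whether the original metric summed
both in-plane directions is not documented; the single-axis form is
implemented as defined, and F is exactly invariant to intensity scaling and
shifts.

## The phantom cohort

`generate_phantom()` builds a skull-stripped FLAIR-like head: an
ellipsoidal brain with white matter, a cortical gray-matter shell and two
ventricular CSF compartments (CSF dark, as FLAIR suppresses it), normalized
to unit within-brain mean so contrast multipliers and moment matching are
scale-free. Realism choices that matter downstream:

* **Partial-volume smoothing** (0.6 mm default) softens tissue interfaces;
  real acquisitions never produce razor-sharp steps.
* **Acquisition noise** is added within the mask only (background stays
  exactly 0). The default sd of 0.005 puts the high-field arm in the
  structure-dominated gradient regime that real 3 T FLAIR occupies — most
  gradient mass at anatomy, not noise — which is what makes its gradient
  entropy low. Low-field noise comes from the transform, not the phantom.
* **Lesions** are superellipsoids with concentric sub-label shells (a core
  and rim with separate contrast multipliers, emulating multi-label tumor
  segmentations). The maximal axial cross-section selects exactly the
  number of pixels matching the requested area by ranking pixels on the
  superellipse implicit value, so achieved area is within one pixel area of
  the request; other slices taper ellipsoidally. Lesion voxels are painted
  as multiplier x (slice's non-lesional in-mask mean), so a multiplier of 1
  is isointense by construction.
* **Mass effect** is a radial displacement field decaying exponentially
  (18 mm length scale) from the lesion centroid, applied by backward
  tri-linear resampling — the cheapest deformation that produces
  midline-shift-like structure. It is what keeps isointense lesions
  detectable.

`generate_cohort()` draws trial patients: maximal lesion areas log-uniform
over 0.5-20 cm^2 (the range spanned by glioma, stroke and MS cohorts), rim
contrast uniform in 1.6-2.0, z extent proportional to lesion diameter,
mass-effect amplitude sqrt(area) mm, and per-patient noise in 0.004-0.008.
What the phantoms do **not** emulate: real anatomical variability, cortical
folding, multi-focal lesions, infiltrative boundaries, or any
sequence-physics contrast. Passing tests on phantoms therefore demonstrate
that the *pipeline* behaves as designed, not that a particular device will
achieve these numbers on patients.

## Contrast modulation and homogeneity selection

`modulate_contrast()` scales lesion intensities toward the slice's
non-lesional in-mask mean, per axial slice and per sub-label:
v' = m + (s/100) (v - m). This is the unique affine map that is the
identity at 100% and achieves the exact isointensity definition (mean
lesion intensity equal to the slice's non-lesional mean) at 0%. Modulation
happens on the high-field volume *before* the low-field transform, so
degraded images of reduced-contrast lesions are what the classifier sees.
`within_lesion_snr()` (mean/sd of lesion voxels, population sd) ranks
lesions by homogeneity, and the contrast ladder restricts itself to the
top 50% so that isointense detection reflects structure rather than
residual intensity texture.

## Datasets, classifier, and the evaluation harness

Axial slices intersecting the brain mask become records labeled "lesion
present" if at least one segmentation pixel is present; covariates are the
per-slice lesion area (pixel count times in-plane pixel area, on each arm's
own grid so sizes are physical and comparable) and a contrast score (mean
lesion minus mean non-lesional intensity over the non-lesional sd). Splits
are patient-exclusive (~a 9:1 or 4:1 ratio, stratified by lesional status
in the pipeline) and seeded; horizontal-flip augmentation applies only to
training records and errors on test records.

The classifier is a pluggable interface. The default baseline extracts
flip-invariant, physically scaled slice features — z-scored intensity
quantiles, thresholded and smoothed bright-blob areas in cm^2, left-right
asymmetry about the mask midline (the structural signature of mass
effect), and gradient entropy — and trains a seeded mini-batch SGD logistic
regression (default 40 epochs, batch 32, learning rate 0.1 with decay,
small L2), logging loss per epoch. A DenseNet-121 configuration carrying
the full-scale recipe (100 epochs, learning rate 0.002, batch 32) can be
constructed, but training it requires registering an external deep-learning
backend; the package's scientific content is the comparison harness, and a
deep backbone is not needed to exercise it. Identical specs and seeds are
used for both arms of any comparison so differences isolate image quality.

Evaluation mirrors the full study: rank-based AUC (equal to the
Mann-Whitney statistic, midranks for ties), F1 at the Youden-optimal
threshold chosen on training scores, a 1000-trial random-chance null model
(predictions uniform at p = 0.5, irrespective of prevalence — disclosed and
configurable), DeLong's test for correlated ROC curves via structural
components (with an unpaired variant for cross-arm comparisons, since the
two arms have different slice grids), logistic regression of detection on
lesion size and intensity with Wald tests (ridge fallback on separation),
sensitivity-ratio-versus-size curves (thresholds with fewer than 5
qualifying slices flagged unstable), and sliding-window patient
classification: a moving mean over ~15 mm of adjacent slices (3 slices at
the 5 mm low-field thickness; truncated edges rather than padding, to avoid
fabricating scores), thresholded at the value maximizing patient-level
accuracy on training patients, ties broken toward the higher threshold to
favor specificity. No multiple-testing correction is applied; p-values are
reported unadjusted.

## Problem sizes and reproducibility

The standard desk-scale trial (`run_lf_trial()`) uses 30 lesional plus 30
control phantoms of 96 x 96 x 36 voxels at 1 x 1 x 3 mm, a stratified 0.8
split, a six-step contrast ladder on the homogeneous half of the lesional
patients (its own 0.7 split so the ladder's test set stays usable), and a
separate clean 12-patient cohort (6 large-lesion patients, 6 controls) for
patient-level evaluation; it completes in about two minutes on one CPU.
Calibration recovery experiments use 3 pairs at full phantom size and about
half a minute per fitting seed. Every random draw derives from one
top-level seed through tagged child seeds (`derive_seed()`), so identical
configurations are bit-reproducible and no stage perturbs another's stream.

## Known limitations

* The amplitude split of the noise cascade is not identifiable from
  three-moment matching (see above); only the blur and the total noise
  level are meaningful.
* Standardized moment residuals bottom out at the target volume's own
  moment-estimation noise (~10^-2 at these volume sizes).
* The phantom's structural signal (mass effect, ventricle displacement) is
  strong relative to real cohorts, so the contrast-ladder AUC declines more
  gently here than it would on real glioma data; the qualitative shape —
  monotone decline with above-chance isointense detection — is the tested
  property.
* Oblique acquisitions are not handled; inputs must be axis-aligned,
  pre-registered and skull-stripped. Registration, brain extraction, and
  field-strength contrast physics are out of scope by design.
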