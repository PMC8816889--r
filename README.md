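# lofisim — simulated clinical trials for low-field MRI

Portable low-field (64 mT) MRI scanners promise point-of-care brain imaging
at a fraction of the cost of clinical 3 T systems, but with much lower
signal-to-noise, coarser resolution (1.6 × 1.6 × 5 mm) and altered
contrast. Which pathology would such a device actually detect? `lofisim`
is an R toolkit for answering that question *in silico*, aimed at imaging
methodologists and device evaluators: it converts high-field FLAIR volumes
into simulated low-field images with an empirically calibrated degradation
model, trains identical slice classifiers on the high-field and simulated
low-field arms, and quantifies how detection changes with lesion size,
intensity and contrast. A seeded synthetic phantom generator stands in for
patient cohorts, so the entire trial runs on one CPU in minutes and is
bit-reproducible from a single integer seed.

## The model

**Degradation.** After re-slicing a volume *g* to the low-field grid, the
simulated image is

    g_LF = G_σb * ( g + a₁ · G₀.₅ * ε₁ ) + a₂ · G_σ₂ * ε₂

where `G_σ *` denotes 3-D Gaussian smoothing (σb, σ₂ in mm; the first
noise pre-smoothing is fixed at 0.5 voxels), ε₁, ε₂ are unit white-noise
fields drawn inside the brain mask, and θ = (a₁, σb, a₂, σ₂) are the four
transform parameters. θ is fitted by minimizing the squared standardized
differences of the first three intensity-histogram moments (mean, SD,
skewness) between simulated and real low-field images over training pairs.

**Quality.** Perceived image quality is scored by gradient entropy
`F = −Σ h log₂ h`, where `h` is the normalized absolute response of each
axial slice to the `[1 −1]` kernel; sharper images give lower F.

**Contrast.** Lesion intensities can be scaled toward isointensity per
axial slice and sub-label, `v′ = m + (s/100)(v − m)` with `m` the slice's
non-lesional in-mask mean, exactly isointense at s = 0.

**Evaluation.** Rank-based AUC, F1 at a Youden threshold chosen on
training data, a 1000-trial random-chance null model, DeLong tests,
logistic regression of per-slice detection on lesion area and contrast
(Wald tests), sensitivity-ratio-versus-size curves, and sliding-window
(~15 mm) per-patient classification with an empirically maximized
threshold.

See `vignette("low-field-simulation")` for assumptions, parameter
defaults, and known limitations.

## Worked example

```r
library(lofisim)
trial <- run_lf_trial(seed = 1)   # ~2 min on one CPU
print(trial)
```

```
<lf_trial>
  slices: hf_train=1536, hf_test=384, lf_train=912, lf_test=228
  AUC: HF 1.000, simLF 0.992 (DeLong p = 0.32)
  F1: HF 1.000, simLF 0.927 (null 0.255 +/- 0.038)
  gradient entropy: HF 9.07, simLF 9.43
  sensitivity ratio: all 0.974, small lesions 0.500
  contrast ladder AUC: 100%=1.000 80%=1.000 60%=1.000 40%=1.000 20%=0.999 0%=0.995
  patient-level: HF sens 100% spec 100%; simLF sens 100% spec 100%
```

Reading the output: per-slice detection is at parity between arms (DeLong
p = 0.32) and far above the chance-level F1 benchmark; the simulated
low-field arm's gradient entropy is higher (perceived quality lower), as a
degraded image's should be; the low-field sensitivity deficit concentrates
on lesions below 1 cm² (ratio 0.50) while overall sensitivity is nearly
preserved (0.974); AUC declines monotonically as lesion contrast is scaled
toward isointensity yet stays far above chance at 0% because mass effect
still deforms the surrounding anatomy; and windowed patient-level
classification is perfect on a clean held-out 6+6 cohort in both arms.

Individual stages are exposed as ordinary functions
(`generate_phantom()`, `reslice()`, `apply_lf_transform()`,
`fit_transform_params()`, `volume_gradient_entropy()`,
`modulate_contrast()`, `extract_slices()`, `train_classifier()`,
`roc_auc()`, `delong_test()`, …) and as a command-line front end,
`inst/cli/lofisim.R`, with subcommands `phantom`, `simulate`,
`fit-transform`, `quality`, `modulate` and `run` operating on NIfTI files.

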