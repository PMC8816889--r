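Package: lofisim
Title: Simulated Clinical Trials for Low-Field MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for running simulated clinical trials of low-field (64 mT)
    portable brain MRI. High-field FLAIR volumes are degraded to low-field
    quality through a four-parameter re-slicing, smoothing and noise cascade
    calibrated by matching the first three intensity-histogram moments of
    paired scans. The package generates seeded synthetic brain phantoms with
    controllable lesion size, contrast, substructure and mass effect; measures
    perceived image quality with gradient entropy; modulates lesion contrast
    down to isointensity; builds patient-exclusive slice-classification
    datasets; trains a pluggable baseline slice classifier; and evaluates
    detectability with ROC/AUC, F1, random-chance null models, DeLong tests,
    logistic sensitivity regression, sensitivity-ratio-versus-size curves and
    sliding-window patient-level classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
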