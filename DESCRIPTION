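Package: dalff
Title: Dynamic Amplitude of Low-Frequency Fluctuation Analysis for Resting-State fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the temporal dynamics of spontaneous brain
    activity in resting-state fMRI. Implements the sliding-window dynamic
    amplitude of low-frequency fluctuation (dALFF) statistic and its
    coefficient-of-variation summary map, desk-scale preprocessing
    (initial-volume removal, linear detrending, nuisance regression,
    Gaussian smoothing), voxelwise covariate-adjusted two-sample inference
    with Gaussian-random-field and permutation cluster correction,
    clinical-scale association statistics (Spearman correlation, ROC/AUC,
    pooled t, Pearson chi-square), and a seeded synthetic two-group cohort
    generator with planted amplitude-modulation effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
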