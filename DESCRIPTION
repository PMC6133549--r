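Package: prestimfc
Title: Pre-Stimulus Functional Connectivity and Noxious-Evoked BOLD
    Activity in Infant fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline linking pre-stimulus functional connectivity
    of the infant descending pain modulatory system to the magnitude of
    noxious-evoked BOLD responses. Provides calibration of a term-infant
    double-gamma haemodynamic response function and its three-function basis
    set, event-related design matrices with DVARS motion-outlier regressors,
    weighted ROI time-series extraction from 4D volumes with dropout and CSF
    voxel exclusion, FSL-style Gaussian running-line high-pass filtering,
    stimulus-locked three-volume pre-stimulus window correlations averaged
    into per-infant connectivity matrices, percent BOLD change
    quantification, age-adjusted association models, repeated-measures
    network comparisons, and a synthetic infant cohort generator with
    serialised ground truth for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
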