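Package: sourcefidelity
Title: Spatial Fidelity Evaluation of MEG/EEG Distributed Source Estimates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies the spatial fidelity of distributed MEG/EEG source
    estimators on fully synthetic fixtures. Simulates uniform cortical patch
    activations on a spherical source space, superposes structured resting-state
    noise at a controlled signal-to-noise ratio, reconstructs with five
    estimators (MNE, dSPM, sLORETA, eLORETA and the L21 mixed-norm estimate),
    and scores the reconstructions via analytic and empirical resolution
    matrices, peak localization error, spatial dispersion, center-of-gravity
    error, and a threshold-sweep ROC/PRC classifier analysis across an SNR
    grid, including a sigmoidal AUROC(SNR) model fit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    MASS,
    readr,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
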