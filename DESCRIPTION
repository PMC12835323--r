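Package: burstsupp
Title: Burst-Suppression Detection and Calibration for Intraoperative Frontal EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects burst suppression in multichannel frontal EEG by amplitude
    envelope thresholding with all-channel consensus, delimits burst-suppression
    epochs, and summarises suppressed time and the burst-suppression ratio (BSR).
    Detector thresholds are calibrated against expert interval annotations by
    minimum mean squared error under stratified k-fold cross-validation.
    Includes simulators for anesthesia-like EEG with ground-truth suppression
    episodes and for patient cohorts with an anesthetic-by-burst-suppression
    interaction on postoperative delirium risk, plus the cohort statistics:
    contingency analysis with Cohen's h and two-proportion power, rank-sum
    comparisons, and multivariable logistic models including the interaction
    decomposition into conditional odds ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
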