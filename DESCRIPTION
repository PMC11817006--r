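Package: thermalbreath
Title: Respiratory Pattern Analysis and COPD Screening from Thermal Video
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies respiration from side-view thermal video of a
    seated subject and screens for chronic obstructive pulmonary disease
    (COPD). Chest motion in one region of interest drives an optical-flow
    phase detector (inspiration vs expiration); a second region in front
    of the mouth accumulates exhalation-plume pixels by positive frame
    differencing. Four breath features (total respiratory volume, mean
    expiration/inspiration spacing, respiratory rate) are combined into a
    Z-score weighted composite score thresholded by Youden's index on the
    ROC curve. Includes a ground-truth-annotated synthetic thermal video
    generator, a median/Gaussian/bilateral denoising chain, ROC/AUC and
    evaluation utilities, a randomized weight search, and a command-line
    interface for the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    optparse,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
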