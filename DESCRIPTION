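Package: swirotome
Title: Shortwave-Infrared Otoscopy Analysis for Middle-Ear Effusion Detection
Version: 0.1.0
Authors@R: person("swirotome", "maintainers", email = "maintainers@swirotome.dev",
    role = c("aut", "cre"))
Description: A tested analysis pipeline for shortwave-infrared (SWIR) otoscopy
    of the tympanic membrane: reading and writing 14-bit SWIR frames, polygon
    annotations and cohort manifests; a synthetic cohort generator with
    ground-truth regions of interest (ROI) and effusion labels; classical and
    trainable encoder-decoder ROI segmentation; ROI intensity-statistics
    parameterization (average intensity alone, or an 11-statistic set); and
    decision-tree / random-forest effusion classifiers evaluated by repeated
    stratified 62/38 hold-out validation with confusion metrics, balanced
    accuracy and ROC/AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
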