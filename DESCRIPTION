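Package: bcrformer
Title: Multi-Region Multi-Sequence MRI Fusion for Biochemical Recurrence
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts post-prostatectomy biochemical recurrence from
    multiparametric prostate MRI. Builds intratumoral, peritumoral and
    periprostatic regions from tumor and prostate segmentations by
    millimetre-exact morphological dilation, converts co-registered T2WI-FS
    and DWI volumes into dual-channel region-masked axial slice stacks,
    and fuses them with encoded clinical covariates through a shared CNN
    slice encoder, an axial spatial embedding, and a transformer feature
    encoder with a per-slice recurrence head and patient-level aggregation.
    Includes a synthetic dual-sequence phantom generator with plantable
    region-specific signal, the stratified repeated cross-validation
    training protocol (AdamW, cosine annealing, early stopping,
    augmentation), and evaluation statistics (ROC/AUC, confusion metrics,
    percentile confidence intervals, DeLong comparison of correlated ROC
    curves).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    EBImage,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
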