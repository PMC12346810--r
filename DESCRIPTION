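Package: radpipe
Title: Reproducible Radiomics Pipelines with Frozen Deployment Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline framework for CT radiomics that makes every image
    processing step explicit, ordered and replayable. Volumes and masks are
    read from NIfTI, preprocessed (label merging, sub-zero-HU fat removal,
    soft-tissue windowing, intensity rescaling, isotropic spatial
    resampling), and summarized into IBSI-style first-order, shape, GLCM,
    GLRLM and GLSZM features with fixed-bin-width discretization. Feature
    post-processing (reference-batch ComBat harmonization and z-score
    normalization) is fitted on a training cohort and persisted as a plain
    statistics file, so that test and deployment runs apply bit-identical
    frozen transforms to new subjects. A gradient-boosted classifier,
    agreement metrics (Cohen's kappa, discordance, absolute probability
    differences) and a nine-variant pipeline-perturbation study quantify how
    sensitive model predictions are to preprocessing choices. A synthetic CT
    phantom cohort generator with a two-level reconstruction-kernel batch
    effect makes the whole chain testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    xgboost,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    sva,
    pROC
Config/testthat/edition: 3
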