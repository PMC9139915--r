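Package: petromics
Title: PET Radiomics Pipelines for Predicting Non-Response to Chemoradiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to build and evaluate machine-learning models that predict
    non-response to neoadjuvant chemoradiotherapy from baseline 18F-FDG PET
    scans. Covers SUV volume input/output and trilinear resampling, tumor
    delineation by SUV thresholding, extraction of a 143-feature radiomic
    registry (morphology, intensity, intensity histogram, and GLCM/GLRLM/
    GLSZM/NGTDM texture families computed from single merged 26-connectivity
    texture matrices), skewness-branched feature normalization, a four-stage
    feature-selection cascade enumerated as 24 strategies, a 144-pipeline
    classifier grid ranked by repeated cross-validated average precision,
    soft-voting ensembles, and precision-recall evaluation. Includes a
    synthetic PET cohort generator so every stage can be exercised and tested
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    igraph,
    glmnet,
    e1071,
    ranger,
    nnet,
    caret,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    withr,
    optparse,
    ggplot2
Config/testthat/edition: 3
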