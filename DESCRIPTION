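Package: CrossDecode
Title: Cross-Modal MVPA Decoding and Predictive Pattern Decomposition for
    Trial-Wise Brain Activity Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for multivariate pattern analysis of trial-wise fMRI
    activity maps. Implements cross-modal classifier generalization (training
    a linear support vector machine on word-evoked maps and testing on
    picture-evoked maps) with recursive feature elimination inside a
    meta-analytically defined search volume, exact binomial significance
    testing of out-of-sample accuracy, and jackknife/bootstrap/split-half
    stability analyses. A second stage performs semi-supervised factored
    logistic regression: a linear bottleneck autoencoder and a four-class
    softmax classifier share one set of latent components, trained jointly by
    RMSProp with Elastic-Net and latent-orthogonality penalties, yielding
    spatial component maps and per-condition contribution weights. Includes a
    seeded synthetic-data generator with latent spatial components, minimal
    NIfTI-1 volume input/output, grid resampling, mask construction from peak
    coordinate tables, and masked feature extraction, so the whole pipeline
    is testable end-to-end without scanner data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'classifier.R'
    'cross-decoding.R'
    'nifti-io.R'
    'pipeline.R'
    'rfe.R'
    'ssflr.R'
    'synthetic-data.R'
    'utils-internal.R'
    'volumes.R'
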