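Package: DeltaRadiomics
Title: Delta-Radiomics Texture Analysis of Longitudinal MR Setup Images
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A pipeline for delta-radiomics analysis of longitudinal
    MR-guided radiotherapy setup images. Per-fraction tumor regions of
    interest are dynamic-range limited, quantized to 64 gray levels by
    histogram equalization, and summarized by 39 three-dimensional texture
    features from gray-level co-occurrence, run-length, size-zone and
    neighborhood gray-tone difference matrices. Fraction images are binned
    by cumulative biologically effective dose (BED20, BED40), delta
    features are formed against the pre-treatment image, ranked by random
    forest Gini importance, and the top features are internally validated
    with a bootstrapped logistic-regression AUC procedure. A synthetic
    cohort generator provides fully reproducible test beds.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    randomForest,
    igraph,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, ImageAnalysis, Classification
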