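Package: FacePheno
Title: Quantitative Facial Phenotyping for Differential Diagnosis of
    Dysmorphic Syndromes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Landmark-based geometric morphometrics and multi-resolution
    block local binary pattern (LBP) texture descriptors for frontal face
    photographs, feeding a class-balanced linear support vector machine with
    recursive feature elimination (SVM-RFE) and leave-one-out
    cross-validation to discriminate two diagnostic classes (Noonan vs.
    Williams-Beuren syndrome) globally and within ethnicity strata.
    Includes per-feature Mann-Whitney screening, Fisher-exact model
    comparison, generalized Procrustes population-average appearance
    images, and a synthetic face-cohort generator with planted,
    calibrated effect sizes so the whole pipeline is testable without
    patient photographs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'landmarks.R'
    'catalog.R'
    'geometry.R'
    'atlas.R'
    'texture.R'
    'synthetic.R'
    'stats.R'
    'selection.R'
    'io.R'
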