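Package: petromics
Title: PET Radiomics Texture Features and Survival-Based Prognostic Modeling
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative analysis of [18F]FDG PET tumor images and
    for building survival-based prognostic indices from the resulting
    radiomic features. Implements fixed-threshold (40% of SUVmax) lesion
    segmentation, fixed-bin-number intensity discretization, intensity
    histogram, gray-level co-occurrence, run-length and size-zone texture
    matrices with the derived heterogeneity features, mesh-based asphericity,
    ROC/Youden feature screening with Bonferroni control, bootstrap
    multivariable Cox regression with Schoenfeld diagnostics, survival
    recursive partitioning, and concordance-index model comparison. A
    synthetic-data module generates PET-like tumor phantoms and clinical
    cohorts with proportional-hazards survival times so that the whole
    pipeline can be exercised and validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    survival,
    pROC,
    igraph,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
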