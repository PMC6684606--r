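Package: beemetab
Title: Metabolomics-Based Biomarker Discovery for Bumblebee Nutritional Stress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for metabolomics-based biomarker
    discovery of low-carbohydrate nutritional stress in bumblebee (Bombus
    terrestris) hemolymph. Provides a synthetic cohort generator that emulates a
    2x2x2 microcolony study design with pooled-QC bracketing and injection-order
    drift, QC-based coefficient-of-variation filtering and QC-pair drift
    normalization, from-scratch PCA and orthogonal partial least squares
    discriminant analysis (OPLS-DA) with cross-validated Q2, CV-ANOVA,
    permutation testing, VIP scores and S-plot coordinates, biomarker selection
    by multi-dataset VIP intersection and targeted two-way ANOVA screening,
    biomarker-panel evaluation with cross-validated classifiers, and metabolite
    pathway over-representation and topology-impact analysis against a bundled
    synthetic pathway library.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml,
    igraph,
    glmnet,
    pROC,
    randomForest,
    rpart,
    nnet,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
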