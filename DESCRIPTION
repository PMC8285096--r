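Package: lawstress
Title: Left Atrial Wall Stress from CT-Derived Wall Thickness and Its
    Prognostic Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measures left atrial wall thickness on CT-like intensity
    volumes by multi-Otsu segmentation, a Laplace-equation potential
    between endocardium and epicardium, and Euler streamline tracing;
    computes left atrial wall stress by the Law of Laplace with quartile
    stratification; trains a small one-dimensional convolutional network
    that predicts top-quartile wall stress from eight non-invasive
    clinical features (with a logistic-regression comparator); and
    analyses arrhythmia recurrence by stress group with Kaplan-Meier,
    log-rank and Cox proportional-hazards models. Ships synthetic shell
    phantoms with analytically known thickness and a proportional-hazards
    cohort simulator so the whole pipeline is testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    survival,
    RNifti,
    jsonlite,
    glmnet
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
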