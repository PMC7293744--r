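Package: rwsr
Title: Risk-Weighted Sparse Regression for Prognostic Gene Signatures
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers sparse prognostic gene signatures from expression and
    right-censored survival data with a risk-weighted sparse regression (RWSR)
    workflow: univariate Cox proportional-hazards screening with
    protective/risky classification, per-patient risk scores and risk
    probabilities, a robust weighted least-absolute-deviation regression with
    the SCAD penalty solved by local linear approximation, and cross-cohort
    intersection of supports. Includes a synthetic-cohort generator with
    planted prognostic structure, Kaplan-Meier and log-rank evaluation,
    IPCW time-dependent ROC/AUC, clinicopathological stratification and
    stage-by-risk grouping.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    survival,
    MASS,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Survival, GeneExpression, Regression, FeatureExtraction
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'simulate.R'
    'surveval.R'
    'wlad.R'
    'risk.R'
    'cox.R'
    'pipeline.R'
    'io.R'
    'cli.R'
    'rwsr-package.R'
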