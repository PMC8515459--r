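Package: tpng
Title: Total Plasma N-Glycome Derived Traits and Complication Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Computes derived structural glycosylation traits from total plasma
    N-glycome (TPNG) mass-spectrometric composition abundances and screens them
    for association with prevalent and incident complications of type 2 diabetes
    in two cohorts. Covers glycan composition parsing and structural
    classification (antennarity, bisection, galactosylation,
    linkage-differentiated sialylation), total-area normalization, replicate
    precision, empirical-Bayes batch correction, chained-equations covariate
    imputation, endpoint definitions including the albumin-to-creatinine-ratio
    nephropathy rule, per-trait logistic and Cox models, DerSimonian-Laird
    random-effects meta-analysis with I-squared heterogeneity, and
    Benjamini-Hochberg false discovery rate control. Includes a synthetic
    two-cohort generator so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    nnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    sva,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
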