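Package: eadi
Title: Empirical Anti-Inflammatory Diet Index Construction and Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and validates empirical anti-inflammatory diet indices
    from food-frequency-questionnaire intake data and inflammatory biomarker
    panels (hsCRP, IL-6, TNF-R1, TNF-R2). Provides a synthetic cohort
    generator with planted food effects and known ground truth, cohort
    preparation (frequency-to-servings conversion, food-group aggregation,
    exclusion rules, discovery/replication splitting), stability-based food
    selection combining a principal-component compound inflammation indicator
    with cross-validated Lasso regression, tertile-point index construction
    and scoring (including the packaged eADI-17 and eADI-15 definitions),
    and validation statistics: Spearman correlation tables, multivariable
    linear models of log2-scale biomarkers with back-transformed relative
    concentrations, trend tests, and stratified subgroup analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
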