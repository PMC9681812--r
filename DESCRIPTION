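Package: gaitprog
Title: Predicting Parkinson's Disease Progression from Instrumented Gait and
    Balance Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for asking whether baseline instrumented
    gait and balance measurements (iTUG, iSway) predict the annual rate of
    clinical progression in Parkinson's disease. Builds annualized
    progression outcomes from longitudinal visit data -- MDS-UPDRS total,
    LEDD, PDQ-39 mobility, MoCA, Schwab & England, and a global composite
    outcome formed from signed z-scores -- fits ridge regression models on
    baseline feature panels, and scores predictive ability by
    cross-validated rank concordance (Goodman-Kruskal gamma expressed as
    percent accuracy). Includes a synthetic longitudinal cohort generator
    with known latent progression rates and tunable feature signal so that
    every stage of the pipeline is testable without access to the original
    repository data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    optparse,
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
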