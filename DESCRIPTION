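Package: lipidscore
Title: Intervention-Derived Multilipid Scores for Cardiometabolic Risk Analysis
Version: 0.1.0
Authors@R: person("lipidscore", "maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to derive weighted multilipid scores from two-arm dietary
    intervention trials and carry them into observational cohorts. Implements
    lipid nomenclature and aggregation (within-class fatty-acid sums, isobaric
    species sums), left-censored imputation, per-lipid intervention-effect
    estimation with Benjamini-Hochberg selection, score construction and
    standardization to the intervention contrast, cross-platform score
    reduction, Prentice-weighted case-cohort Cox regression, conditional
    logistic regression for matched designs, isocaloric macronutrient
    substitution models, diet-quality indices, conditional-independence
    network estimation with Louvain clustering and direct-effect
    classification, and a synthetic-data generator with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
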