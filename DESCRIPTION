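Package: metaprs
Title: Meta Polygenic Risk Scores for Type 2 Diabetes Risk Prediction
Version: 0.1.0
Authors@R: person("metaprs", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to compute component polygenic risk scores (PRS) from
    imputed allelic dosages and PGS-Catalog-style scoring files, combine
    them into meta-scores (weighted averages of standardized component
    scores with elastic-net log-odds weights), and evaluate prediction of
    a binary outcome such as type 2 diabetes.  Includes genotype quality
    control (call rate, minor allele frequency, Hardy-Weinberg exact
    test, identity-by-descent, principal components, cross-platform
    harmonization), quintile and per-SD logistic association models,
    AUC with DeLong variance and paired tests, Nagelkerke pseudo-R2,
    continuous net reclassification improvement with bootstrap intervals,
    and a seeded synthetic-cohort generator so the full pipeline is
    testable without access to controlled genotype data.
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
    tools,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
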