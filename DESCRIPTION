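Package: idburden
Title: Rare and Common Variant Burden Analysis for Intellectual Disability Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for case-control analyses of rare and common
    genetic variation in intellectual disability cohorts from founder
    populations. Classifies variants as diagnostic-grade from
    loss-of-function confidence and missense deleteriousness scores,
    summarizes diagnostic yield, calls de novo variants from trio genotype
    likelihoods and tests their enrichment against per-gene mutation rates,
    fits covariate-adjusted burden regressions with maximum-likelihood and
    Firth bias-corrected logistic engines, contrasts control-normalized
    polygenic scores between groups, and assesses rare-by-common additivity
    by interaction tests and AIC/BIC multimodel inference. Includes a
    synthetic cohort generator with an additive liability model so every
    stage is testable without access to patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    vcfR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
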