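Package: seedlongevity
Title: Seed Longevity Estimation from Artificial-Ageing Germination Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the rate of seed viability loss (sigma, days per probit)
    from artificial-ageing germination time courses via quasibinomial probit
    regression, applies seed-lot screening rules (initial germination,
    slope significance, maximum-sigma bound), tests within-species
    heterogeneity in sigma with nested quasi-F tests, and models sigma
    against seed-lot and species predictors with a REML random-intercept
    mixed model, type-III Wald tests and marginal/conditional R-squared
    decomposition. A synthetic-data module generates germination datasets
    with the assumed statistical structure (probit-linear decay,
    beta-binomial overdispersion, species-level random effects) so every
    stage is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4
Config/testthat/edition: 3
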