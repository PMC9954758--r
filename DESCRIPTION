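Package: mfim
Title: Multifactor Interaction Models of Reading Ability in Developmental
    Dyslexia
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Moderation analysis for multifactor models of developmental
    dyslexia. Builds correlation-weighted "other factors" (OF) indices from
    z-scored cognitive predictors, fits linear models with a
    predictor-by-OF interaction and reports directional one-tailed
    inference, computes small-sample-adjusted uniform-prior Bayes factors
    for the interaction estimates, and simulates clinically ascertained
    cohorts from a threshold model of reading in which deficits are
    amplified when the aggregate efficiency of the remaining cognitive
    functions falls below a threshold.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
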