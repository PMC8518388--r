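Package: bitlesion
Title: Risk-Factor Analysis of Bit-Related Oral Lesions in Trotting Horses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for cross-sectional risk-factor studies of bit-related
    oral lesions in harness-racing horses. Implements an ordinal lesion
    point-scoring and severity classification scheme (categories A-D,
    merged AB/CD), a synthetic cohort generator that reproduces the
    covariate marginals and effect sizes of a Finnish trotter study
    population, and the full inference pipeline: univariable chi-square
    screening, exact and chi-square contingency tests, multivariable
    logistic regression with Wald inference, manual stepwise model
    building with confounding checks, quasi-separation handling, and
    covariate-pattern diagnostics (goodness of fit, leverage,
    delta-betas, ROC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
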