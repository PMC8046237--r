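Package: epicmapr
Title: Mapping EPIC Prostate-Cancer Quality-of-Life Scores to EQ-5D-3L Utilities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for crosswalking Expanded Prostate Cancer Index Composite
    (EPIC) domain and sub-domain scores to EQ-5D-3L health utilities for use in
    cost-utility analyses. Ships published mapping equations as built-in
    models, a generic additive EQ-5D-3L tariff engine driven by value-set
    configuration files, and the full model-development battery used to derive
    such crosswalks: design-matrix construction for six specification groups,
    ordinary least squares, upper-censored Tobit maximum likelihood, two-part
    (logistic + linear) estimation, forward stepwise selection, 70/30
    estimation-validation splitting, k-fold cross-validation with PRESS-based
    RMSE, model ranking, and Bland-Altman agreement diagnostics. A
    Gaussian-copula synthetic cohort generator reproduces the ceiling-inflated
    utility distribution and correlated 0-100 instrument scores typical of
    low-risk prostate-cancer trial populations, so the whole workflow can be
    exercised and re-estimated without patient-level trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse
Config/testthat/edition: 3
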