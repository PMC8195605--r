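Package: fedclaims
Title: Federated Retrospective Causal Analysis of Medication Exposure in Claims Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Target-trial emulation from insurance-claims-shaped data, end to end:
    a synthetic multi-source claims generator with a potential-outcomes oracle and
    configurable confounding by indication; cohort construction under a medication
    possession ratio exposure rule with CONSORT accounting; per-source unadjusted
    (Fisher exact), adjusted (propensity trimming plus inverse-propensity-weighted
    logistic regression with robust variance), and 5:1 matched (exact-age greedy
    Mahalanobis matching, Cochran-Mantel-Haenszel) effect estimation; privacy-
    preserving federation across sources by inverse-variance pooling of coefficients
    and relative risk reductions and by stratified CMH pooling; and sensitivity
    analyses including E-values for unmeasured confounding, alternative IPW/AIPW
    estimators, exposure-window redefinition, and pre-index health-trend comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    sandwich,
    stats,
    utils,
    xgboost
Suggests:
    ranger,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
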