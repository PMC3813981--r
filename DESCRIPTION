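Package: seamest
Title: Conditional Estimation After Two-Stage Seamless Phase II/III Trials
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Point estimation of the selected-treatment versus control
    difference after a two-stage adaptive seamless phase II/III trial in
    which the best-performing of k experimental arms is selected at an
    interim analysis and the trial may stop early for futility. Implements
    the conditionally unbiased (Rao-Blackwell / UMVUE) estimator built from
    truncated-normal conditional expectations, an iteratively bias-adjusted
    maximum-likelihood estimator based on analytic selection-bias integrals,
    and the reference naive and stage-2-only estimators, together with a
    trial simulator for operating characteristics and plain Monte-Carlo
    oracles that certify the estimators' conditional unbiasedness.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
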