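Package: acwrbayes
Title: Bayesian Analysis of Session-RPE Workload Metrics and Injury Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring internal training load from session ratings of
    perceived exertion (sRPE) and for testing whether the acute:chronic workload
    ratio (ACWR) carries injury-predictive information beyond acute load alone.
    Computes weekly acute, cumulative and chronic loads, coupled or uncoupled
    ACWR, training monotony, and a randomised-denominator null comparator
    (ACWRr); fits Bayesian robust Student-t two-group comparisons (BEST-style)
    and Bayesian logistic models of injury probability over load quantiles with
    sum-to-zero deviation coding, via JAGS; reports posterior means, 95%
    highest-density intervals, effective sample sizes and split-Rhat
    diagnostics; and includes a calibrated synthetic team-season generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    coda,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rjags,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    zoo
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
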