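Package: infoacq
Title: Information-Theoretic Analysis of Pavlovian Acquisition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing the acquisition of Pavlovian conditioned
    responding from timestamped magazine-entry (poke) records. Implements the
    nDKL statistic (effective sample size times the Kullback-Leibler
    divergence between exponential rate estimates, with its Gamma(0.5, 1)
    null distribution), cumulative-rate trials-to-acquisition criteria with
    the restart rule, recursive change-point parsing of inter-poke interval
    vectors into constant-rate segments, corrected response-rate estimators
    and log-log scalar rate-reinforcement regressions, decile growth-curve
    extraction with BIC model comparison, informativeness-based learning-rate
    and generative response-probability models, the rate-estimation matrix
    solver, and a synthetic-cohort simulator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
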