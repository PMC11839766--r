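Package: stagescore
Title: Automated STAGES Scoring of Sentence Completion Tests with
    Agreement Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Scores sentence-completion-test responses on the 12-level
    STAGES ego-development scale (1.0-6.5 in half steps) by answering
    three classification questions per sentence (Concrete/Subtle/MetAware
    tier, Individual/Collective focus, Passive/Active agency) through a
    pluggable classifier backend, stabilising stochastic backends with a
    median-of-runs protocol, and aggregating sentence scores to
    respondent and group level.  Includes the statistical machinery used
    to validate such a protocol: quadratic-weighted Cohen's kappa with
    its asymptotic standard error and confidence interval, ordinal
    cross-tabulation, run-count regression calibration, minimum-item
    subsample calibration, and resampled aggregate-agreement analysis,
    plus synthetic-data generators with known ground truth for testing
    the estimators end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
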