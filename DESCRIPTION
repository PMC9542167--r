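Package: festimands
Title: Estimands, Estimators and Simulation for 2x2 Factorial Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Defines the four treatment-A estimands for 2x2 factorial
    randomized trials via potential outcomes (effect of A without B, with B,
    under usual-practice use of B, and of the A+B combination), computes their
    true values exactly from cell-level outcome parameters, and estimates them
    from participant-level data with factorial (at-the-margins) and multiarm
    (inside-the-table) estimators, including the pi-weighted usual-practice
    estimator.  Handles noncollapsible summary measures (odds ratios) by
    always adjusting the factorial model for the other factor, assesses the
    no-interaction assumption, runs the four-step estimand framework
    end-to-end, and provides a seeded potential-outcomes simulator plus
    Monte-Carlo machinery for bias, empirical SE and confidence-interval
    coverage of every estimator, including the discouraged two-stage
    (interaction pre-test) procedure as a negative control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
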