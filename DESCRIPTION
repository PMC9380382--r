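Package: ncctrends
Title: Platform Trials with Non-Concurrent Controls and Time-Trend
    Adjustment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Design, simulation and analysis of two-period platform trials
    in which a new experimental arm enters after the trial has started, so
    that part of the shared control arm is non-concurrent with the new arm.
    Provides permuted-block and simple randomisation, configurable time
    trends (linear, step-wise and inverted-U), data generation for
    continuous and binary endpoints, regression-based analysis methods that
    adjust for time as a step function or a linear term, the closed-form
    weighted-means representation of the step-function estimator (including
    the non-concurrent-control weight and the implied variance reduction),
    analytic power calculators, and a replicate simulation engine that
    estimates type 1 error, power, bias and RMSE of the treatment effect
    for the newly added arm.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
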