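Package: caratrial
Title: Biomarker-Guided Covariate-Adjusted Response-Adaptive Trial Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation engine and operating-characteristics toolkit for a
    covariate-adjusted response-adaptive (CARA) randomization design in which
    each incoming patient's biomarkers are fed to per-arm regression models,
    the arm with the best predicted outcome is favoured through a linearly
    decaying randomization sequence, and the first patients are allocated in
    an equal-probability burn-in. Ships scenario generators for continuous
    outcomes with a single continuous biomarker and for right-censored
    survival outcomes with two binary biomarkers (staggered arrivals, dropout
    and administrative censoring), a catalogue of regression learners
    (polynomial, nearest-neighbour, Gaussian process, smoothing spline,
    random forest, and censoring-aware exponential models), and replicate
    aggregation of ethical and inferential operating characteristics
    (proportion of patients on their best treatment, allocation performance
    ratio, type I error and power overall and in biomarker subgroups, logrank
    analysis) against equal fixed randomization.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
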