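Package: normadapt
Title: Computational Models of Fairness-Norm Adaptation in the Ultimatum Game
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and model-based analysis of responder behavior in a
    conditioning Ultimatum Game. Generates three-block offer schedules,
    simulates responders under six candidate norm-learning models built on
    Fehr-Schmidt inequity-aversion utility (fixed-norm, Bayesian-observer and
    Rescorla-Wagner norm updating, each with a fixed or free initial norm),
    fits each model to trial-level choice data by multi-start maximum
    likelihood, compares models by summed BIC/AIC, and runs parameter and
    model recovery studies. Also provides the model-free behavioral analyses:
    block rejection-rate contrasts with paired t-tests and Cohen's d,
    Benjamini-Hochberg false-discovery-rate correction, sliding-window
    rejection curves, mixed-effects logistic regression of choice on offer
    size, and emotion-rating contrasts.
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
    lme4,
    purrr,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
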