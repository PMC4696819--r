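Package: dosefit
Title: Dose-Response Curve Fitting and Inference on Derived Doses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits parametric dose-response models (log-logistic, log-normal,
    Weibull, gamma, multistage, threshold and hormesis families) to continuous,
    binomial and count responses by weighted least squares, maximum likelihood
    or robust M-estimation, with optional Box-Cox transform-both-sides and box
    constraints. Provides hierarchical parameter fixing, data-driven starting
    values, joint fitting of several curves with parameter sharing, lack-of-fit
    and no-effect tests, model selection, and inference on derived doses:
    relative and absolute effective doses, benchmark doses, and relative
    potencies with delta-method, Fieller and back-transformed confidence
    intervals. Tidyverse-friendly: functions take a data frame first and return
    tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
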