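Package: boutfit
Title: Sleep Bout Architecture Analysis and Power-Law Regulation Modelling
    for Drosophila Activity-Monitor Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores sleep bouts from TriKinetics-style Drosophila activity
    monitor (DAM) recordings using the five-minute inactivity rule, builds
    animal-period summaries (total sleep, bout count, mean bout length),
    and fits the power law Y = a*X^b relating sleep bout count to mean
    sleep bout length by Levenberg-Marquardt least squares. The coefficient
    of determination of that fit is reported as a measure of how tightly
    sleep is regulated, together with 95% parameter confidence intervals,
    delta-method confidence bands, parameter dependency, and D'Agostino-
    Pearson omnibus normality diagnostics. A calibrated cohort simulator
    generates animal-period summaries and realizable minute-level activity
    traces for control, hyposomnolent-mutant and sleep-deprivation/rebound
    regimes, so the full pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
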