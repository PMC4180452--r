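Package: lifeyears
Title: Life Expectancy Estimates for Older Adults from Mortality Risk Points
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Converts a 12-item mortality point score for adults aged 50 and
    over into median life expectancy and survival quantiles. Risk-point groups
    are modelled with a shared-shape Gompertz proportional-hazards survival
    function fitted to right-censored follow-up by maximum likelihood, with
    percentile-bootstrap confidence intervals, 50% prediction intervals, and
    re-calibration from published quantile tables. Includes survival-model
    diagnostics (Kaplan-Meier comparison curves, Harrell's concordance,
    fixed-horizon Hosmer-Lemeshow calibration, AIC/BIC comparison against
    Weibull and exponential alternatives) and a synthetic-cohort simulator
    with known truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    flexsurv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
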