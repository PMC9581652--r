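Package: visitcast
Title: Bayesian Autoregressive Forecasting of Monthly Outpatient Visits
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for forecasting monthly hospital outpatient-visit volumes
    from their own history. Provides a least-squares autoregressive (AR)
    baseline with AIC lag-order selection, a Gibbs-sampling Bayesian AR
    model with conjugate normal/inverse-gamma conditionals, posterior
    predictive forecasts with multi-level prediction intervals, forecast
    accuracy metrics (RMSE, MAPE), training-fraction stability sweeps,
    series diagnostics (moment statistics, permutation entropy, seasonal
    trend decomposition), and a calibrated synthetic-data generator for
    hospital-like monthly count series.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
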