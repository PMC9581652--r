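# visitcast

Bayesian autoregressive forecasting of monthly hospital outpatient-visit
volumes.

Hospital outpatient series are univariate monthly counts with an upward
trend, a strong annual cycle, and autocorrelated fluctuations driven by
factors nobody can measure. `visitcast` forecasts such series from their
own history and, unlike a plug-in AR fit, quantifies how uncertain those
forecasts are.

## What it implements

* **Classical baseline** — AR(p) by conditional least squares,

  $$y_t = \alpha + \sum_{k=1}^{p} \beta_k y_{t-k} + \epsilon_t,
    \qquad \epsilon_t \sim N(0, \sigma^2),$$

  with lag order chosen by minimising
  $\mathrm{AIC}(p) = \log(\mathrm{SSE}_p/(T-p)) + ((T-p)+2p)/(T-p)$
  subject to a stationarity check, and deterministic recursive forecasts.
* **Bayesian AR** — the same regression with priors
  $\alpha, \beta_k \sim N(0,1)$ and
  $\sigma^2 \sim \mathrm{InvGamma}(1/2, 1/20)$, sampled by a
  systematic-scan Gibbs sampler with closed-form conjugate conditionals
  (20,000 iterations, 4,000 burn-in by default). No stationarity
  constraint is imposed, which lets the model use the seasonal lag orders
  (12–16) that monthly data reward.
* **Posterior-predictive forecasting** — one trajectory per retained draw
  with fresh process noise; point forecast = trajectory mean, uncertainty
  = trajectory SD, plus central prediction intervals at 17 levels
  (10%–90% in 5% steps).
* **Evaluation** — RMSE and MAPE (percent) on a chronological 80/20
  split, AR-vs-Bayesian comparisons, lag-order sweeps, and
  training-fraction stability curves (50%–90%).
* **Diagnostics** — moment skewness/kurtosis, permutation entropy, robust
  STL decomposition, calendar-month (polar) seasonal profiles.
* **Synthetic data** — a calibrated generator of hospital-like monthly
  series (trend + July-peaking seasonality + AR noise + optional
  late-series pattern shift) plus parameter-recovery and
  interval-calibration harnesses.

## Worked example

```r
library(visitcast)
library(dplyr)

series <- generate_series(synthetic_spec(), seed = 1)   # 120 months, ~2e5 visits
parts  <- split_series(series, 0.8)                     # anterior 96 / posterior 24

fit <- gibbs_sample(parts$train, p = 12,
                    config = gibbs_config(20000, 4000, seed = 1),
                    allow_large_order = TRUE)
tidy(fit)[c(1, 2, 13, 14), ]
#>   term   estimate    std.error     conf.low    conf.high
#> 1 alpha   5.28e-3       1.00         -2.00         1.98
#> 2 beta1   5.38e-1       0.0959        0.378        0.720
#> 3 beta12  2.45e-1       0.0811        0.0721       0.390
#> 4 sigma2  2.83e+7 4795221.     20307410.    39119992.
```

The intercept posterior hugs zero — the N(0, 1) prior is extremely
informative on an intercept at this scale, and the lag coefficients absorb
the level (see the vignette; `prior_spec(coef_var = ...)` relaxes it).
Forecast the held-out two years with full posterior-predictive
uncertainty:

```r
fc <- posterior_forecast(fit, horizon = nrow(parts$test), seed = 2)
tidy(fc)[1:3, c("month", "point", "sd", "lower_90", "upper_90")]
#>   month        point    sd lower_90 upper_90
#> 1 2020-01-01 202866. 5644.  193598.  212226.
#> 2 2020-02-01 203868. 6316.  193366.  214188.
#> 3 2020-03-01 216006. 6711.  204893.  227023.
```

Each row is a forecast month: `point` is the mean of 16,000 posterior
trajectories (visits/month), `sd` its spread, and `lower_90`/`upper_90`
the central 90% prediction interval. Head-to-head against the
stationarity-checked classical baseline on the identical split:

```r
compare_models(series, baseline_order = "aic", bayes_order = 12,
               max_order = 16, config = gibbs_config(20000, 4000, seed = 1),
               seed = 2)
#>        model order     rmse     mape  n n_train
#> 1         AR     9 7100.801 2.520539 24      96
#> 2 BayesianAR    12 6014.910 2.253699 24      96
```

The seasonal-order Bayesian model beats the stationarity-checked baseline
on both metrics here (forecast errors around 2--2.5% of monthly volume),
and the lag-12 coefficient is clearly loaded (0.245 +- 0.081) — the annual
cycle is doing real predictive work. Across many seeds the median MAPE
advantage persists (the test suite checks it over 20 seeds). `autoplot(fc, series)` draws the
fan chart, `stability_analysis()` the training-fraction robustness curve,
and

```r
series_diagnostics(series)
#>       n permutation_entropy kurtosis skewness
#> 1   120                 2.3     2.28  -0.0616
```

summarises the series' complexity (nats; max for embedding 4 is
ln 24 ≈ 3.18) and moment shape.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/visitcast.R simulate --seed 1 --out series.csv
Rscript inst/cli/visitcast.R bayes-fit --input series.csv --order 12 --seed 2 --draws-out draws.csv
Rscript inst/cli/visitcast.R forecast --draws draws.csv --input series.csv --horizon 24 --out forecast.csv
```

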