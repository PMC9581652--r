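test_that("a point-mass posterior without noise reproduces the plug-in forecast", {
  train <- generate_pure_ar(10, 0.5, 2, n = 40, seed = 1)
  fit <- point_mass_fit(10, 0.5, 4, train)
  fc <- posterior_forecast(fit, horizon = 6, include_noise = FALSE)
  plug_in <- forecast_point(structure(list(alpha = 10, betas = 0.5), class = "ar_fit"),
                            6, seed_lags = rev(tail(train$visits, 1)))
  expect_equal(fc$summary$point, plug_in, tolerance = 1e-12)
  expect_equal(fc$summary$sd, rep(0, 6))
  expect_true(all(apply(fc$samples, 2, function(col) all(col == col[1]))))
})

test_that("an intercept-only posterior forecasts its own alpha draws one step ahead", {
  train <- generate_pure_ar(10, 0.5, 2, n = 40, seed = 2)
  set.seed(3)
  alphas <- rnorm(300, 50, 4)
  fit <- point_mass_fit(0, 0, 1, train, n_draws = 300)
  fit$draws$alpha <- alphas
  fc <- posterior_forecast(fit, horizon = 1, include_noise = FALSE)
  expect_equal(fc$samples[, 1], alphas)
  expect_equal(fc$summary$point, mean(alphas), tolerance = 1e-12)
})

test_that("forecast summary months continue the training calendar", {
  train <- generate_pure_ar(50, c(0.5, 0.3), 5, n = 60, seed = 4)
  fit <- gibbs_sample(train, 2, config = quick_config(seed = 4, iterations = 600,
                                                      burn_in = 100))
  fc <- posterior_forecast(fit, horizon = 3, seed = 5)
  expect_equal(fc$summary$month[1], seq(max(train$month), by = "month",
                                        length.out = 2)[2])
  expect_equal(fc$summary$point, colMeans(fc$samples), tolerance = 1e-9)
  expect_equal(nrow(fc$samples), nrow(fit$draws))
  expect_error(posterior_forecast(fit, horizon = 0), ">= 1")
})

test_that("interval construction follows the type-7 quantile rule on the 17-level grid", {
  samples <- matrix(1:100, ncol = 1)
  iv <- build_intervals(samples)
  expect_equal(sort(unique(iv$level)), seq(0.10, 0.90, by = 0.05))
  expect_equal(nrow(iv), 17)

  # sort-and-index oracle: h = (n-1)p + 1, linear interpolation
  type7 <- function(x, p) {
    x <- sort(x)
    h <- (length(x) - 1) * p + 1
    x[floor(h)] + (h - floor(h)) * (x[ceiling(h)] - x[floor(h)])
  }
  l90 <- iv[abs(iv$level - 0.90) < 1e-9, ]
  expect_equal(l90$lower, type7(1:100, 0.05))
  expect_equal(l90$upper, type7(1:100, 0.95))
  l10 <- iv[abs(iv$level - 0.10) < 1e-9, ]
  expect_equal(l10$lower, type7(1:100, 0.45))

  # symmetric samples give intervals symmetric about zero
  sym <- matrix(c(seq(0.1, 30, by = 0.1), -seq(0.1, 30, by = 0.1)), ncol = 1)
  ivs <- build_intervals(sym)
  expect_equal(ivs$lower, -ivs$upper, tolerance = 1e-9)

  expect_error(build_intervals(matrix(1:50, ncol = 1)), "100")
})

test_that("prediction intervals are nested across all 17 levels at every month", {
  train <- generate_pure_ar(50, c(0.5, 0.3), 5, n = 80, seed = 6)
  fit <- gibbs_sample(train, 2, config = quick_config(seed = 6, iterations = 1500,
                                                      burn_in = 300))
  fc <- posterior_forecast(fit, horizon = 5, seed = 7)
  nested <- fc$intervals |>
    dplyr::arrange(.data$step, .data$level) |>
    dplyr::group_by(.data$step) |>
    dplyr::summarise(ok = all(diff(lower) <= 1e-12) && all(diff(upper) >= -1e-12))
  expect_true(all(nested$ok))
  # every interval straddles the per-month median
  med <- apply(fc$samples, 2, median)
  joined <- dplyr::mutate(fc$intervals, med = med[step])
  expect_true(all(joined$lower <= joined$med & joined$med <= joined$upper))
})

test_that("one-step forecast variance decomposes into parameter plus process uncertainty", {
  train <- generate_pure_ar(50, 0.8, 5, n = 150, seed = 8)
  fit <- gibbs_sample(train, 1, prior = prior_spec(coef_var = 1e4),
                      config = quick_config(seed = 9, iterations = 8000,
                                            burn_in = 1000))
  fc <- posterior_forecast(fit, horizon = 1, include_noise = TRUE, seed = 10)
  y_T <- tail(train$visits, 1)
  mu_draws <- fit$draws$alpha + fit$draws$beta1 * y_T
  expected <- var(mu_draws) + mean(fit$draws$sigma2)
  expect_equal(var(fc$samples[, 1]), expected, tolerance = 0.1)
})

test_that("forecast spread grows with horizon for a stationary generator, on average", {
  gaps <- vapply(1:10, function(s) {
    train <- generate_pure_ar(50, 0.7, 5, n = 80, seed = 40 + s)
    fit <- gibbs_sample(train, 1, prior = prior_spec(coef_var = 1e4),
                        config = quick_config(seed = 40 + s, iterations = 1500,
                                              burn_in = 300))
    fc <- posterior_forecast(fit, horizon = 6, seed = 70 + s)
    fc$summary$sd[6] - fc$summary$sd[1]
  }, numeric(1))
  expect_gt(mean(gaps), 0)
})

test_that("the coverage experiment enforces its contract", {
  spec <- synthetic_spec(length = 60, base_level = 250, trend_slope = 0,
                         seasonal_amplitudes = rep(0, 12),
                         ar_coefs = c(0.5, 0.3), noise_sd = 5)
  expect_error(coverage_experiment(spec, level = 1.0), "grid")
  expect_error(coverage_experiment(spec, level = 0.12), "grid")
  expect_error(coverage_experiment(spec, level = 0.9, replicates = 10), "50")
})

test_that("low-level intervals cover at roughly their nominal rate", {
  spec <- synthetic_spec(length = 60, base_level = 250, trend_slope = 0,
                         seasonal_amplitudes = rep(0, 12),
                         ar_coefs = c(0.5, 0.3), noise_sd = 5)
  cov10 <- coverage_experiment(spec, level = 0.10, replicates = 100, seed = 31,
                               config = gibbs_config(1000, 250))
  # binomial 3-sigma band around 0.10 at 100 replicates
  expect_gte(cov10$coverage, 0.01)
  expect_lte(cov10$coverage, 0.19)
  expect_equal(nrow(cov10$results), 100)
})

test_that("tidy() flattens a forecast into one row per month with interval columns", {
  train <- generate_pure_ar(50, c(0.5, 0.3), 5, n = 60, seed = 11)
  fit <- gibbs_sample(train, 2, config = quick_config(seed = 11, iterations = 600,
                                                      burn_in = 100))
  fc <- posterior_forecast(fit, horizon = 4, seed = 12)
  td <- tidy(fc)
  expect_equal(nrow(td), 4)
  expect_true(all(c("point", "sd", "lower_10", "upper_90") %in% names(td)))
})
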