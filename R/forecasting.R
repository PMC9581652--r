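#' Posterior-predictive multistep forecast
#'
#' Propagates every retained posterior draw through the AR recurrence: one
#' trajectory per draw, each step feeding its own prediction back in as a
#' lag. With `include_noise` on (the default, the full posterior
#' predictive) each step also adds a fresh Gaussian innovation with that
#' draw's noise variance, so the forecast spread carries both parameter and
#' process uncertainty; switching it off gives the plug-in trajectory of
#' each draw. The per-month point forecast is the sample mean across
#' trajectories and the per-month SD is the forecasting-uncertainty
#' measure.
#'
#' @param fit A `bayes_ar_fit` from [gibbs_sample()].
#' @param horizon Months ahead to forecast, >= 1 (conventionally the length
#'   of the held-out test set).
#' @param include_noise Add per-step process noise (default `TRUE`).
#' @param seed Optional integer seed for the innovation draws.
#' @param seed_lags Optional `p` observations preceding the forecast
#'   origin, most recent first; defaults to the last training months.
#' @return An object of class `forecast_dist`: a list with `samples`
#'   (`draws x horizon` matrix), `summary` (tibble: `step`, `month`,
#'   `point`, `sd`), `intervals` (see [build_intervals()]), `levels`, and
#'   `horizon`.
#' @export
posterior_forecast <- function(fit, horizon, include_noise = TRUE,
                               seed = NULL, seed_lags = NULL) {
  if (!inherits(fit, "bayes_ar_fit")) abort("`fit` must be a bayes_ar_fit.")
  if (!is.numeric(horizon) || horizon < 1) abort("`horizon` must be >= 1.")
  horizon <- as.integer(horizon)
  p <- fit$p
  if (is.null(seed_lags)) seed_lags <- fit$seed_lags
  if (length(seed_lags) != p) {
    abort(paste0("`seed_lags` must hold exactly p = ", p, " values."))
  }
  dm <- as.matrix(fit$draws)
  D <- nrow(dm)
  alpha <- dm[, 1]
  B <- dm[, 1 + seq_len(p), drop = FALSE]
  sig <- sqrt(dm[, p + 2])
  samples <- matrix(NA_real_, D, horizon)
  run <- function() {
    lags <- matrix(rep(as.numeric(seed_lags), each = D), nrow = D, ncol = p)
    for (h in seq_len(horizon)) {
      val <- alpha + rowSums(B * lags)
      if (include_noise) val <- val + rnorm(D, 0, sig)
      samples[, h] <<- val
      lags <- cbind(val, lags[, -p, drop = FALSE])
    }
  }
  with_seed_maybe(seed, run())

  last_month <- tail(fit$train$month, 1)
  months <- seq(last_month, by = "month", length.out = horizon + 1)[-1]
  summary <- tibble::tibble(
    step = seq_len(horizon),
    month = months,
    point = colMeans(samples),
    sd = apply(samples, 2, sd)
  )
  out <- structure(
    list(samples = samples, summary = summary, horizon = horizon,
         include_noise = include_noise,
         levels = interval_levels(), intervals = NULL),
    class = "forecast_dist"
  )
  out$intervals <- build_intervals(out)
  out
}

interval_levels <- function() seq(0.10, 0.90, by = 0.05)

#' Central prediction intervals at 17 levels
#'
#' Converts the per-month forecast samples into central prediction
#' intervals at the 17 levels 0.10, 0.15, ..., 0.90: at level `l` the
#' interval runs from the empirical `(1-l)/2` quantile to the `(1+l)/2`
#' quantile of that month's samples. Quantiles use linear interpolation
#' between order statistics (R's type 7 convention), and the intervals are
#' nested by construction.
#'
#' @param dist A `forecast_dist`, or a matrix of forecast samples with one
#'   column per horizon month (>= 100 rows).
#' @param levels Interval levels; defaults to the 17-level grid.
#' @return A tibble with columns `level`, `step`, `lower`, `upper`.
#' @export
build_intervals <- function(dist, levels = interval_levels()) {
  samples <- if (inherits(dist, "forecast_dist")) dist$samples else as.matrix(dist)
  if (nrow(samples) < 100) {
    abort("Need at least 100 forecast samples per month to form intervals.")
  }
  if (any(levels <= 0 | levels >= 1)) abort("Interval levels must lie in (0, 1).")
  purrr::map_dfr(levels, function(l) {
    tibble::tibble(
      level = l,
      step = seq_len(ncol(samples)),
      lower = apply(samples, 2, quantile, probs = (1 - l) / 2, type = 7, names = FALSE),
      upper = apply(samples, 2, quantile, probs = (1 + l) / 2, type = 7, names = FALSE)
    )
  })
}

#' Empirical coverage of a prediction-interval level
#'
#' Monte-Carlo check of interval calibration: repeatedly simulate a series
#' from `spec`, fit the Bayesian AR model to all but the last month,
#' forecast one step, and record whether the held-out month falls inside
#' the level-`level` interval. With a well-specified generator the hit
#' fraction should sit near the nominal level.
#'
#' @param spec A [synthetic_spec()] describing the generator.
#' @param level Interval level; must be one of the 17-level grid values.
#' @param replicates Number of simulated replicates, >= 50.
#' @param seed Integer seed driving the whole experiment.
#' @param p Lag order fitted to each replicate (default: the generator's
#'   AR order).
#' @param prior Prior used for each fit; defaults to a weakly-informative
#'   coefficient prior so that the check exercises the sampler and the
#'   interval construction rather than prior shrinkage.
#' @param config Gibbs configuration per replicate (default: 2000
#'   iterations, 500 burn-in).
#' @return A list with `coverage` (hit fraction) and `results` (a tibble
#'   with one row per replicate: `replicate`, `truth`, `lower`, `upper`,
#'   `hit`).
#' @export
coverage_experiment <- function(spec, level = 0.90, replicates = 200,
                                seed = 1, p = NULL,
                                prior = prior_spec(coef_var = 1e4),
                                config = gibbs_config(2000, 500)) {
  if (replicates < 50) abort("Need at least 50 replicates.")
  lv <- interval_levels()
  if (!any(abs(lv - level) < 1e-9)) {
    abort("`level` must belong to the 0.10..0.90 (step 0.05) interval grid.")
  }
  p <- p %||% length(spec$ar_coefs)
  results <- purrr::map_dfr(seq_len(replicates), function(r) {
    rep_seed <- seed * 10000L + r
    s <- generate_series(spec, seed = rep_seed)
    n <- nrow(s)
    train <- validate_monthly_series(s[seq_len(n - 1), ])
    truth <- s$visits[n]
    cfg <- config
    cfg$seed <- rep_seed + 1L
    fit <- gibbs_sample(train, p = p, prior = prior, config = cfg)
    fc <- posterior_forecast(fit, horizon = 1, include_noise = TRUE,
                             seed = rep_seed + 2L)
    iv <- fc$intervals[abs(fc$intervals$level - level) < 1e-9, ]
    tibble::tibble(replicate = r, truth = truth,
                   lower = iv$lower, upper = iv$upper,
                   hit = truth >= iv$lower & truth <= iv$upper)
  })
  list(coverage = mean(results$hit), results = results)
}

#' @export
print.forecast_dist <- function(x, ...) {
  cat("Posterior-predictive forecast, horizon ", x$horizon, " months, ",
      nrow(x$samples), " trajectories",
      if (!x$include_noise) " (plug-in, no process noise)", "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @rdname posterior_forecast
#' @param x,object A `forecast_dist`.
#' @param ... Unused.
#' @method tidy forecast_dist
#' @export
tidy.forecast_dist <- function(x, ...) {
  dplyr::left_join(
    x$summary,
    tidyr::pivot_wider(
      x$intervals,
      names_from = "level",
      values_from = c("lower", "upper"),
      names_glue = "{.value}_{sprintf('%02d', round(level * 100))}"
    ),
    by = "step"
  )
}
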