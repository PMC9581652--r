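#' Specification for a hospital-like synthetic monthly series
#'
#' Describes a generator of positive monthly visit counts with the
#' structure seen in real outpatient records: a base level in the
#' hundreds of thousands of visits, an upward long-term trend, an annual
#' seasonal cycle peaking mid-year, autocorrelated (AR) noise, and an
#' optional late-series level shift that emulates an abrupt pattern
#' change.
#'
#' The defaults are the package's reference study conditions: 120 months
#' at a base level of 200,000 visits, +250 visits/month trend, a cosine
#' seasonal cycle of 20,000-visit amplitude peaking in July (amplitudes
#' sum to zero over the year), stationary AR(2) noise with coefficients
#' (0.5, 0.2) and innovation SD 4,000.
#'
#' @param length Number of months (default 120).
#' @param base_level Mean level in visits, > 0 (default 2e5).
#' @param trend_slope Linear trend in visits/month (default 250).
#' @param seasonal_amplitudes Numeric vector of 12 calendar-month offsets
#'   (Jan..Dec) summing to zero.
#' @param ar_coefs Stationary AR coefficients of the noise process.
#' @param noise_sd Innovation SD in visits, >= 0 (default 4000).
#' @param shift Optional `list(month = , delta = )`: from month index
#'   `month` (1-based) onward, `delta` visits are added, producing a
#'   late-series pattern shift.
#' @param start Calendar position `c(year, month)` of the first value.
#' @param seed Optional default seed used by [generate_series()].
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(length = 120, base_level = 2e5, trend_slope = 250,
                           seasonal_amplitudes = default_seasonal_amplitudes(),
                           ar_coefs = c(0.5, 0.2), noise_sd = 4000,
                           shift = NULL, start = c(2012, 1), seed = NULL) {
  if (length < 1) abort("`length` must be >= 1.")
  if (base_level <= 0) abort("`base_level` must be > 0.")
  if (length(seasonal_amplitudes) != 12) {
    abort("`seasonal_amplitudes` must have one entry per calendar month (12).")
  }
  if (abs(sum(seasonal_amplitudes)) > 1e-6 * max(1, max(abs(seasonal_amplitudes)))) {
    abort("`seasonal_amplitudes` must sum to zero.")
  }
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (length(ar_coefs) >= 1 && any(ar_coefs != 0) && !check_stationarity(ar_coefs)) {
    abort("`ar_coefs` must describe a stationary AR process.")
  }
  if (!is.null(shift)) {
    if (!is.list(shift) || is.null(shift$month) || is.null(shift$delta)) {
      abort("`shift` must be list(month = , delta = ).")
    }
    if (shift$month < 1 || shift$month > length) {
      abort("`shift$month` must index a month inside the series.")
    }
  }
  structure(
    list(length = as.integer(length), base_level = base_level,
         trend_slope = trend_slope,
         seasonal_amplitudes = as.numeric(seasonal_amplitudes),
         ar_coefs = as.numeric(ar_coefs), noise_sd = noise_sd,
         shift = shift, start = start, seed = seed),
    class = "synthetic_spec"
  )
}

#' Default July-peaking seasonal amplitudes
#'
#' A hospital-like annual profile: a sharp July--August peak, a deep
#' January--February trough, and fast spring/autumn transitions, scaled to
#' `amplitude` visits at the peak. The shape is deliberately
#' non-sinusoidal — its harmonic content spans many frequencies, as real
#' outpatient seasonality does, so capturing it autoregressively genuinely
#' requires the 12-month lag rather than a low-order cycle. Sums to zero
#' exactly over the 12 months.
#'
#' @param amplitude Peak seasonal offset in visits (default 2e4).
#' @return Numeric vector of length 12 (Jan..Dec).
#' @export
default_seasonal_amplitudes <- function(amplitude = 2e4) {
  shape <- c(-1.0, -0.9, -0.25, 0.05, 0.3, 0.65,
             1.0, 0.95, 0.35, 0.05, -0.3, -0.9)
  amplitude * (shape - mean(shape))
}

#' Generate a synthetic hospital-like monthly series
#'
#' Simulates `y_t = base + slope * (t - 1) + seasonal[calendar month] +
#' u_t (+ delta for t >= shift month)`, where `u_t` is a zero-mean AR
#' process with Gaussian innovations, warmed up for 200 discarded steps so
#' the noise starts in its stationary regime. Reproducible under a fixed
#' seed.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed; defaults to `spec$seed`.
#' @return A `monthly_series` tibble.
#' @examples
#' s <- generate_series(synthetic_spec(), seed = 1)
#' @export
generate_series <- function(spec, seed = spec$seed) {
  if (!inherits(spec, "synthetic_spec")) abort("`spec` must be a synthetic_spec.")
  n <- spec$length
  u <- with_seed_maybe(seed, ar_noise(spec$ar_coefs, spec$noise_sd, n))
  t_idx <- seq_len(n) - 1
  cal_month <- ((spec$start[2] - 1 + t_idx) %% 12) + 1
  y <- spec$base_level + spec$trend_slope * t_idx +
    spec$seasonal_amplitudes[cal_month] + u
  if (!is.null(spec$shift)) {
    y[seq_len(n) >= spec$shift$month] <- y[seq_len(n) >= spec$shift$month] +
      spec$shift$delta
  }
  if (any(y <= 0)) {
    abort("Generated series has non-positive values; raise base_level or lower noise_sd/trend magnitude.")
  }
  monthly_series(y, start = spec$start)
}

# Zero-mean AR noise with Gaussian innovations and a 200-step warm-up.
ar_noise <- function(coefs, sd, n, warmup = 200) {
  p <- length(coefs)
  if (sd == 0 && (p == 0 || all(coefs == 0))) return(numeric(n))
  total <- warmup + n
  e <- rnorm(total, 0, sd)
  if (p == 0 || all(coefs == 0)) return(e[(warmup + 1):total])
  u <- numeric(total)
  for (t in seq_len(total)) {
    lags <- if (t == 1) numeric(0) else u[max(1, t - p):(t - 1)]
    lags <- rev(lags)                       # most recent first
    u[t] <- sum(coefs[seq_along(lags)] * lags) + e[t]
  }
  u[(warmup + 1):total]
}

#' Generate a pure AR(p) series
#'
#' Simulates the plain AR recurrence `y_t = alpha + sum(betas * lags) +
#' N(0, sigma^2)` with a 200-step warm-up started at the process mean, and
#' returns it as a dated monthly series. The substrate for
#' parameter-recovery and calibration experiments.
#'
#' @param alpha Intercept (visits).
#' @param betas Stationary AR coefficients.
#' @param sigma Innovation SD, >= 0.
#' @param n Months to return.
#' @param seed Optional integer seed.
#' @param start Calendar position of the first returned month.
#' @return A `monthly_series`.
#' @export
generate_pure_ar <- function(alpha, betas, sigma, n, seed = NULL,
                             start = c(2012, 1)) {
  if (!check_stationarity(betas)) abort("`betas` must be stationary.")
  if (sigma < 0) abort("`sigma` must be >= 0.")
  p <- length(betas)
  mu <- alpha / (1 - sum(betas))
  total <- 200 + n
  y <- with_seed_maybe(seed, {
    e <- rnorm(total, 0, sigma)
    out <- numeric(total)
    lags <- rep(mu, p)                      # warm start at the process mean
    for (t in seq_len(total)) {
      out[t] <- alpha + sum(betas * lags) + e[t]
      lags <- c(out[t], lags)[seq_len(p)]
    }
    out
  })
  monthly_series(y[(total - n + 1):total], start = start)
}

#' Simulate-fit-summarise parameter-recovery harness
#'
#' For each seed: simulate a pure AR series from the stated truth, run the
#' Gibbs sampler, and record each parameter's posterior mean and SD along
#' with whether the truth lies within 3 posterior SDs of the mean. Over
#' many seeds the per-parameter coverage of that 3-SD band validates the
#' sampler end to end.
#'
#' By default the harness uses a weakly-informative coefficient prior
#' (`coef_var = 1e4`): recovery coverage is a check of the sampler, which
#' is only meaningful when the likelihood dominates the prior.
#'
#' @param alpha,betas,sigma True AR parameters.
#' @param n Series length per replicate (default 200).
#' @param seeds Integer vector of replicate seeds (>= 5).
#' @param prior,config Prior and Gibbs configuration per fit.
#' @return A tibble with one row per seed x parameter: `seed`,
#'   `parameter`, `truth`, `post_mean`, `post_sd`, `covered`.
#' @examples
#' \donttest{
#' rec <- recovery_harness(50, c(0.5, 0.3), 5, seeds = 1:5,
#'                         config = gibbs_config(2000, 500))
#' dplyr::summarise(rec, coverage = mean(covered), .by = parameter)
#' }
#' @export
recovery_harness <- function(alpha, betas, sigma, n = 200, seeds = 1:20,
                             prior = prior_spec(coef_var = 1e4),
                             config = gibbs_config()) {
  if (length(seeds) < 5) abort("Need at least 5 seeds.")
  truth <- c(alpha = alpha,
             stats::setNames(betas, paste0("beta", seq_along(betas))),
             sigma2 = sigma^2)
  purrr::map_dfr(seeds, function(s) {
    series <- generate_pure_ar(alpha, betas, sigma, n, seed = s)
    cfg <- config
    cfg$seed <- s + 500000L
    fit <- gibbs_sample(series, p = length(betas), prior = prior, config = cfg)
    pm <- unname(posterior_mean(fit)[names(truth)])
    psd <- unname(vapply(fit$draws, sd, numeric(1))[names(truth)])
    tibble::tibble(
      seed = s,
      parameter = names(truth),
      truth = unname(truth),
      post_mean = pm,
      post_sd = psd,
      covered = abs(pm - unname(truth)) <= 3 * psd
    )
  })
}
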