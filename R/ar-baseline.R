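#' Build the lagged design matrix for an AR(p) regression
#'
#' Writes the autoregression \eqn{y_t = \alpha + \sum_k \beta_k y_{t-k} +
#' \epsilon_t} as an ordinary regression on the lag-trimmed sample: row `t`
#' of the lag matrix holds the `p` previous observations (most recent
#' first), aligned to target `y_t`. The first `p` observations appear only
#' as lags, never as targets.
#'
#' @param series A `monthly_series` or numeric vector.
#' @param p Lag order, `1 <= p < length(series)`.
#' @return A list with `lags` (a `(T-p) x p` matrix) and `targets`
#'   (length `T-p`).
#' @export
build_design <- function(series, p) {
  y <- series_values(series)
  n <- length(y)
  p <- check_order(p)
  if (p >= n) abort(paste0("Lag order p = ", p, " must be smaller than the series length ", n, "."))
  lags <- vapply(seq_len(p), function(k) y[(p - k + 1):(n - k)],
                 numeric(n - p))
  lags <- matrix(lags, nrow = n - p, ncol = p)
  colnames(lags) <- paste0("lag", seq_len(p))
  list(lags = lags, targets = y[(p + 1):n])
}

#' Fit an AR(p) model by conditional least squares
#'
#' Estimates the intercept and lag coefficients by ordinary least squares on
#' the lag-trimmed sample (the regression form of the AR recurrence). The
#' residual variance uses the residual-degrees-of-freedom denominator
#' `T_used - p - 1`, where `T_used = T - p` is the number of regression rows.
#'
#' @inheritParams build_design
#' @param include_intercept Keep the intercept term (default `TRUE`).
#' @return An object of class `ar_fit`: a list with `alpha`, `betas`,
#'   `sigma2`, `sse`, `residuals`, `T_used`, `p`, `aic`, and the training
#'   series.
#' @examples
#' y <- Reduce(function(acc, i) c(acc, 10 + 0.5 * acc[length(acc)]), 1:30, 100)
#' fit <- fit_ar(monthly_series(y), p = 1)
#' tidy(fit)
#' @export
fit_ar <- function(series, p, include_intercept = TRUE) {
  series <- ensure_series(series)
  y <- series$visits
  d <- build_design(y, p)
  X <- if (include_intercept) cbind(`(Intercept)` = 1, d$lags) else d$lags
  ls <- lm.fit(X, d$targets)
  if (ls$rank < ncol(X)) {
    abort("degenerate design: lag matrix is rank deficient (e.g. a constant series).")
  }
  coefs <- ls$coefficients
  alpha <- if (include_intercept) unname(coefs[1]) else 0
  betas <- unname(if (include_intercept) coefs[-1] else coefs)
  res <- unname(ls$residuals)
  sse <- sum(res^2)
  T_used <- length(d$targets)
  df <- T_used - p - as.integer(include_intercept)
  if (df < 1) abort("Not enough observations for the requested order.")
  structure(
    list(
      alpha = alpha, betas = betas,
      sigma2 = sse / df, sse = sse, residuals = res,
      T_used = T_used, p = p,
      aic = ar_aic(sse, length(y), p),
      include_intercept = include_intercept,
      train = series
    ),
    class = "ar_fit"
  )
}

#' AIC for an AR(p) fit
#'
#' The order-selection criterion used throughout the package:
#' \deqn{AIC(p) = \log\left(\frac{SSE_p}{T-p}\right) + \frac{(T-p) + 2p}{T-p},}
#' with natural logarithm, where `T` is the training length and `SSE` the
#' residual sum of squares of the lag-trimmed least-squares fit. A perfect
#' fit (`sse = 0`) returns `-Inf` so that an exactly-fitting order always
#' wins the order search.
#'
#' @param sse Residual sum of squares, >= 0.
#' @param T Training-set length (number of observation periods).
#' @param p Lag order, `1 <= p < T`.
#' @return The criterion value (scalar).
#' @examples
#' ar_aic(sse = 8, T = 10, p = 2)  # log(1) + 12/8 = 1.5
#' @export
ar_aic <- function(sse, T, p) {
  p <- check_order(p)
  if (!is.numeric(T) || T <= p) abort("Need T > p for the AIC denominator.")
  if (!is.numeric(sse) || sse < 0) abort("`sse` must be non-negative.")
  if (sse == 0) return(-Inf)
  log(sse / (T - p)) + ((T - p) + 2 * p) / (T - p)
}

#' Check AR stationarity from the lag coefficients
#'
#' An AR(p) process is stationary when all roots of the characteristic
#' polynomial \eqn{1 - \beta_1 z - \dots - \beta_p z^p} lie strictly
#' outside the unit circle.
#'
#' @param betas Numeric vector of lag coefficients.
#' @return `TRUE` if stationary, `FALSE` otherwise.
#' @examples
#' check_stationarity(0.5)        # TRUE  (root z = 2)
#' check_stationarity(1)          # FALSE (random walk)
#' check_stationarity(c(0.5, 0.5))  # FALSE (unit root at z = 1)
#' @export
check_stationarity <- function(betas) {
  if (length(betas) < 1) abort("Need at least one coefficient.")
  roots <- polyroot(c(1, -betas))
  all(Mod(roots) > 1 + 1e-8)
}

#' Select the AR lag order by minimising the AIC
#'
#' Fits orders `1..max_p` by least squares and returns the order with the
#' smallest [ar_aic()] value. When `check_stationarity` is on (the classical
#' regime), orders whose fitted coefficients fail the stationarity check are
#' excluded from the argmin; switching it off reproduces the extended
#' order search in which high, seasonal lag orders remain admissible. Ties
#' break toward the smaller order.
#'
#' @inheritParams build_design
#' @param max_p Largest order to try; defaults to half the series length.
#' @param check_stationarity Exclude non-stationary fits (default `TRUE`).
#' @return A list with `order` (the selected order) and `trace`, a tibble
#'   with one row per candidate order (`order`, `aic`, `stationary`,
#'   `admissible`).
#' @export
select_order <- function(series, max_p = NULL, check_stationarity = TRUE) {
  y <- series_values(series)
  n <- length(y)
  max_p <- if (is.null(max_p)) max(floor(n / 2), 1) else check_order(max_p)
  trace <- purrr::map_dfr(seq_len(max_p), function(p) {
    fit <- tryCatch(fit_ar(y, p), error = function(e) NULL)
    if (is.null(fit)) {
      return(tibble::tibble(order = p, aic = NA_real_, stationary = NA))
    }
    tibble::tibble(order = p, aic = fit$aic,
                   stationary = check_stationarity(fit$betas))
  })
  trace$admissible <- !is.na(trace$aic) &
    (!check_stationarity | (!is.na(trace$stationary) & trace$stationary))
  if (!any(trace$admissible)) {
    abort("No admissible order: every candidate fit failed or was non-stationary.")
  }
  cand <- trace[trace$admissible, ]
  best <- cand$order[which.min(cand$aic)]
  list(order = best, trace = trace)
}

#' Deterministic multistep AR forecast
#'
#' Iterates the AR recurrence with the noise term set to zero, feeding each
#' prediction back in as a lag (the classical plug-in multistep forecast).
#'
#' @param fit An `ar_fit` from [fit_ar()].
#' @param horizon Number of months ahead, >= 1.
#' @param seed_lags Optional numeric vector of the `p` observations
#'   preceding the forecast origin, most recent first; defaults to the last
#'   `p` training observations stored in the fit.
#' @return Numeric vector of length `horizon`.
#' @examples
#' fit <- list(alpha = 10, betas = 0.5)
#' # 10 + 0.5*100 = 60, then 40, then 30:
#' forecast_point(structure(fit, class = "ar_fit"), horizon = 3, seed_lags = 100)
#' @export
forecast_point <- function(fit, horizon, seed_lags = NULL) {
  if (!is.numeric(horizon) || horizon < 1) abort("`horizon` must be >= 1.")
  horizon <- as.integer(horizon)
  p <- length(fit$betas)
  if (is.null(seed_lags)) {
    seed_lags <- rev(tail(fit$train$visits, p))
  }
  if (length(seed_lags) != p) {
    abort(paste0("`seed_lags` must hold exactly p = ", p, " values."))
  }
  lags <- as.numeric(seed_lags)   # most recent first
  out <- numeric(horizon)
  for (h in seq_len(horizon)) {
    out[h] <- fit$alpha + sum(fit$betas * lags)
    lags <- c(out[h], lags)[seq_len(p)]
  }
  out
}

#' @export
print.ar_fit <- function(x, ...) {
  cat("AR(", x$p, ") least-squares fit on ", nrow(x$train), " months\n", sep = "")
  cat("  alpha:", format(x$alpha, digits = 5),
      " sigma2:", format(x$sigma2, digits = 5),
      " AIC:", format(x$aic, digits = 5), "\n")
  cat("  betas:", paste(format(x$betas, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname fit_ar
#' @param x,object An `ar_fit`.
#' @param ... Unused.
#' @method tidy ar_fit
#' @export
tidy.ar_fit <- function(x, ...) {
  tibble::tibble(
    term = c(if (x$include_intercept) "alpha", paste0("beta", seq_along(x$betas))),
    estimate = c(if (x$include_intercept) x$alpha, x$betas)
  )
}

#' @rdname fit_ar
#' @method glance ar_fit
#' @export
glance.ar_fit <- function(x, ...) {
  tibble::tibble(
    order = x$p, sigma2 = x$sigma2, sse = x$sse, aic = x$aic,
    T_used = x$T_used, stationary = check_stationarity(x$betas)
  )
}

check_order <- function(p) {
  if (!is.numeric(p) || length(p) != 1 || p < 1 || p != floor(p)) {
    abort("Lag order must be a single integer >= 1.")
  }
  as.integer(p)
}
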