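#' Moment skewness and kurtosis of a series
#'
#' Population-moment definitions: skewness \eqn{m_3 / m_2^{3/2}} and
#' non-excess kurtosis \eqn{m_4 / m_2^2} (a large normal sample gives
#' kurtosis near 3), where \eqn{m_k} is the k-th central sample moment.
#'
#' @param series A `monthly_series` or numeric vector, length >= 4 with
#'   non-zero variance.
#' @return A one-row tibble with `kurtosis` and `skewness`.
#' @export
moment_stats <- function(series) {
  x <- if (is.numeric(series)) as.numeric(series) else series_values(series)
  if (length(x) < 4) abort("Need at least 4 observations for moment statistics.")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) abort("Series has zero variance; moments are undefined.")
  tibble::tibble(
    kurtosis = mean((x - m)^4) / m2^2,
    skewness = mean((x - m)^3) / m2^(3 / 2)
  )
}

#' Ordinal pattern counts of a series
#'
#' Slides a window of `m` points at delay `tau` along the series and maps
#' each window to the permutation that sorts it (ties broken by earlier
#' position first). These pattern frequencies are the basis of
#' [permutation_entropy()].
#'
#' @param series A `monthly_series` or numeric vector.
#' @param m Embedding dimension (window length), >= 2.
#' @param tau Delay between window points, >= 1.
#' @return A tibble with `pattern` (dash-separated sort order) and `n`.
#' @export
ordinal_patterns <- function(series, m = 4, tau = 1) {
  x <- if (is.numeric(series)) as.numeric(series) else series_values(series)
  if (m < 2 || m != floor(m)) abort("`m` must be an integer >= 2.")
  if (tau < 1 || tau != floor(tau)) abort("`tau` must be an integer >= 1.")
  n_windows <- length(x) - (m - 1) * tau
  if (n_windows < 1) abort("Series too short for the requested embedding.")
  pats <- vapply(seq_len(n_windows), function(i) {
    w <- x[i + (0:(m - 1)) * tau]
    paste(order(w), collapse = "-")   # stable sort: ties keep position order
  }, character(1))
  out <- tibble::as_tibble(table(pattern = pats))
  names(out)[2] <- "n"
  out$n <- as.integer(out$n)
  out
}

#' Permutation entropy of a series
#'
#' Shannon entropy (natural log, nats) of the empirical distribution of
#' ordinal patterns in sliding windows of `m` points at delay `tau`. A
#' monotone series has a single pattern and entropy 0; white noise
#' approaches the maximum `log(factorial(m))`. Because the statistic is
#' rank-based it is invariant under any strictly increasing transform of
#' the values.
#'
#' @inheritParams ordinal_patterns
#' @return Scalar entropy in nats, in `[0, log(factorial(m))]`.
#' @export
permutation_entropy <- function(series, m = 4, tau = 1) {
  x <- if (is.numeric(series)) as.numeric(series) else series_values(series)
  if (length(x) < m * tau + 10) {
    abort("Series too short: need at least m*tau + 10 points.")
  }
  counts <- ordinal_patterns(x, m = m, tau = tau)$n
  p <- counts / sum(counts)
  -sum(p * log(p))
}

#' Seasonal-trend decomposition of a monthly series
#'
#' Additive seasonal/trend/remainder decomposition by LOESS (delegating to
#' [stats::stl()] with a periodic seasonal window), with the robust
#' fitting loop enabled by default. The three components reconstruct the
#' input exactly.
#'
#' @param series A `monthly_series` (or numeric vector), longer than two
#'   full periods.
#' @param period Seasonal period in months (default 12).
#' @param robust Use the robust LOESS iterations (default `TRUE`).
#' @return A tibble with columns `month` (if dated), `observed`,
#'   `seasonal`, `trend`, `remainder`.
#' @export
stl_components <- function(series, period = 12, robust = TRUE) {
  s <- ensure_series(series)
  y <- s$visits
  if (length(y) < 2 * period + 1) {
    abort(paste0("Need more than two full periods (> ", 2 * period,
                 " months) for the decomposition."))
  }
  dec <- stl(ts(y, frequency = period), s.window = "periodic", robust = robust)
  comp <- dec$time.series
  tibble::tibble(
    month = s$month,
    observed = y,
    seasonal = as.numeric(comp[, "seasonal"]),
    trend = as.numeric(comp[, "trend"]),
    remainder = as.numeric(comp[, "remainder"])
  )
}

#' Calendar-month profile of a series
#'
#' Reshapes the series into a year-by-calendar-month table for seasonal
#' (polar) plotting: cell (year, month) holds the observation of that
#' date, with `NA` padding where the first or last calendar year is
#' incomplete.
#'
#' @param series A `monthly_series`.
#' @return A tibble with `year` and one column per calendar month
#'   (`Jan`..`Dec`).
#' @export
seasonal_profile <- function(series) {
  s <- ensure_series(series)
  yr <- as.integer(format(s$month, "%Y"))
  mo <- as.integer(format(s$month, "%m"))
  years <- seq(min(yr), max(yr))
  mat <- matrix(NA_real_, nrow = length(years), ncol = 12,
                dimnames = list(NULL, month.abb))
  mat[cbind(match(yr, years), mo)] <- s$visits
  dplyr::bind_cols(tibble::tibble(year = years), tibble::as_tibble(mat))
}

#' One-row diagnostic summary of a series
#'
#' Bundles the moment statistics and permutation entropy used to
#' characterise visit series (heavy-tailedness, asymmetry, complexity).
#'
#' @inheritParams stl_components
#' @param pe_dim,pe_tau Embedding dimension and delay for the permutation
#'   entropy (defaults 4 and 1).
#' @return A one-row tibble: `n`, `kurtosis`, `skewness`,
#'   `permutation_entropy`.
#' @export
series_diagnostics <- function(series, pe_dim = 4, pe_tau = 1) {
  x <- series_values(series)
  dplyr::mutate(moment_stats(x),
                n = length(x), .before = 1,
                permutation_entropy = permutation_entropy(x, pe_dim, pe_tau))
}
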