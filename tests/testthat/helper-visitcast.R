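# Shared fixtures and independent oracles for the test suite.

# Deterministic first-order recurrence y_{t+1} = a + b * y_t (no noise).
exact_ar1 <- function(a, b, y0, n) {
  y <- numeric(n)
  y[1] <- y0
  for (t in seq_len(n)[-1]) y[t] <- a + b * y[t - 1]
  y
}

# Deterministic second-order recurrence (no noise).
exact_ar2 <- function(a, b1, b2, y0, y1, n) {
  y <- numeric(n)
  y[1] <- y0
  y[2] <- y1
  for (t in seq_len(n)[-(1:2)]) y[t] <- a + b1 * y[t - 1] + b2 * y[t - 2]
  y
}

# Numeric quadrature oracle for a single-coefficient full conditional:
# evaluates likelihood x prior on a dense grid and returns the normalised
# mean and variance. Independent of the package's conjugate algebra.
quad_coef_moments <- function(X, y, j, coefs, sigma2, prior,
                              lo = -10, hi = 10, step = 1e-4) {
  X <- as.matrix(X)
  grid <- seq(lo, hi, by = step)
  xj <- X[, j]
  partial <- y - as.vector(X[, -j, drop = FALSE] %*% coefs[-j])
  # column g holds the residuals if coefficient j were grid[g]
  sq <- colSums((matrix(partial, length(partial), length(grid)) -
                   outer(xj, grid))^2)
  logpost <- -sq / (2 * sigma2) -
    (grid - prior$coef_mean)^2 / (2 * prior$coef_var)
  w <- exp(logpost - max(logpost))
  m <- sum(w * grid) / sum(w)
  list(mean = m, variance = sum(w * (grid - m)^2) / sum(w))
}

# Numeric quadrature oracle for the noise-variance full conditional:
# likelihood x inverse-gamma prior on a dense sigma^2 grid.
quad_var_moments <- function(residuals, prior, n_grid = 2e5) {
  n <- length(residuals)
  sse <- sum(residuals^2)
  a <- prior$var_shape + n / 2
  b <- prior$var_scale + sse / 2
  lo <- b / stats::qgamma(1 - 1e-12, shape = a, rate = 1)
  hi <- b / stats::qgamma(1e-12, shape = a, rate = 1)
  grid <- seq(lo, hi, length.out = n_grid)
  logd <- -(n / 2) * log(grid) - sse / (2 * grid) -
    (prior$var_shape + 1) * log(grid) - prior$var_scale / grid
  w <- exp(logd - max(logd))
  m <- sum(w * grid) / sum(w)
  list(mean = m, variance = sum(w * (grid - m)^2) / sum(w))
}

# Inverse-gamma moments for a shape/scale pair (valid when shape > 2).
invgamma_moments <- function(shape, scale) {
  list(mean = scale / (shape - 1),
       variance = scale^2 / ((shape - 1)^2 * (shape - 2)))
}

# A compact Gibbs configuration for tests that only need a working chain.
quick_config <- function(seed = 1, iterations = 2000, burn_in = 500) {
  gibbs_config(iterations = iterations, burn_in = burn_in, seed = seed)
}

# Build a degenerate bayes_ar_fit whose posterior is a point mass.
point_mass_fit <- function(alpha, betas, sigma2, train, n_draws = 200) {
  p <- length(betas)
  draws <- tibble::as_tibble(
    matrix(rep(c(alpha, betas, sigma2), each = n_draws), nrow = n_draws,
           dimnames = list(NULL, c("alpha", paste0("beta", seq_len(p)), "sigma2")))
  )
  train <- visitcast:::ensure_series(train)
  structure(
    list(draws = draws, p = p, prior = prior_spec(),
         config = gibbs_config(n_draws + 1, 0),
         train = train, seed_lags = rev(utils::tail(train$visits, p))),
    class = "bayes_ar_fit"
  )
}
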