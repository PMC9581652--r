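#' Prior specification for the Bayesian AR model
#'
#' The intercept and every lag coefficient share an independent normal
#' prior; the noise variance gets an inverse-gamma prior with density
#' proportional to \eqn{x^{-a-1} e^{-b/x}} (shape `a`, scale `b`). The
#' defaults are a standard-normal prior on each coefficient and
#' inverse-gamma(1/2, 1/20) on the variance.
#'
#' Note that the N(0, 1) default is strongly informative on an intercept
#' when the series lives at the scale of thousands of visits; raise
#' `coef_var` for a weakly-informative analysis (the sampler-validation
#' harnesses do exactly that).
#'
#' @param coef_mean,coef_var Normal prior mean and variance shared by the
#'   intercept and all lag coefficients.
#' @param var_shape,var_scale Inverse-gamma shape and scale for the noise
#'   variance.
#' @return A `prior_spec` list.
#' @export
prior_spec <- function(coef_mean = 0, coef_var = 1,
                       var_shape = 1 / 2, var_scale = 1 / 20) {
  vals <- c(coef_mean, coef_var, var_shape, var_scale)
  if (!all(is.finite(vals))) abort("Prior hyperparameters must be finite.")
  if (coef_var <= 0 || var_shape <= 0 || var_scale <= 0) {
    abort("Prior variances, shapes and scales must be strictly positive.")
  }
  structure(list(coef_mean = coef_mean, coef_var = coef_var,
                 var_shape = var_shape, var_scale = var_scale),
            class = "prior_spec")
}

#' Gibbs sampler configuration
#'
#' @param iterations Total Gibbs iterations `M` (default 20000).
#' @param burn_in Iterations `N` discarded from the front (default 4000),
#'   `0 <= N < M`.
#' @param seed Optional integer seed; identical inputs and seed give
#'   bit-identical draws.
#' @param init Initialisation: `"least_squares"` starts from the OLS fit
#'   when the design is full rank (falling back to zeros otherwise),
#'   `"zeros"` starts all coefficients at zero with the sample variance of
#'   the targets as the initial noise variance.
#' @return A `gibbs_config` list.
#' @export
gibbs_config <- function(iterations = 20000, burn_in = 4000, seed = NULL,
                         init = c("least_squares", "zeros")) {
  init <- match.arg(init)
  if (iterations < 1 || burn_in < 0 || burn_in >= iterations) {
    abort("Need 0 <= burn_in < iterations.")
  }
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in),
                 seed = seed, init = init),
            class = "gibbs_config")
}

#' Full conditional of one regression coefficient
#'
#' Under the Gaussian AR likelihood and an independent N(m0, v0) prior on
#' coefficient `j` (given all other coefficients and the noise variance),
#' the full conditional is normal with
#' precision `1/v0 + sum(x_j^2)/sigma2` and mean
#' `variance * (m0/v0 + sum(x_j * r_j)/sigma2)`, where `r_j` is the partial
#' residual of each target excluding coefficient `j`. Column 1 of `X` is
#' the all-ones intercept column.
#'
#' @param X Design matrix including the intercept column of ones.
#' @param y Target vector.
#' @param j Index of the coefficient being updated (1 = intercept).
#' @param coefs Current values of all coefficients (length `ncol(X)`).
#' @param sigma2 Current noise variance, > 0.
#' @param prior A [prior_spec()].
#' @return A list with `mean` and `variance` of the normal conditional.
#' @export
coef_conditional <- function(X, y, j, coefs, sigma2, prior = prior_spec()) {
  if (!is.numeric(sigma2) || sigma2 <= 0) abort("`sigma2` must be > 0.")
  X <- as.matrix(X)
  if (nrow(X) == 0) {
    return(list(mean = prior$coef_mean, variance = prior$coef_var))
  }
  xj <- X[, j]
  partial <- y - drop(X[, -j, drop = FALSE] %*% coefs[-j])
  precision <- 1 / prior$coef_var + sum(xj^2) / sigma2
  mean <- (prior$coef_mean / prior$coef_var + sum(xj * partial) / sigma2) / precision
  list(mean = mean, variance = 1 / precision)
}

#' Full conditional of the noise variance
#'
#' With the inverse-gamma(shape, scale) prior and a Gaussian likelihood,
#' the full conditional of the noise variance given the coefficients is
#' inverse-gamma with shape `var_shape + n/2` and scale
#' `var_scale + SSE/2`, where SSE is the current residual sum of squares.
#'
#' @param residuals Current residual vector (may be empty).
#' @param prior A [prior_spec()].
#' @return A list with `shape` and `scale` of the inverse-gamma conditional.
#' @export
var_conditional <- function(residuals, prior = prior_spec()) {
  n <- length(residuals)
  list(shape = prior$var_shape + n / 2,
       scale = prior$var_scale + sum(residuals^2) / 2)
}

#' Gibbs sampling for the Bayesian AR(p) model
#'
#' Systematic-scan Gibbs sampler for the AR regression with independent
#' normal priors on the intercept and lag coefficients and an
#' inverse-gamma prior on the noise variance. Each iteration samples the
#' intercept, then each lag coefficient in turn (always conditioning on
#' the freshest values), then the noise variance; the first `burn_in`
#' iterations are discarded. No stationarity constraint is imposed on the
#' draws, which is what lets the model use high seasonal lag orders that a
#' stability-checked classical fit rejects.
#'
#' @inheritParams build_design
#' @param prior A [prior_spec()].
#' @param config A [gibbs_config()].
#' @param allow_large_order Permit `p >= length(series)/2` (default off).
#' @param scan_order Optional permutation of `1:p` giving the update order
#'   of the lag coefficients (the intercept always goes first); used to
#'   probe scan-order invariance.
#' @return An object of class `bayes_ar_fit`: a list carrying `draws`
#'   (a tibble with columns `alpha`, `beta1..betap`, `sigma2`, one row per
#'   retained iteration), the order `p`, the prior, the config, and the
#'   training series.
#' @examples
#' s <- generate_pure_ar(50, c(0.5, 0.3), 5, n = 120, seed = 1)
#' fit <- gibbs_sample(s, p = 2, config = gibbs_config(2000, 500, seed = 1))
#' tidy(fit)
#' @export
gibbs_sample <- function(series, p, prior = prior_spec(),
                         config = gibbs_config(),
                         allow_large_order = FALSE, scan_order = NULL) {
  series <- ensure_series(series)
  y_all <- series$visits
  p <- check_order(p)
  if (!allow_large_order && p >= length(y_all) / 2) {
    abort(paste0("p = ", p, " is >= half the series length ", length(y_all),
                 "; set allow_large_order = TRUE to override."))
  }
  d <- build_design(y_all, p)
  X <- cbind(1, d$lags)
  y <- d$targets
  n <- length(y)
  k <- p + 1
  if (is.null(scan_order)) scan_order <- seq_len(p)
  if (!setequal(scan_order, seq_len(p))) {
    abort("`scan_order` must be a permutation of 1:p.")
  }
  scan <- c(1L, as.integer(scan_order) + 1L)

  # initial state
  theta <- rep(0, k)
  sig2 <- max(var(y), 1e-8)
  if (config$init == "least_squares") {
    ls <- tryCatch(fit_ar(y_all, p), error = function(e) NULL)
    if (!is.null(ls)) {
      theta <- c(ls$alpha, ls$betas)
      sig2 <- max(ls$sigma2, 1e-12)
    }
  }

  m0 <- prior$coef_mean; v0 <- prior$coef_var
  a0 <- prior$var_shape; b0 <- prior$var_scale
  css <- colSums(X^2)
  M <- config$iterations; N <- config$burn_in
  draws <- matrix(NA_real_, M - N, k + 1)

  run_chain <- function() {
    r <- y - drop(X %*% theta)
    for (m in seq_len(M)) {
      for (j in scan) {
        xj <- X[, j]
        rj <- r + xj * theta[j]
        precision <- 1 / v0 + css[j] / sig2
        mu <- (m0 / v0 + sum(xj * rj) / sig2) / precision
        theta[j] <<- rnorm(1, mu, sqrt(1 / precision))
        r <- rj - xj * theta[j]
      }
      sig2 <<- 1 / rgamma(1, shape = a0 + n / 2, rate = b0 + sum(r^2) / 2)
      state <- c(theta, sig2)
      if (!all(is.finite(state))) {
        bad <- which(!is.finite(state))[1]
        par_names <- c("alpha", paste0("beta", seq_len(p)), "sigma2")
        abort(paste0("Non-finite draw for ", par_names[bad],
                     " at iteration ", m, "; the chain overflowed."))
      }
      if (m > N) draws[m - N, ] <<- state
    }
  }
  with_seed_maybe(config$seed, run_chain())

  colnames(draws) <- c("alpha", paste0("beta", seq_len(p)), "sigma2")
  structure(
    list(
      draws = tibble::as_tibble(draws),
      p = p, prior = prior, config = config,
      train = series,
      seed_lags = rev(tail(y_all, p))
    ),
    class = "bayes_ar_fit"
  )
}

#' Posterior summary and convergence diagnostics for a Gibbs chain
#'
#' For each parameter, reports the posterior mean and SD together with the
#' split-half mean gap: the absolute difference between the first-half and
#' second-half means of the retained chain, in units of the whole-chain
#' SD. A gap above `threshold` flags the parameter as not converged.
#'
#' @param draws A `bayes_ar_fit` or a data frame of retained draws (one
#'   column per parameter) with at least 200 rows.
#' @param threshold Flagging threshold on the split-half gap (default 0.5).
#' @return A tibble with columns `parameter`, `mean`, `sd`, `split_gap`,
#'   `converged`.
#' @export
chain_diagnostics <- function(draws, threshold = 0.5) {
  if (inherits(draws, "bayes_ar_fit")) draws <- draws$draws
  if (!is.data.frame(draws)) abort("`draws` must be a bayes_ar_fit or a data frame.")
  n <- nrow(draws)
  if (n < 200) abort("Need at least 200 retained draws for diagnostics.")
  half <- floor(n / 2)
  purrr::map_dfr(names(draws), function(par) {
    x <- draws[[par]]
    s <- sd(x)
    gap <- abs(mean(x[seq_len(half)]) - mean(x[(half + 1):n])) / s
    tibble::tibble(parameter = par, mean = mean(x), sd = s,
                   split_gap = gap, converged = gap <= threshold)
  })
}

#' AIC of a Bayesian AR fit from posterior-mean parameters
#'
#' Plugs the posterior means of the intercept and lag coefficients into the
#' one-step AR recurrence on the training set, forms the residual sum of
#' squares, and evaluates [ar_aic()]. This is the quantity traced against
#' the lag order in the extended order search.
#'
#' @param fit A `bayes_ar_fit`.
#' @param series Optional training series; defaults to the one stored in
#'   the fit.
#' @return The criterion value (scalar).
#' @export
posterior_aic <- function(fit, series = NULL) {
  series <- ensure_series(series %||% fit$train)
  y <- series$visits
  d <- build_design(y, fit$p)
  pm <- posterior_mean(fit)
  fitted <- drop(cbind(1, d$lags) %*% pm[seq_len(fit$p + 1)])
  sse <- sum((d$targets - fitted)^2)
  ar_aic(sse, length(y), fit$p)
}

#' Posterior means of all parameters
#'
#' @param fit A `bayes_ar_fit`.
#' @return Named numeric vector `(alpha, beta1..betap, sigma2)`.
#' @export
posterior_mean <- function(fit) {
  vapply(fit$draws, mean, numeric(1))
}

#' @export
print.bayes_ar_fit <- function(x, ...) {
  cat("Bayesian AR(", x$p, ") fit: ", nrow(x$draws), " retained draws (",
      x$config$iterations, " iterations, ", x$config$burn_in, " burn-in)\n",
      sep = "")
  print(tidy(x))
  invisible(x)
}

#' @rdname gibbs_sample
#' @param x,object A `bayes_ar_fit`.
#' @param ... Unused.
#' @method tidy bayes_ar_fit
#' @export
tidy.bayes_ar_fit <- function(x, ...) {
  purrr::map_dfr(names(x$draws), function(par) {
    v <- x$draws[[par]]
    tibble::tibble(term = par, estimate = mean(v), std.error = sd(v),
                   conf.low = unname(quantile(v, 0.025)),
                   conf.high = unname(quantile(v, 0.975)))
  })
}

#' @rdname gibbs_sample
#' @method glance bayes_ar_fit
#' @export
glance.bayes_ar_fit <- function(x, ...) {
  tibble::tibble(
    order = x$p,
    iterations = x$config$iterations,
    burn_in = x$config$burn_in,
    retained = nrow(x$draws),
    sigma2 = mean(x$draws$sigma2),
    aic = posterior_aic(x)
  )
}
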