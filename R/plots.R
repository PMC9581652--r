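#' Fan chart of a posterior-predictive forecast
#'
#' Draws the point forecast with the nested central prediction intervals
#' as graded ribbons; optionally overlays the observed series.
#'
#' @param object A `forecast_dist`.
#' @param series Optional `monthly_series` of observations to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot forecast_dist
#' @export
autoplot.forecast_dist <- function(object, series = NULL, ...) {
  iv <- object$intervals
  iv$month <- object$summary$month[iv$step]
  p <- ggplot2::ggplot() +
    ggplot2::geom_ribbon(
      data = iv,
      ggplot2::aes(x = .data$month, ymin = .data$lower, ymax = .data$upper,
                   group = .data$level, alpha = -.data$level),
      fill = "steelblue", show.legend = FALSE
    ) +
    ggplot2::geom_line(
      data = object$summary,
      ggplot2::aes(x = .data$month, y = .data$point),
      colour = "navy", linewidth = 0.7
    ) +
    ggplot2::scale_alpha_continuous(range = c(0.05, 0.35)) +
    ggplot2::labs(x = NULL, y = "visits / month",
                  title = "Posterior-predictive forecast")
  if (!is.null(series)) {
    s <- ensure_series(series)
    p <- p + ggplot2::geom_line(
      data = s, ggplot2::aes(x = .data$month, y = .data$visits),
      colour = "grey30", linewidth = 0.4
    )
  }
  p
}

#' Trace and density plots of a Gibbs chain
#'
#' @param object A `bayes_ar_fit`.
#' @param type `"trace"` or `"density"`.
#' @param ... Unused.
#' @return A ggplot object faceted by parameter.
#' @method autoplot bayes_ar_fit
#' @export
autoplot.bayes_ar_fit <- function(object, type = c("trace", "density"), ...) {
  type <- match.arg(type)
  long <- tidyr::pivot_longer(
    dplyr::mutate(object$draws, .iteration = dplyr::row_number()),
    -".iteration", names_to = "parameter", values_to = "value"
  )
  if (type == "trace") {
    ggplot2::ggplot(long, ggplot2::aes(x = .data$.iteration, y = .data$value)) +
      ggplot2::geom_line(linewidth = 0.2, colour = "steelblue") +
      ggplot2::facet_wrap(~parameter, scales = "free_y") +
      ggplot2::labs(x = "retained iteration", y = NULL,
                    title = "Gibbs sampling traces")
  } else {
    ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
      ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
      ggplot2::facet_wrap(~parameter, scales = "free") +
      ggplot2::labs(x = NULL, y = "posterior density")
  }
}

#' MAPE stability curve across training fractions
#'
#' @param object A `stability_curve` from [stability_analysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot stability_curve
#' @export
autoplot.stability_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fraction, y = .data$mape)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = "training fraction", y = "MAPE (%)",
                  title = "Forecast stability across training fractions")
}

#' Seasonal-trend decomposition panel
#'
#' Facets the observed series and its seasonal, trend, and remainder
#' components, mirroring the usual STL display.
#'
#' @param series A `monthly_series`.
#' @param period,robust Passed to [stl_components()].
#' @return A ggplot object.
#' @export
plot_stl <- function(series, period = 12, robust = TRUE) {
  comp <- stl_components(series, period = period, robust = robust)
  long <- tidyr::pivot_longer(comp, -"month",
                              names_to = "component", values_to = "value")
  long$component <- factor(long$component,
                           levels = c("observed", "seasonal", "trend", "remainder"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$month, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$component), scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, title = "Seasonal-trend decomposition")
}

#' Polar seasonal plot of a monthly series
#'
#' One line per calendar year over a circular month axis; distance from
#' the centre is the visit volume, making the annual cycle and its
#' mid-year peak directly visible.
#'
#' @param series A `monthly_series`.
#' @return A ggplot object.
#' @export
plot_seasonal <- function(series) {
  prof <- seasonal_profile(series)
  long <- tidyr::pivot_longer(prof, -"year",
                              names_to = "month", values_to = "visits")
  long$month <- factor(long$month, levels = month.abb)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$month, y = .data$visits,
                                     group = .data$year,
                                     colour = factor(.data$year))) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::coord_polar() +
    ggplot2::labs(x = NULL, y = "visits / month", colour = "year",
                  title = "Seasonal profile")
}
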