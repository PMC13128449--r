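#' Plot a fitted recovery trajectory
#'
#' Shows the per-plot points of one legacy, the fitted
#' negative-exponential curve, and the active-plot and old-growth
#' reference levels. A dashed curve marks a return rate not significantly
#' different from zero.
#'
#' @param object A `recovery_fit`.
#' @param t_max Right edge of the time axis (years).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.recovery_fit <- function(object, t_max = NULL, ...) {
  t_max <- t_max %||% max(object$data$age_years, 38)
  curve <- tibble::tibble(
    t = seq(0, t_max, length.out = 200),
    psi = predict(object, seq(0, t_max, length.out = 200))
  )
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$age_years, y = .data$value)) +
    ggplot2::geom_hline(yintercept = object$psi_ref,
                        colour = "darkgreen", linetype = "dotted") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_line(
      data = curve, ggplot2::aes(x = .data$t, y = .data$psi),
      colour = "steelblue",
      linetype = if (isTRUE(object$lambda_significant)) "solid" else "dashed"
    ) +
    ggplot2::labs(
      x = "Years since abandonment",
      y = object$metric,
      title = paste0(object$metric, " recovery (", object$legacy, " legacy)"),
      subtitle = sprintf("lambda = %.3g per year, R² = %.2f",
                         object$lambda, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' @export
plot.recovery_fit <- function(x, ...) print(autoplot.recovery_fit(x, ...))

#' Plot a jackknife trajectory band
#'
#' Full-data fitted curve with the pointwise percentile envelope of the
#' leave-one-out replicate curves.
#'
#' @param object A `resilience_jackknife`.
#' @param times Time grid in years.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.resilience_jackknife <- function(object,
                                          times = seq(0, 40, by = 0.5),
                                          ...) {
  band <- jackknife_band(object, times = times)
  ggplot2::ggplot(band, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      fill = "steelblue", alpha = 0.25
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit), colour = "steelblue") +
    ggplot2::labs(
      x = "Years since abandonment", y = object$metric,
      title = paste0(object$taxon, ": ", object$metric, " (",
                     object$legacy, " legacy)"),
      subtitle = "95% jackknife envelope"
    ) +
    ggplot2::theme_minimal()
}

#' @export
plot.resilience_jackknife <- function(x, ...) {
  print(autoplot.resilience_jackknife(x, ...))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
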