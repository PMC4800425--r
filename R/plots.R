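#' Plot a power-law fit with its confidence band
#'
#' Scatter of the animal-period pairs (bout count vs mean bout length), the
#' fitted curve, and the dotted 95% confidence band, annotated with the
#' fitted equation and R^2 in the style of a figure inset.
#'
#' @param object A `powerlaw_fit`.
#' @param band Draw the delta-method confidence band (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.powerlaw_fit <- function(object, band = TRUE, ...) {
  d <- object$data
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.6)
  grid <- seq(min(d$x), max(d$x), length.out = 200)
  curve <- tibble::tibble(x = grid, y = object$a * grid^object$b)
  p <- p + ggplot2::geom_line(data = curve, colour = "black")
  if (band && object$converged) {
    cb <- confidence_band(object, x_grid = grid)
    p <- p +
      ggplot2::geom_line(data = cb, ggplot2::aes(y = .data$lower),
                         linetype = "dotted") +
      ggplot2::geom_line(data = cb, ggplot2::aes(y = .data$upper),
                         linetype = "dotted")
  }
  p + ggplot2::labs(
    x = "Sleep bout count", y = "Mean sleep bout length (min)",
    title = if (!is.na(object$label)) object$label else NULL,
    subtitle = sprintf("Y = %.3g · X^%.3g;  R² = %.3f",
                       object$a, object$b, object$r_squared)
  ) + ggplot2::theme_minimal()
}

#' @export
plot.powerlaw_fit <- function(x, ...) print(autoplot.powerlaw_fit(x, ...))

#' Activity raster of a trace cohort
#'
#' One row per animal, minutes on the x axis; sleep minutes (zero counts)
#' light, active minutes dark, with day/night boundaries marked.
#'
#' @param trace Trace tibble.
#' @return A ggplot object.
#' @export
plot_trace <- function(trace) {
  check_trace(trace)
  d <- dplyr::mutate(trace,
                     abs_min = (.data$day_index - 1L) * DAY_MIN + .data$zt_minute)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$abs_min / 60, y = .data$animal_id,
                                  fill = .data$count > 0)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey90", `TRUE` = "grey20"),
                               labels = c("inactive", "active"), name = NULL) +
    ggplot2::geom_vline(xintercept = seq(0, max(d$abs_min) / 60, by = 12),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::labs(x = "Hours from first lights-on", y = NULL) +
    ggplot2::theme_minimal()
}
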