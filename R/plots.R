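# ggplot2 views of the two result types. The field's standard picture is
# width d against the scaling abscissa D^2 sqrt(dP), one panel or colour
# per stage speed, with the model as a line and measurements as points.

#' @export
#' @method autoplot width_comparison
autoplot.width_comparison <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object),
    cols = c("width_um", "width_pred_um"),
    names_to = "source", values_to = "width"
  ) |>
    mutate(source = ifelse(.data$source == "width_um", "measured", "model"))
  ggplot2::ggplot(
    long,
    ggplot2::aes(.data$d2_sqrt_p, .data$width,
      colour = factor(.data$speed), linetype = .data$source,
      shape = .data$source
    )
  ) +
    ggplot2::geom_point(data = ~ filter(.x, .data$source == "measured")) +
    ggplot2::geom_line(data = ~ filter(.x, .data$source == "model")) +
    ggplot2::labs(
      x = expression(D^2 * sqrt(Delta * P) ~ (m^2 ~ Pa^0.5)),
      y = "line width (um)",
      colour = "speed (m/s)", linetype = NULL, shape = NULL,
      title = "Measured vs predicted line width"
    )
}

#' Width-scaling plot for a prediction sweep
#'
#' Plots predicted line width against the scaling abscissa D^2 sqrt(dP),
#' one line per stage speed, optionally overlaying measured runs.
#'
#' @param pred A [predict_width()] / [sweep_design()] result.
#' @param runs Optional `print_runs` tibble of measurements to overlay.
#' @return A ggplot.
#' @export
plot_width_scaling <- function(pred, runs = NULL) {
  p <- ggplot2::ggplot(
    as_tibble(pred),
    ggplot2::aes(.data$d2_sqrt_p, .data$width_pred_um,
      colour = factor(.data$speed)
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(shape = 1) +
    ggplot2::labs(
      x = expression(D^2 * sqrt(Delta * P) ~ (m^2 ~ Pa^0.5)),
      y = "predicted line width (um)", colour = "speed (m/s)"
    )
  if (!is.null(runs)) {
    meas <- filter(as_tibble(runs), !is.na(.data$width_um)) |>
      mutate(d2_sqrt_p = .data$diameter^2 * sqrt(.data$pressure))
    p <- p + ggplot2::geom_point(
      data = meas,
      ggplot2::aes(.data$d2_sqrt_p, .data$width_um, colour = factor(.data$speed)),
      shape = 17
    )
  }
  p
}
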