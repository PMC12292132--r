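#' Plot a reference band, optionally with records
#'
#' Mean growth curve with the +/-2 SD envelope over the reference's
#' gestational-age range; records, when supplied, are overplotted and
#' coloured by anomaly status.
#'
#' @param object A `growth_reference`.
#' @param records Optional records data frame of the same parameter.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.growth_reference <- function(object, records = NULL, ...) {
  days <- seq(object$ga_range[1], object$ga_range[2])
  bands <- evaluate_bands(object, days)
  p <- ggplot2::ggplot(bands, ggplot2::aes(x = .data$ga_days)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         fill = "grey85") +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), colour = "red") +
    ggplot2::labs(
      x = "Gestational age (days)",
      y = sprintf("%s (%s)", object$parameter, object$units),
      title = sprintf("%s reference: mean curve with ±2 SD band",
                      object$parameter)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(records)) {
    flagged <- flag_anomalies(records, object)
    p <- p + ggplot2::geom_point(
      data = flagged,
      ggplot2::aes(y = .data$value, colour = .data$status),
      size = 0.6, alpha = 0.6
    ) +
      ggplot2::scale_colour_manual(values = c(
        normal = "grey30", above_upper = "#d95f02", below_lower = "#7570b3"
      ))
  }
  p
}

#' Plot per-day empirical summaries
#'
#' Scatter of raw values with the daily mean and mean +/- 2 SD dots, the
#' raw-data distribution view plotted next to fitted reference curves.
#'
#' @param data Records data frame of a single parameter.
#' @return A ggplot object.
#' @export
plot_daily_summary <- function(data) {
  data <- validate_records(data)
  daily <- daily_summary(data)
  ggplot2::ggplot(data, ggplot2::aes(x = .data$ga_days)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$value), colour = "black",
                        size = 0.4, alpha = 0.3) +
    ggplot2::geom_point(data = daily, ggplot2::aes(y = .data$mean),
                        colour = "red", size = 0.8) +
    ggplot2::geom_point(data = daily, ggplot2::aes(y = .data$upper),
                        colour = "darkgreen", size = 0.6) +
    ggplot2::geom_point(data = daily, ggplot2::aes(y = .data$lower),
                        colour = "darkgreen", size = 0.6) +
    ggplot2::labs(x = "Gestational age (days)",
                  y = unique(data$parameter)) +
    ggplot2::theme_minimal()
}

#' Plot per-fold cross-validation R-squared
#'
#' @param object A `growth_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.growth_cv <- function(object, ...) {
  ggplot2::ggplot(object$folds,
                  ggplot2::aes(x = factor(.data$fold), y = .data$r2)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mean_r2, linetype = "dashed") +
    ggplot2::labs(
      x = "Fold", y = expression(R^2),
      title = sprintf("%s: %d-fold cross-validation", object$parameter,
                      object$k)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
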