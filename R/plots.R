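# Diagnostic figures: enrichment kinetics and calibration curves.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a logistic labeling fit
#'
#' Observed enrichment points with the fitted logistic curve and the T50
#' marker.
#'
#' @param object A converged `logistic_fit`.
#' @param ... Unused.
#' @export
autoplot.logistic_fit <- function(object, ...) {
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(x = .data$time_min, y = .data$enrichment)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Time (min)", y = "Mean 13C enrichment") +
    ggplot2::theme_bw()
  if (object$converged) {
    grid <- tibble::tibble(
      time_min = seq(min(object$data$time_min), max(object$data$time_min),
                     length.out = 200)
    )
    grid$enrichment <- logistic_enrichment(grid$time_min, object$k,
                                           object$y0, object$T)
    p <- p +
      ggplot2::geom_line(data = grid, colour = "steelblue") +
      ggplot2::geom_vline(xintercept = object$t50, linetype = "dashed",
                          colour = "grey40") +
      ggplot2::annotate("text", x = object$t50, y = 0,
                        label = sprintf("T50 = %.1f min", object$t50),
                        hjust = -0.1, vjust = -0.5, size = 3)
  }
  p
}

#' Plot a calibration curve
#'
#' Ratio vs amount on log-log axes, the fitted line, and the validated
#' linear range when present.
#'
#' @param object A `calibration_curve`.
#' @param ... Unused.
#' @export
autoplot.calibration_curve <- function(object, ...) {
  pts <- object$points
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$level_pmol, y = .data$ratio)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = NA) +
    ggplot2::stat_function(
      fun = function(x) object$intercept + object$slope * x,
      colour = "steelblue"
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Amount on column (pmol)", y = "12C/13C area ratio",
                  title = object$compound,
                  subtitle = sprintf("R² = %.4f", object$r_squared)) +
    ggplot2::theme_bw()
  if (!is.na(object$linear_range[1])) {
    p <- p + ggplot2::geom_vline(xintercept = object$linear_range,
                                 linetype = "dotted", colour = "grey40")
  }
  p
}

#' Plot enrichment time courses per metabolite
#'
#' @param df Output of [enrichment_series()].
#' @param colour Column mapped to colour (default strain if present).
#' @export
plot_enrichment <- function(df, colour = NULL) {
  colour <- colour %||% (if ("strain" %in% names(df)) "strain" else NULL)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_min,
                                        y = .data$mean_enrichment))
  p <- if (is.null(colour)) {
    p + ggplot2::geom_line() + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_line(ggplot2::aes(colour = .data[[colour]])) +
      ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]))
  }
  p + ggplot2::facet_wrap(~metabolite) +
    ggplot2::labs(x = "Time (min)", y = "Mean 13C enrichment") +
    ggplot2::theme_bw()
}

#' Plot isotopologue distributions over time
#'
#' Stacked-area view of the labeling trajectory of one pool.
#'
#' @param trajectory Output of [simulate_labeling()].
#' @param metabolite Pool to display.
#' @export
plot_isotopologues <- function(trajectory, metabolite) {
  df <- dplyr::filter(trajectory, .data$metabolite == !!metabolite)
  if (nrow(df) == 0) stop("no rows for ", metabolite)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_min, y = .data$fraction,
                                   fill = factor(.data$m_index))) +
    ggplot2::geom_area(position = "stack") +
    ggplot2::labs(x = "Time (min)", y = "Isotopologue fraction",
                  fill = "13C atoms", title = metabolite) +
    ggplot2::theme_bw()
}
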