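#' Plot a diurnal affect curve
#'
#' Draws the 24-point population rhythm for each dimension: the mean
#' relative probability by clock hour, one panel per dimension with free
#' y scales since the dimensions live on very different rate scales.
#'
#' @param object A [diurnal_curve()] tibble.
#' @param dimensions Optional subset of dimensions to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot diurnal_curve
#' @export
autoplot.diurnal_curve <- function(object, dimensions = NULL, ...) {
  df <- tibble::as_tibble(object)
  df$dimension <- as.character(df$dimension)
  if (!is.null(dimensions)) {
    df <- dplyr::filter(df, .data$dimension %in% dimensions)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hour, y = .data$rpa_mean)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(size = 0.8, na.rm = TRUE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$dimension), scales = "free_y") +
    ggplot2::scale_x_continuous(breaks = seq(0, 23, 6)) +
    ggplot2::labs(x = "Clock hour", y = "Relative probability of affect") +
    ggplot2::theme_minimal()
}

#' Plot permutation-regression coefficients
#'
#' Dot plot of the fitted coefficients with their permutation p-values;
#' terms significant at `alpha` are highlighted.
#'
#' @param object A [perm_lm()] fit.
#' @param alpha Significance threshold for highlighting (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot perm_lm
#' @export
autoplot.perm_lm <- function(object, alpha = 0.05, ...) {
  df <- tidy(object)
  df <- dplyr::filter(df, .data$term != "(Intercept)")
  df$significant <- df$p_value < alpha
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate,
                                   y = stats::reorder(.data$term, .data$estimate),
                                   colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#D55E00", `FALSE` = "grey40"),
                                 name = sprintf("p < %.2g", alpha)) +
    ggplot2::labs(x = "Coefficient", y = NULL,
                  title = sprintf("%s (%s scheme, B = %d)",
                                  object$outcome, object$scheme, object$B)) +
    ggplot2::theme_minimal()
}
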