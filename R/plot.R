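#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fitted three-category psychometric function
#'
#' Observed response proportions (points) with the fitted left, middle and
#' right curves, plus dashed verticals at the curve crossings whose
#' distance is the cone width.
#'
#' @param object A `cone_fit` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cone_fit <- function(object, ...) {
  counts <- object$counts
  obs <- tibble::tibble(
    azimuth_deg = rep(counts$azimuth_deg, 3),
    category = rep(c("left", "middle", "right"), each = nrow(counts)),
    proportion = c(counts$n_left, counts$n_middle, counts$n_right) /
      rep(counts$n_total, 3)
  )
  xx <- seq(min(counts$azimuth_deg), max(counts$azimuth_deg), length.out = 201)
  pred <- predict_proportions(object$params, xx) |>
    tidyr::pivot_longer(cols = c("p_left", "p_middle", "p_right"),
                        names_to = "category", values_to = "proportion",
                        names_prefix = "p_")
  cr <- find_crossings(object)
  p <- ggplot2::ggplot(obs, ggplot2::aes(x = .data$azimuth_deg,
                                         y = .data$proportion,
                                         colour = .data$category)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = pred) +
    ggplot2::labs(x = "azimuth (deg, negative = left)",
                  y = "response proportion", colour = NULL) +
    ggplot2::theme_minimal()
  if (cr$status == "ok") {
    p <- p + ggplot2::geom_vline(xintercept = c(cr$x_left_cross,
                                                cr$x_right_cross),
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' Plot cone widths by condition
#'
#' Violin plots of per-participant cone widths per visual condition, with
#' participant trajectories drawn as thin lines.
#'
#' @param widths A [cone_widths()] table (rows with `fit_ok = FALSE` are
#'   dropped).
#' @return A ggplot.
#' @export
plot_cone_widths <- function(widths) {
  d <- prepare_width_data(widths)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$condition, y = .data$width)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$participant_id),
                       alpha = 0.2, colour = "grey50") +
    ggplot2::geom_violin(ggplot2::aes(fill = .data$condition), alpha = 0.5) +
    ggplot2::stat_summary(fun = mean, geom = "point", size = 2) +
    ggplot2::labs(x = NULL, y = "cone width (deg)") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
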