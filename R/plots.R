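#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Coefficient-interval plot for a fitted huddle GLM
#'
#' Dot-and-whisker plot of the estimated regression coefficients with their
#' 95 percent Wald intervals, the usual companion to the numeric summary.
#'
#' @param object A `huddle_glm`.
#' @param intercept Include the intercept term (default `FALSE`; its scale
#'   usually dwarfs the predictor effects).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.huddle_glm <- function(object, intercept = FALSE, ...) {
  tb <- coefficient_summary(object)
  if (!intercept) tb <- tb[tb$term != "(Intercept)", ]
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.15
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "coefficient estimate (log link)", y = NULL,
      title = sprintf("Count GLM coefficients (%s)",
                      if (object$family == "negbin") {
                        "negative binomial"
                      } else {
                        "Poisson"
                      })
    ) +
    ggplot2::theme_minimal()
}

#' Simulated cluster size against temperature, with empirical site lines
#'
#' Plots the per-run mean cluster size of a sweep against temperature,
#' with one least-squares line per joining threshold, and overlays the
#' built-in empirical site lines for visual comparison.
#'
#' @param table A sweep result table (one group size per facet).
#' @param sites Site lines to overlay (default [builtin_site_lines()];
#'   `NULL` for none).
#' @return A ggplot object.
#' @export
plot_temperature_lines <- function(table, sites = builtin_site_lines()) {
  tb <- dplyr::filter(table, !.data$no_cluster)
  p <- ggplot2::ggplot(tb, ggplot2::aes(x = .data$temperature,
                                        y = .data$mean_cluster_size)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$join_threshold)),
                        alpha = 0.3, size = 0.8) +
    ggplot2::geom_smooth(
      ggplot2::aes(colour = factor(.data$join_threshold)),
      method = "lm", formula = y ~ x, se = FALSE, linewidth = 0.6
    ) +
    ggplot2::facet_wrap(~group_size, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "temperature", y = "individuals per cluster",
                  colour = "join\nthreshold") +
    ggplot2::theme_minimal()
  if (!is.null(sites)) {
    p <- p + ggplot2::geom_abline(
      data = sites,
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept,
                   linetype = .data$site),
      colour = "black"
    ) +
      ggplot2::labs(linetype = "site")
  }
  p
}
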