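#' Forest plot of metaboliser-status association results
#'
#' Odds ratios with 95% confidence intervals per contrast, faceted by
#' outcome family and scope, on a log scale with a reference line at
#' OR = 1.
#'
#' @param object A `pgx_results` tibble from [run_primary_analysis()].
#' @param families Optional subset of families to show (the side-effect
#'   scan is omitted by default).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pgx_results <- function(object,
                                 families = setdiff(unique(object$family),
                                                    "side_effect_scan"),
                                 ...) {
  dat <- object[object$family %in% families, ]
  dat$contrast <- factor(dat$contrast,
                         levels = rev(c("poor", "intermediate", "rapid",
                                        "ultrarapid")))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$or, y = .data$contrast,
                                    colour = .data$family)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      position = ggplot2::position_dodge(width = 0.6)
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$scope)) +
    ggplot2::labs(x = "odds ratio (vs normal metabolisers)", y = NULL,
                  colour = "outcome") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.pgx_results
#' @param results A `pgx_results` tibble.
#' @export
plot_forest <- function(results, ...) autoplot.pgx_results(results, ...)

#' Power curves from a simulation grid
#'
#' Estimated power (with Monte-Carlo error bars) against the log-odds
#' effect size, one curve per metaboliser status, with the 80% target line.
#'
#' @param object A `power_grid` from [estimate_power()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.power_grid <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$effect, y = .data$power,
                                       colour = .data$status)) +
    ggplot2::geom_hline(yintercept = 0.8, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = pmax(.data$power - 1.96 * .data$mc_se, 0),
      ymax = pmin(.data$power + 1.96 * .data$mc_se, 1)
    )) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "effect size (log-odds vs normal)",
                  y = "estimated power", colour = "status") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.power_grid
#' @param grid A `power_grid` tibble.
#' @export
plot_power_curves <- function(grid, ...) autoplot.power_grid(grid, ...)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
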