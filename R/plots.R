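# ggplot2 presentations of PSA results.

#' Cost-utility plane plot
#'
#' Scatter of replicate (incremental QALY, incremental cost) pairs with the
#' willingness-to-pay threshold as a line through the origin; replicates to
#' the right of the line are cost-effective.
#'
#' @param replicates A [run_psa()] result (or a tibble with `delta_qaly`
#'   and `delta_cost`).
#' @param lambda Willingness-to-pay threshold (EUR/QALY).
#' @return A ggplot object.
#' @export
plot_cu_plane <- function(replicates, lambda = 30000) {
  plane <- plane_export(replicates, lambda)
  ggplot2::ggplot(plane,
                  ggplot2::aes(x = .data$delta_qaly, y = .data$delta_cost,
                               colour = .data$cost_effective)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_abline(slope = lambda, intercept = 0,
                         colour = "red", linetype = 2) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#2166ac", `FALSE` = "#b2182b"),
      name = paste0("NMB > 0 at ", format(lambda, big.mark = ","),
                    " EUR/QALY")) +
    ggplot2::labs(x = "Incremental effect (QALY)",
                  y = "Incremental cost (EUR)",
                  title = "Cost-utility plane") +
    ggplot2::theme_minimal()
}

#' Acceptability curve plot
#'
#' @param curve A [ceac()] curve.
#' @param lambda_ref Optional reference threshold drawn as a vertical line.
#' @return A ggplot object.
#' @export
plot_ceac <- function(curve, lambda_ref = 30000) {
  p <- ggplot2::ggplot(curve,
                       ggplot2::aes(x = .data$lambda,
                                    y = .data$probability)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::geom_hline(yintercept = 0.5, colour = "grey60", linetype = 3) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Willingness to pay (EUR per QALY)",
                  y = "P(cost-effective)",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
  if (!is.null(lambda_ref)) {
    p <- p + ggplot2::geom_vline(xintercept = lambda_ref,
                                 colour = "red", linetype = 2)
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.psa_result <- function(object, lambda = 30000, ...) {
  plot_cu_plane(object, lambda)
}

#' @exportS3Method ggplot2::autoplot
autoplot.ceac_curve <- function(object, lambda_ref = 30000, ...) {
  plot_ceac(object, lambda_ref)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
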