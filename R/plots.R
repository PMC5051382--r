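# ggplot2 layers for PSA results.

#' Plot the cost-effectiveness plane
#'
#' Scatter of per-iteration (incremental QALY, incremental cost) pairs,
#' faceted by duration-of-effect scenario, with a willingness-to-pay line.
#'
#' @param psa A `cea_psa` object.
#' @param threshold Willingness-to-pay line to draw (GBP/QALY); `NULL`
#'   omits it.
#' @return A ggplot object.
#' @export
plot_plane <- function(psa, threshold = 20000) {
  inc <- psa_increments(psa)
  p <- ggplot2::ggplot(
    inc,
    ggplot2::aes(x = .data$delta_qaly, y = .data$delta_cost)
  ) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$scenario)) +
    ggplot2::labs(
      x = "Incremental QALYs",
      y = "Incremental cost (GBP)",
      title = "Cost-effectiveness plane by duration of effect"
    )
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_abline(
      slope = threshold, intercept = 0,
      linetype = "dashed", colour = "grey40"
    )
  }
  p
}

#' Plot cost-effectiveness acceptability curves
#'
#' Probability of positive net monetary benefit against the
#' willingness-to-pay threshold, one curve per duration-of-effect
#' scenario.
#'
#' @param psa A `cea_psa` object.
#' @param thresholds Threshold grid (GBP/QALY).
#' @return A ggplot object.
#' @export
plot_ceac <- function(psa, thresholds = default_thresholds()) {
  cc <- ceac(psa, thresholds)
  ggplot2::ggplot(
    cc,
    ggplot2::aes(
      x = .data$threshold, y = .data$prob_ce,
      colour = .data$scenario
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Willingness to pay (GBP per QALY)",
      y = "Probability cost-effective",
      colour = "Duration of effect",
      title = "Cost-effectiveness acceptability curves"
    )
}

#' Autoplot a PSA result
#'
#' @param object A `cea_psa` object.
#' @param type `"ceac"` for acceptability curves or `"plane"` for the
#'   cost-effectiveness plane.
#' @param ... Passed to [plot_ceac()] or [plot_plane()].
#' @return A ggplot object.
#' @method autoplot cea_psa
#' @export
autoplot.cea_psa <- function(object, type = c("ceac", "plane"), ...) {
  type <- match.arg(type)
  switch(type,
    ceac = plot_ceac(object, ...),
    plane = plot_plane(object, ...)
  )
}
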