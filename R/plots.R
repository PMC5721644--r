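# ggplot2 figures for the sensitivity analyses. ggplot2 is suggested, not
# imported: each function checks for it at call time.

need_ggplot2 <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package")
  }
}

#' Cost-effectiveness plane
#'
#' @param res A `psa_result`.
#' @param wtp Willingness-to-pay threshold drawn as a reference line.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(res, wtp = 20000) {
  need_ggplot2()
  pts <- ce_plane(res)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$delta_qaly, y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Incremental QALYs (intervention - usual care)",
                  y = "Incremental cost (£)",
                  title = "Cost-effectiveness plane")
}

#' Cost-effectiveness acceptability curve
#'
#' @param ceac_df Output of [ceac()].
#' @return A ggplot object.
#' @export
plot_ceac <- function(ceac_df) {
  need_ggplot2()
  ggplot2::ggplot(ceac_df, ggplot2::aes(x = .data$wtp, y = .data$p_intervention)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (£/QALY)",
                  y = "P(early PRP cost-effective)",
                  title = "Cost-effectiveness acceptability curve")
}

#' Tornado diagram of net monetary benefit
#'
#' @param tornado_df Output of [tornado()].
#' @param top Number of widest bars to show.
#' @return A ggplot object.
#' @export
plot_tornado <- function(tornado_df, top = 12) {
  need_ggplot2()
  df <- utils::head(tornado_df, top)
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  base_nmb <- attr(tornado_df, "base_nmb")
  ggplot2::ggplot(df, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$nmb_low, xend = .data$nmb_high,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base_nmb, linetype = "dashed") +
    ggplot2::labs(x = "Net monetary benefit (£)", y = NULL,
                  title = "Tornado diagram, net monetary benefit")
}
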