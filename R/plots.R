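#' Tornado diagram of a one-way sensitivity analysis
#'
#' Horizontal bars spanning the ICUR at each parameter's bounds, widest
#' at the top, with the base-case ICUR as a vertical reference.
#' Parameters flagged unstable (incremental QALYs change sign across
#' the range, making the ratio discontinuous) are drawn hollow and
#' annotated rather than read as a ratio span.
#'
#' @param owsa An [one_way_sa()] result.
#' @return A ggplot object.
#' @export
plot_tornado <- function(owsa) {
  stopifnot(inherits(owsa, "owsa_result"))
  df <- as.data.frame(owsa)
  df <- df[is.finite(df$icur_low) & is.finite(df$icur_high), , drop = FALSE]
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$icur_low, xend = .data$icur_high,
                   yend = .data$parameter,
                   linetype = .data$unstable),
      linewidth = 4, colour = "steelblue", alpha = 0.8) +
    ggplot2::geom_vline(xintercept = attr(owsa, "base_icur"),
                        linetype = "dashed") +
    ggplot2::scale_linetype_manual(values = c(`FALSE` = "solid", `TRUE` = "dotted"),
                                   labels = c(`FALSE` = "stable", `TRUE` = "unstable"),
                                   name = NULL) +
    ggplot2::labs(x = "ICUR (USD per QALY)", y = NULL,
                  title = "One-way sensitivity of the ICUR") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curve plot
#'
#' @param ceac_curve A [ceac()] result.
#' @return A ggplot object.
#' @export
plot_ceac <- function(ceac_curve) {
  stopifnot(inherits(ceac_curve, "ceac_curve"))
  ggplot2::ggplot(as.data.frame(ceac_curve),
                  ggplot2::aes(x = .data$wtp, y = .data$probability)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Willingness to pay (USD per QALY)",
                  y = "Probability new strategy preferred",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}
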