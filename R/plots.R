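# Presentation-only plotting helpers (ggplot2 is suggested, not imported).

#' Plot a population concentration profile
#'
#' Mean profile with a shaded 5th-95th percentile band and dotted
#' minimum/maximum envelopes, the conventional display for virtual
#' population simulations.
#'
#' @param ps A `population_summary` from [simulate_population()].
#' @param log_y Log-scale the concentration axis.
#' @return A ggplot object.
#' @export
plot_population_profile <- function(ps, log_y = FALSE) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  df <- data.frame(time_h = ps$time_h, mean = ps$mean, min = ps$min,
                   max = ps$max, p05 = ps$p05, p95 = ps$p95)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_h)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p05, ymax = .data$p95),
                         fill = "grey70", alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), linewidth = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$min), linetype = "dotted") +
    ggplot2::geom_line(ggplot2::aes(y = .data$max), linetype = "dotted") +
    ggplot2::labs(x = "Time (h)", y = "Plasma concentration (ng/ml)")
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}
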