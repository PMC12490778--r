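#' Phase plot of one participant's daily outcome
#'
#' Daily values with vertical separators at the phase boundaries, a
#' horizontal per-phase mean line and the within-phase trend line - the
#' standard layout for structured visual analysis of a single-case
#' phase design.
#'
#' @param scored_one Scored tibble restricted to one participant.
#' @param design The participant's [phase_design()].
#' @param outcome Which outcome column to plot.
#' @param trend_method Passed to [summarize_phase()].
#' @return A ggplot object.
#' @export
plot_daily_series <- function(scored_one, design, outcome = "anxiety_sum",
                              trend_method = "ols") {
  pid <- unique(scored_one$participant_id)
  v <- series_from_scored(scored_one, pid, outcome, design)
  df <- tibble(
    day_index = seq_len(design$total_days),
    value = v,
    phase = phase_labels(design)
  )
  bounds <- cumsum(c(design$baseline_days, design$treatment_days))
  seg <- dplyr::bind_rows(lapply(c("A", "B", "C"), function(ph) {
    s <- summarize_phase(v, design, ph, trend_method)
    days <- range(df$day_index[df$phase == ph])
    tibble(
      phase = ph, x = days[1], xend = days[2],
      mean = s$mean,
      y_tr = s$trend_intercept + s$trend_slope * days[1],
      yend_tr = s$trend_intercept + s$trend_slope * days[2]
    )
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day_index, y = .data$value)) +
    ggplot2::geom_vline(xintercept = bounds + 0.5, linetype = "dotted") +
    ggplot2::geom_line(na.rm = TRUE, colour = "grey60") +
    ggplot2::geom_point(na.rm = TRUE, size = 1) +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$mean, yend = .data$mean),
      colour = "red", inherit.aes = FALSE, na.rm = TRUE
    ) +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$y_tr, yend = .data$yend_tr),
      colour = "black", inherit.aes = FALSE, na.rm = TRUE
    ) +
    ggplot2::labs(
      title = sprintf("%s - %s", pid, outcome),
      x = "Study day", y = outcome
    ) +
    ggplot2::theme_minimal()
}
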