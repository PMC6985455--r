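#' Growth-curve overview plot
#'
#' Mean confluency over time per condition with SEM ribbons, on a linear or
#' log scale.
#'
#' @param screen Long-format screen table.
#' @param log_scale Plot confluency on a log10 axis.
#' @return A ggplot object.
#' @export
plot_growth_curves <- function(screen, log_scale = FALSE) {
  summ <- screen %>%
    group_by(.data$cell_line, .data$drug, .data$time_h) %>%
    summarise(mean_conf = mean(.data$confluency_pct),
              sem = sd(.data$confluency_pct) / sqrt(dplyr::n()),
              .groups = "drop") %>%
    mutate(condition = paste(.data$cell_line, .data$drug, sep = " + "))
  p <- ggplot2::ggplot(summ, ggplot2::aes(x = .data$time_h, y = .data$mean_conf,
                                          colour = .data$condition,
                                          fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_conf - .data$sem,
                                      ymax = .data$mean_conf + .data$sem),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = "confluency (%)") +
    ggplot2::theme_minimal()
  if (log_scale) p <- p + ggplot2::scale_y_log10()
  p
}
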