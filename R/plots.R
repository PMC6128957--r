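#' Plot a regimen level trajectory
#'
#' Step plot of the exercise level over the event history of a regimen
#' state, marking level changes and 6MWT re-tests.
#'
#' @param history A regimen `history` tibble (from a `regimen_state` or
#'   [simulate_cohort()]'s `history`, one patient).
#' @return A ggplot object.
#' @export
plot_level_history <- function(history) {
  h <- dplyr::filter(history, !is.na(.data$date))
  if (nrow(h) == 0) abort("No dated events to plot.")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$date, y = .data$level)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(
      data = dplyr::filter(h, .data$event %in%
                             c("level_up", "level_down", "retest_applied")),
      ggplot2::aes(shape = .data$event), size = 2
    ) +
    ggplot2::labs(x = "Date", y = "Exercise level", shape = "Event") +
    ggplot2::theme_minimal()
}

#' Plot an in-session SpO2 trace with the desaturation threshold
#'
#' @param samples Telemetry tibble with `elapsed_seconds` and `spo2`.
#' @param threshold Alert threshold (default 90%).
#' @return A ggplot object with alert samples highlighted.
#' @export
plot_session_spo2 <- function(samples, threshold = 90) {
  alerts <- monitor_spo2(samples, threshold = threshold)
  ggplot2::ggplot(samples,
                  ggplot2::aes(x = .data$elapsed_seconds, y = .data$spo2)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        color = "red") +
    ggplot2::geom_point(data = alerts, color = "red", size = 2) +
    ggplot2::labs(x = "Elapsed time (s)", y = "SpO2 (%)") +
    ggplot2::theme_minimal()
}

#' Plot per-arm change scores from a repeated-measures ANOVA
#'
#' @param object A `pw_rm_anova` fit.
#' @param ... Unused.
#' @return A ggplot object of mean change from baseline per arm and visit
#'   contrast, with +/- 1 SD bars.
#' @export
autoplot.pw_rm_anova <- function(object, ...) {
  ch <- object$changes
  ggplot2::ggplot(ch, ggplot2::aes(x = .data$contrast, y = .data$mean_change,
                                   fill = .data$arm)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_change - .data$sd_change,
                   ymax = .data$mean_change + .data$sd_change),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2
    ) +
    ggplot2::labs(x = "Visit contrast", y = paste("Change in", object$variable),
                  fill = "Arm") +
    ggplot2::theme_minimal()
}
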