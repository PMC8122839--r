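# ggplot2 methods for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a power spectrum
#'
#' @param object a `power_spectrum` tibble from [average_and_spectrum()].
#' @param xlim frequency range shown, Hz.
#' @param log_power plot power on a log10 scale. Default TRUE.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot power_spectrum
#' @export
autoplot.power_spectrum <- function(object, xlim = c(0, 100),
                                    log_power = TRUE, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$freq_hz,
                                            y = .data$power_uv2)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 1) +
    ggplot2::coord_cartesian(xlim = xlim) +
    ggplot2::labs(x = "Frequency (Hz)",
                  y = expression(Power ~ (mu * V^2))) +
    ggplot2::theme_minimal()
  if (log_power) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot grand-average ERPs and the difference wave
#'
#' @param object an `erp_result`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot erp_result
#' @export
autoplot.erp_result <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$time_ms, y = .data$amplitude_uv,
                                 color = .data$condition)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2, linetype = 2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (ms)", y = expression(Amplitude ~ (mu * V)),
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a recording excerpt
#'
#' @param object an [eeg_recording()].
#' @param t_range time range shown, seconds.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot eeg_recording
#' @export
autoplot.eeg_recording <- function(object, t_range = c(0, 10), ...) {
  as_tibble(object) |>
    dplyr::filter(.data$time_s >= t_range[1], .data$time_s <= t_range[2]) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$time_s, y = .data$amplitude_uv)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Time (s)", y = expression(Amplitude ~ (mu * V))) +
    ggplot2::theme_minimal()
}
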