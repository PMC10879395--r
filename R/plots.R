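#' @exportS3Method ggplot2::autoplot
autoplot.spectrogram <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$time_s, .data$freq_hz,
                                 fill = .data$power)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "power") +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.zscored_spectrogram <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$time_s, .data$freq_hz,
                                 fill = .data$zpower)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(name = "z power") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::labs(x = "time from SWR onset (s)", y = "frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.pac_result <- function(object, ...) {
  d <- tidy(object)
  dplyr::bind_rows(d, dplyr::mutate(d, bin_center_deg = .data$bin_center_deg + 360)) |>
    ggplot2::ggplot(ggplot2::aes(.data$bin_center_deg, .data$mean_amp)) +
    ggplot2::geom_col(width = 360 / object$n_bins * 0.92) +
    ggplot2::labs(x = "theta phase (deg)", y = "mean gamma amplitude",
                  subtitle = sprintf("MI = %.4f", object$mi)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.comodulogram <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$phase_freq_hz, .data$amp_freq_hz,
                                 fill = .data$mi)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "MI") +
    ggplot2::labs(x = "phase frequency (Hz)", y = "amplitude frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Duration histogram of detected SWRs
#'
#' @param result An `swr_result`.
#' @param bin_ms Histogram bin width in ms (default 10).
#' @return A ggplot.
#' @export
plot_swr_durations <- function(result, bin_ms = 10) {
  ds <- duration_stats(result, n_boot = 0, bin_ms = bin_ms)
  ggplot2::ggplot(ds$histogram,
                  ggplot2::aes(x = (.data$bin_left_ms + .data$bin_right_ms) / 2,
                               y = .data$count)) +
    ggplot2::geom_col(width = bin_ms * 0.92) +
    ggplot2::labs(x = "SWR duration (ms)", y = "count") +
    ggplot2::theme_minimal()
}
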