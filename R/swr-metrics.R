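#' Duration statistics of detected SWRs
#'
#' Median event duration with a seeded bootstrap 95% confidence interval
#' (percentile method) and a binned duration histogram.
#'
#' @param result An `swr_result` from [detect_swr()].
#' @param n_boot Bootstrap resamples (default 10000).
#' @param seed Seed for the bootstrap (default 0; always applied, so CIs
#'   are bit-reproducible).
#' @param bin_ms Histogram bin width in ms (default 10).
#' @param conf Confidence level (default 0.95).
#' @return A list of class `swr_duration_stats`: `n`, `median_ms`,
#'   `ci_low_ms`, `ci_high_ms`, `histogram` (tibble `bin_left_ms`,
#'   `bin_right_ms`, `count`). With no events, an empty sentinel
#'   (`n = 0`, medians `NA`) is returned rather than an error.
#' @export
duration_stats <- function(result, n_boot = 10000, seed = 0, bin_ms = 10,
                           conf = 0.95) {
  stopifnot(inherits(result, "swr_result"))
  d <- result$events$duration_ms
  if (length(d) == 0) {
    return(structure(list(n = 0L, median_ms = NA_real_, ci_low_ms = NA_real_,
                          ci_high_ms = NA_real_,
                          histogram = tibble(bin_left_ms = numeric(),
                                             bin_right_ms = numeric(),
                                             count = integer())),
                     class = "swr_duration_stats"))
  }
  med <- median(d)
  if (length(d) == 1) {
    ci <- c(med, med)
  } else if (n_boot < 1) {
    ci <- c(NA_real_, NA_real_)
  } else {
    boots <- withr::with_seed(seed, {
      vapply(seq_len(n_boot),
             function(i) median(d[sample.int(length(d), replace = TRUE)]),
             numeric(1))
    })
    alpha <- (1 - conf) / 2
    ci <- unname(quantile(boots, c(alpha, 1 - alpha), type = 7))
  }
  breaks <- seq(0, (floor(max(d) / bin_ms) + 1) * bin_ms, by = bin_ms)
  cnt <- tabulate(findInterval(d, breaks, left.open = FALSE),
                  nbins = length(breaks) - 1)
  structure(
    list(n = length(d), median_ms = med, ci_low_ms = ci[1], ci_high_ms = ci[2],
         histogram = tibble(bin_left_ms = head(breaks, -1),
                            bin_right_ms = breaks[-1], count = cnt)),
    class = "swr_duration_stats"
  )
}

#' @export
print.swr_duration_stats <- function(x, ...) {
  if (x$n == 0) {
    cat("<swr_duration_stats> no events\n")
  } else {
    cat(sprintf("<swr_duration_stats> n=%d, median %.1f ms (95%% CI %.1f-%.1f)\n",
                x$n, x$median_ms, x$ci_low_ms, x$ci_high_ms))
  }
  invisible(x)
}

#' SWR-triggered z-scored spectrogram
#'
#' Computes a multitaper spectrogram around each SWR onset (default
#' window 400 ms before to 400 ms after), averages the power matrices
#' across events, and z-scores each frequency row using that row's mean
#' and standard deviation. By default the normalization statistics come
#' from the averaged event window itself; `norm = "session"` instead uses
#' the per-frequency statistics of the whole recording's spectrogram.
#'
#' @param recording The [lfp_recording()] the events were detected in.
#' @param result An `swr_result`, or a data frame of events with an
#'   `onset_s` column.
#' @param window_s Half-window around each onset in seconds (default 0.4).
#' @param spec_window_s,spec_step_s,nw,k Multitaper parameters passed to
#'   [mt_spectrogram()] (defaults 0.1 s window, 0.01 s step, NW = 3,
#'   K = 5).
#' @param norm `"event_window"` (default) or `"session"`.
#' @return An object of class `zscored_spectrogram`: `times` (s relative
#'   to SWR onset), `freqs` (Hz), `zpower` (`freq x time`), `n_events`
#'   used, `n_excluded` (events without a full window of data),
#'   `norm_stats` (tibble `freq_hz`, `mean`, `sd`), `taper_params`,
#'   `norm`. With zero usable events an empty sentinel (`n_events = 0`,
#'   `zpower` absent) is returned.
#' @export
swr_triggered_spectrogram <- function(recording, result, window_s = 0.4,
                                      spec_window_s = 0.1, spec_step_s = 0.01,
                                      nw = 3, k = 5,
                                      norm = c("event_window", "session")) {
  norm <- match.arg(norm)
  stopifnot(inherits(recording, "lfp_recording"))
  events <- if (inherits(result, "swr_result")) result$events else as.data.frame(result)
  if (!"onset_s" %in% names(events)) {
    abort("`result` must be an swr_result or a table with an `onset_s` column.",
          class = "ripplepac_parameter_error")
  }
  fs <- recording$sampling_rate
  n <- length(recording$samples)
  w_samp <- round(window_s * fs)

  onset_idx <- round((events$onset_s - recording$start_time) * fs) + 1L
  usable <- onset_idx - w_samp >= 1L & onset_idx + w_samp - 1L <= n
  n_excl <- sum(!usable)
  onset_idx <- onset_idx[usable]
  if (length(onset_idx) == 0) {
    return(structure(list(n_events = 0L, n_excluded = n_excl),
                     class = "zscored_spectrogram"))
  }

  acc <- NULL
  for (i in onset_idx) {
    seg <- recording$samples[(i - w_samp):(i + w_samp - 1L)]
    sp <- mt_spectrogram(seg, fs = fs, window_s = spec_window_s,
                         step_s = spec_step_s, nw = nw, k = k,
                         t0 = -window_s)
    acc <- if (is.null(acc)) sp$power else acc + sp$power
  }
  avg <- acc / length(onset_idx)

  if (norm == "event_window") {
    mu <- rowMeans(avg)
    sdv <- apply(avg, 1, stats::sd)
  } else {
    full <- mt_spectrogram(recording$samples, fs = fs,
                           window_s = spec_window_s, step_s = spec_step_s,
                           nw = nw, k = k)
    mu <- rowMeans(full$power)
    sdv <- apply(full$power, 1, stats::sd)
  }
  sdv[sdv == 0] <- NA_real_
  z <- sweep(sweep(avg, 1, mu, `-`), 1, sdv, `/`)

  structure(
    list(times = sp$times, freqs = sp$freqs, zpower = z,
         n_events = length(onset_idx), n_excluded = n_excl,
         norm_stats = tibble(freq_hz = sp$freqs, mean = mu, sd = sdv),
         taper_params = sp$taper_params, norm = norm),
    class = "zscored_spectrogram"
  )
}

#' @export
print.zscored_spectrogram <- function(x, ...) {
  if (identical(x$n_events, 0L)) {
    cat("<zscored_spectrogram> no usable events\n")
  } else {
    cat(sprintf("<zscored_spectrogram> %d freqs x %d times, %d events (%d excluded), norm=%s\n",
                length(x$freqs), length(x$times), x$n_events, x$n_excluded,
                x$norm))
  }
  invisible(x)
}

#' Long-format tibble of a z-scored spectrogram
#' @param x A `zscored_spectrogram`.
#' @param ... Unused.
#' @return Tibble with columns `time_s` (relative to SWR onset),
#'   `freq_hz`, `zpower`.
#' @method tidy zscored_spectrogram
#' @export
tidy.zscored_spectrogram <- function(x, ...) {
  tidyr::expand_grid(freq_hz = x$freqs, time_s = x$times) |>
    dplyr::arrange(.data$time_s, .data$freq_hz) |>
    dplyr::mutate(zpower = as.vector(x$zpower))
}

#' Mean z-scored slow-gamma power after SWR onset
#'
#' Averages the z-scored power over a frequency band (default 30-50 Hz)
#' and a post-onset time window (default 1-100 ms): the standard scalar
#' summary of transient slow-gamma engagement during ripples.
#'
#' @param zspec A `zscored_spectrogram` from
#'   [swr_triggered_spectrogram()].
#' @param band Frequency band in Hz (default `c(30, 50)`).
#' @param window Time window in seconds relative to SWR onset (default
#'   `c(0.001, 0.100)`); time bins whose centers fall inside the closed
#'   window are used.
#' @return A single numeric z value.
#' @export
slow_gamma_power <- function(zspec, band = c(30, 50), window = c(0.001, 0.100)) {
  stopifnot(inherits(zspec, "zscored_spectrogram"))
  if (identical(zspec$n_events, 0L)) return(NA_real_)
  eps <- 1e-9
  fsel <- zspec$freqs >= band[1] - eps & zspec$freqs <= band[2] + eps
  tsel <- zspec$times >= window[1] - eps & zspec$times <= window[2] + eps
  if (!any(fsel) || !any(tsel)) {
    abort("Requested band/window lies outside the spectrogram axes.",
          class = "ripplepac_parameter_error")
  }
  mean(zspec$zpower[fsel, tsel, drop = FALSE], na.rm = TRUE)
}
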