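#' Zero-phase bandpass filter
#'
#' Filters a recording (or bare numeric trace) to a frequency band with no
#' phase distortion, by applying the filter forward and backward
#' ([signal::filtfilt()]). The default family is a Hamming-windowed-sinc
#' FIR whose order spans about three cycles of the band's low edge; an
#' order-4 Butterworth IIR is available as an alternative.
#'
#' @param x An [lfp_recording()] or a numeric vector (then `fs` is
#'   required).
#' @param band Numeric length-2, `c(low, high)` in Hz; must satisfy
#'   `0 < low < high < fs/2`.
#' @param fs Sampling rate in Hz; ignored when `x` is a recording.
#' @param family `"fir"` (default) or `"butter"`.
#' @return Numeric vector, same length as the input trace. The attribute
#'   `"transient"` gives the number of edge samples contaminated by the
#'   filter transient at each end; downstream event detection and PAC
#'   exclude them.
#' @examples
#' fs <- 1000
#' x <- sin(2 * pi * 200 * seq(0, 1, by = 1 / fs))
#' y <- bandpass(x, c(150, 250), fs = fs)
#' @export
bandpass <- function(x, band, fs = NULL, family = c("fir", "butter")) {
  family <- match.arg(family)
  if (inherits(x, "lfp_recording")) {
    fs <- x$sampling_rate
    x <- x$samples
  }
  if (is.null(fs)) abort("`fs` is required for a bare numeric trace.",
                         class = "ripplepac_parameter_error")
  check_band(band, fs)
  n_tr <- filter_transient(band, fs, family)
  if (length(x) < 3 * n_tr) {
    abort(sprintf("Trace too short: %d samples < 3 x filter transient (%d).",
                  length(x), n_tr), class = "ripplepac_length_error")
  }
  if (family == "fir") {
    ord <- fir_order(band, fs)
    h <- signal::fir1(ord, band / (fs / 2), type = "pass")
    y <- signal::filtfilt(as.numeric(h), 1, x)
  } else {
    bt <- signal::butter(4, band / (fs / 2), type = "pass")
    y <- signal::filtfilt(bt, x)
  }
  attr(y, "transient") <- n_tr
  y
}

check_band <- function(band, fs) {
  if (!is.numeric(band) || length(band) != 2 || any(!is.finite(band))) {
    abort("`band` must be numeric c(low, high).", class = "ripplepac_parameter_error")
  }
  if (band[1] <= 0 || band[1] >= band[2]) {
    abort("`band` must satisfy 0 < low < high.", class = "ripplepac_parameter_error")
  }
  if (band[2] >= fs / 2) {
    abort(sprintf("band high (%g Hz) must be below the Nyquist frequency (%g Hz).",
                  band[2], fs / 2), class = "ripplepac_parameter_error")
  }
  invisible(band)
}

# FIR order: ~3 cycles of the band's low edge, rounded up to even.
fir_order <- function(band, fs) {
  ord <- ceiling(3 * fs / band[1])
  if (ord %% 2 == 1) ord <- ord + 1
  ord
}

#' Number of edge samples contaminated by the filter transient
#' @param band Filter band `c(low, high)` in Hz.
#' @param fs Sampling rate in Hz.
#' @param family Filter family, as in [bandpass()].
#' @return Integer count of samples to exclude at each end of the trace.
#' @export
filter_transient <- function(band, fs, family = c("fir", "butter")) {
  family <- match.arg(family)
  if (family == "fir") fir_order(band, fs) else ceiling(3 * fs / band[1])
}

# Analytic signal via the FFT half-spectrum construction: negative
# frequencies zeroed, positive doubled, DC (and Nyquist for even n) kept.
hilbert_analytic <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

#' Instantaneous phase and envelope of a band-limited signal
#'
#' Band-pass filters the trace (unless `filter = FALSE`, the caller
#' contract being that it is already band-limited) and forms the analytic
#' signal by the Hilbert transform. The phase convention is
#' `phase(cos(2*pi*f*t)) = 0` at `t = 0`; phase is returned wrapped to
#' `(-pi, pi]`.
#'
#' @inheritParams bandpass
#' @param filter If `TRUE` (default), filter to `band` first.
#' @return An object of class `analytic_signal`: list with `phase`
#'   (radians), `envelope` (same units as input, nonnegative), `band`,
#'   `sampling_rate`, `n_edge` (edge-transient samples per end) and
#'   `degenerate` (`TRUE` for a constant input, whose phase is undefined).
#' @examples
#' fs <- 1000
#' x <- 3 * sin(2 * pi * 8 * seq(0, 5, by = 1 / fs))
#' a <- analytic_signal(x, c(4, 12), fs = fs)
#' @export
analytic_signal <- function(x, band, fs = NULL, filter = TRUE,
                            family = c("fir", "butter")) {
  family <- match.arg(family)
  if (inherits(x, "lfp_recording")) {
    fs <- x$sampling_rate
    x <- x$samples
  }
  if (is.null(fs)) abort("`fs` is required for a bare numeric trace.",
                         class = "ripplepac_parameter_error")
  check_band(band, fs)
  degenerate <- (max(x) - min(x)) == 0
  if (degenerate) {
    warn("Constant trace: envelope is 0 and phase undefined.")
    y <- x - x[1]
    n_edge <- filter_transient(band, fs, family)
  } else if (filter) {
    y <- bandpass(x, band, fs = fs, family = family)
    n_edge <- attr(y, "transient")
  } else {
    y <- x
    n_edge <- filter_transient(band, fs, family)
  }
  z <- hilbert_analytic(as.numeric(y))
  structure(
    list(phase = Arg(z), envelope = Mod(z), filtered = as.numeric(y),
         band = band, sampling_rate = fs, n_edge = n_edge,
         degenerate = degenerate),
    class = "analytic_signal"
  )
}

#' @export
print.analytic_signal <- function(x, ...) {
  cat(sprintf("<analytic_signal> band %g-%g Hz, %d samples @ %g Hz%s\n",
              x$band[1], x$band[2], length(x$envelope), x$sampling_rate,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Welch power spectral density
#'
#' One-sided PSD by Welch's method: Hann-windowed segments with 50%
#' overlap, averaged periodograms, density scaling such that the integral
#' of the PSD over frequency approximates the trace variance (Parseval).
#'
#' @inheritParams bandpass
#' @param freq_range Optional `c(low, high)` in Hz to restrict the
#'   returned rows; both must lie within `[0, fs/2]`.
#' @param nperseg Segment length in samples; default about 1 s of data
#'   (nearest power of two), capped at the trace length.
#' @return A tibble with columns `freq_hz` and `power` (units^2 / Hz),
#'   with attribute `"df"` holding the frequency bin width.
#' @export
psd_welch <- function(x, freq_range = NULL, fs = NULL, nperseg = NULL) {
  if (inherits(x, "lfp_recording")) {
    fs <- x$sampling_rate
    x <- x$samples
  }
  if (is.null(fs)) abort("`fs` is required for a bare numeric trace.",
                         class = "ripplepac_parameter_error")
  if (length(x) < 2 * fs) {
    abort("PSD requires at least 2 s of data.", class = "ripplepac_length_error")
  }
  if (!is.null(freq_range)) {
    if (freq_range[1] < 0 || freq_range[2] > fs / 2 || freq_range[1] >= freq_range[2]) {
      abort("`freq_range` must lie within [0, fs/2].",
            class = "ripplepac_parameter_error")
    }
  }
  if (is.null(nperseg)) nperseg <- min(length(x), 2^round(log2(fs)))
  nperseg <- as.integer(nperseg)
  step <- max(1L, nperseg %/% 2L)
  starts <- seq(1L, length(x) - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nperseg - 1)) / nperseg)  # periodic Hann
  scale <- 1 / (fs * sum(w^2))
  nfreq <- nperseg %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)] * w
    p <- Mod(fft(seg))^2 * scale
    acc <- acc + p[seq_len(nfreq)]
  }
  pxx <- acc / length(starts)
  # one-sided: double all interior bins
  if (nperseg %% 2 == 0) {
    pxx[2:(nfreq - 1)] <- 2 * pxx[2:(nfreq - 1)]
  } else {
    pxx[2:nfreq] <- 2 * pxx[2:nfreq]
  }
  freqs <- (seq_len(nfreq) - 1) * fs / nperseg
  out <- tibble(freq_hz = freqs, power = pxx)
  if (!is.null(freq_range)) {
    out <- dplyr::filter(out, .data$freq_hz >= freq_range[1],
                         .data$freq_hz <= freq_range[2])
  }
  attr(out, "df") <- fs / nperseg
  out
}

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` with time-bandwidth
#' product `nw`, as eigenvectors of the standard symmetric tridiagonal
#' formulation. Tapers are unit-energy; even-order tapers are
#' sign-normalized to positive mean.
#'
#' @param n Taper length in samples (>= 8).
#' @param nw Time-bandwidth product (typical 2-4).
#' @param k Number of tapers; must satisfy `k <= 2 * nw - 1`.
#' @return An `n x k` matrix, one taper per column, ordered by decreasing
#'   spectral concentration.
#' @export
dpss_tapers <- function(n, nw, k) {
  n <- as.integer(n)
  if (n < 8) abort("DPSS length must be >= 8 samples.",
                   class = "ripplepac_parameter_error")
  if (k > 2 * nw - 1) {
    abort("Require k <= 2*nw - 1 for well-concentrated tapers.",
          class = "ripplepac_parameter_error")
  }
  w <- nw / n
  i <- 0:(n - 1)
  diag_v <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  off_v <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  m <- matrix(0, n, n)
  m[cbind(i + 1, i + 1)] <- diag_v
  m[cbind(1:(n - 1), 2:n)] <- off_v
  m[cbind(2:n, 1:(n - 1))] <- off_v
  eg <- eigen(m, symmetric = TRUE)
  tap <- eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (j %% 2 == 1) {
      if (sum(tap[, j]) < 0) tap[, j] <- -tap[, j]
    } else {
      if (sum(tap[, j] * i) < 0) tap[, j] <- -tap[, j]
    }
  }
  tap
}

#' Multitaper spectrogram
#'
#' Sliding-window spectral estimate in which each window's power is the
#' mean over `k` DPSS-tapered periodograms, trading a little frequency
#' resolution for a large variance reduction relative to a single taper.
#'
#' @inheritParams bandpass
#' @param window_s Window length in seconds (default 0.1).
#' @param step_s Step between window starts in seconds (default 0.01).
#' @param nw Time-bandwidth product (default 3).
#' @param k Number of tapers (default 5; must satisfy `k <= 2*nw - 1`).
#' @param t0 Time assigned to the first sample (seconds); window times are
#'   centers relative to this origin.
#' @return An object of class `spectrogram`: list with `times` (s, window
#'   centers), `freqs` (Hz), `power` (`freq x time` matrix, units^2/Hz)
#'   and `taper_params`.
#' @export
mt_spectrogram <- function(x, fs = NULL, window_s = 0.1, step_s = 0.01,
                           nw = 3, k = 5, t0 = 0) {
  if (inherits(x, "lfp_recording")) {
    t0 <- x$start_time
    fs <- x$sampling_rate
    x <- x$samples
  }
  if (is.null(fs)) abort("`fs` is required for a bare numeric trace.",
                         class = "ripplepac_parameter_error")
  nwin <- round(window_s * fs)
  if (nwin < 8) abort("Window must span at least 8 samples.",
                      class = "ripplepac_parameter_error")
  if (length(x) < nwin) {
    abort("Trace shorter than one spectrogram window.",
          class = "ripplepac_length_error")
  }
  nstep <- max(1L, round(step_s * fs))
  starts <- seq(1L, length(x) - nwin + 1L, by = nstep)
  tap <- dpss_tapers(nwin, nw, k)
  nfreq <- nwin %/% 2L + 1L
  segmat <- matrix(x[outer(0:(nwin - 1L), starts, `+`)], nrow = nwin)
  acc <- matrix(0, nfreq, length(starts))
  for (j in seq_len(k)) {
    ftap <- stats::mvfft(segmat * tap[, j])
    acc <- acc + Mod(ftap[seq_len(nfreq), , drop = FALSE])^2 / fs
  }
  power <- acc / k
  if (nwin %% 2 == 0) {
    power[2:(nfreq - 1), ] <- 2 * power[2:(nfreq - 1), ]
  } else {
    power[2:nfreq, ] <- 2 * power[2:nfreq, ]
  }
  structure(
    list(times = t0 + (starts - 1 + (nwin - 1) / 2) / fs,
         freqs = (seq_len(nfreq) - 1) * fs / nwin,
         power = power,
         taper_params = list(nw = nw, k = k, window_s = window_s,
                             step_s = step_s)),
    class = "spectrogram"
  )
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d freqs x %d times (window %g s, step %g s, NW=%g, K=%d)\n",
              length(x$freqs), length(x$times), x$taper_params$window_s,
              x$taper_params$step_s, x$taper_params$nw, x$taper_params$k))
  invisible(x)
}

#' Long-format tibble of a spectrogram
#' @param x A `spectrogram`.
#' @param ... Unused.
#' @return Tibble with columns `time_s`, `freq_hz`, `power`.
#' @method tidy spectrogram
#' @export
tidy.spectrogram <- function(x, ...) {
  tidyr::expand_grid(freq_hz = x$freqs, time_s = x$times) |>
    dplyr::arrange(.data$time_s, .data$freq_hz) |>
    dplyr::mutate(power = as.vector(x$power))
}

#' Export a spectrogram as a CSV matrix with JSON sidecar
#'
#' First row holds the time axis, first column the frequency axis; the
#' sidecar `<path>.json` records the taper parameters.
#'
#' @param spec A `spectrogram` or `zscored_spectrogram`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_spectrogram <- function(spec, path) {
  pw <- if (!is.null(spec$power)) spec$power else spec$zpower
  m <- rbind(c(NA, spec$times), cbind(spec$freqs, pw))
  utils::write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE,
                     na = "")
  meta <- spec$taper_params
  meta$n_events <- spec$n_events
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
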