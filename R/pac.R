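#' Theta-gamma phase-amplitude coupling and modulation index
#'
#' Quantifies how much the amplitude of a fast band (default slow gamma,
#' 30-50 Hz) is modulated by the phase of a slow band (default theta,
#' 4-12 Hz). Instantaneous phase and amplitude come from Hilbert
#' transforms of the band-passed trace; amplitude samples are assigned to
#' the phase bin containing their concurrent phase, per-bin mean
#' amplitudes are normalized to a distribution `p`, and the modulation
#' index is the KL divergence of `p` from uniform scaled to `[0, 1]`:
#' `MI = (log N - H(p)) / log N` with `H` the Shannon entropy and `N` the
#' bin count. `MI = 0` iff `p` is uniform; `MI = 1` iff all amplitude
#' mass sits in a single bin.
#'
#' @param recording An [lfp_recording()], long enough for at least 10
#'   cycles of the phase band's low edge.
#' @param phase_band Slow (phase-providing) band in Hz, default
#'   `c(4, 12)`.
#' @param amp_band Fast (amplitude-providing) band in Hz, default
#'   `c(30, 50)`; must not overlap `phase_band`.
#' @param n_bins Number of phase bins (default 18, i.e. 20 degrees each;
#'   minimum 6). Bin 1 starts at `-pi`; bins are half-open on the right,
#'   except the last which includes `pi`.
#' @param mask Optional [interval_mask()] restricting the samples used
#'   (e.g. immobility); otherwise the whole edge-trimmed recording is
#'   used.
#' @param n_surrogates If > 0, a surrogate distribution of MI values is
#'   built by circularly time-shifting the amplitude series by random
#'   offsets, and a surrogate z-score of the observed MI is reported
#'   (seeded; >= 200 recommended).
#' @param seed Seed for surrogate shifts (default 0).
#' @return An object of class `pac_result`: `bin_centers` (radians),
#'   `mean_amp`, `p` (sums to 1), `mi`, `n_bins`, `n_samples`,
#'   `phase_band`, `amp_band`, and when surrogates were requested
#'   `mi_surrogate_z`, `n_surrogates`.
#' @examples
#' sim <- generate_lfp(synth_config(duration_s = 60, seed = 2,
#'                                  gamma_coupling_k = 0.8))
#' pac_mi(sim$recording)$mi
#' @export
pac_mi <- function(recording, phase_band = c(4, 12), amp_band = c(30, 50),
                   n_bins = 18, mask = NULL, n_surrogates = 0, seed = 0) {
  stopifnot(inherits(recording, "lfp_recording"))
  fs <- recording$sampling_rate
  if (n_bins < 6) abort("`n_bins` must be at least 6.",
                        class = "ripplepac_parameter_error")
  check_band(phase_band, fs); check_band(amp_band, fs)
  if (phase_band[2] > amp_band[1]) {
    abort("`phase_band` and `amp_band` must not overlap.",
          class = "ripplepac_parameter_error")
  }
  if (lfp_duration(recording) < 10 / phase_band[1]) {
    abort("Recording shorter than 10 cycles of the phase band's low edge.",
          class = "ripplepac_length_error")
  }

  ph <- analytic_signal(recording$samples, phase_band, fs = fs)
  am <- analytic_signal(recording$samples, amp_band, fs = fs)
  idx <- pac_sample_index(recording, max(ph$n_edge, am$n_edge), mask)
  phase <- ph$phase[idx]
  amp <- am$envelope[idx]
  if (all(amp == 0)) {
    abort("Amplitude envelope is identically zero.",
          class = "ripplepac_degenerate_error")
  }

  binned <- bin_amplitude(phase, amp, n_bins)
  mi <- mi_from_p(binned$p)

  out <- list(bin_centers = binned$centers, mean_amp = binned$mean_amp,
              p = binned$p, mi = mi, n_bins = n_bins,
              n_samples = length(amp),
              phase_band = phase_band, amp_band = amp_band)
  if (n_surrogates > 0) {
    n <- length(amp)
    min_shift <- ceiling(fs / phase_band[1])  # at least one slow cycle
    sur <- withr::with_seed(seed, {
      shifts <- sample.int(n - 2L * min_shift, n_surrogates, replace = TRUE) +
        min_shift
      vapply(shifts, function(s) {
        a2 <- c(amp[(s + 1L):n], amp[seq_len(s)])
        mi_from_p(bin_amplitude(phase, a2, n_bins)$p)
      }, numeric(1))
    })
    out$mi_surrogate_z <- (mi - mean(sur)) / stats::sd(sur)
    out$n_surrogates <- n_surrogates
  }
  structure(out, class = "pac_result")
}

pac_sample_index <- function(recording, n_edge, mask) {
  n <- length(recording$samples)
  ok <- rep(TRUE, n)
  if (n_edge > 0) {
    ok[seq_len(min(n_edge, n))] <- FALSE
    ok[seq.int(max(1L, n - n_edge + 1L), n)] <- FALSE
  }
  if (!is.null(mask)) {
    mask <- bind_mask(mask, recording)
    ok <- ok & mask_sample_index(mask, recording)
  }
  if (!any(ok)) abort("No usable samples for PAC.",
                      class = "ripplepac_parameter_error")
  ok
}

# Phase-binned amplitude distribution. Bins are [-pi, pi] split into
# n_bins half-open [left, right) bins, the last closed at pi. Empty bins
# contribute zero amplitude mass (0 * log 0 = 0 in the entropy).
bin_amplitude <- function(phase, amp, n_bins) {
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  bin <- findInterval(phase, edges, rightmost.closed = TRUE)
  bin[bin < 1L] <- 1L  # guard against -pi - eps rounding
  sums <- vapply(seq_len(n_bins), function(b) sum(amp[bin == b]), numeric(1))
  cnts <- tabulate(bin, nbins = n_bins)
  mean_amp <- ifelse(cnts > 0, sums / pmax(cnts, 1L), 0)
  list(centers = (head(edges, -1) + edges[-1]) / 2,
       mean_amp = mean_amp,
       p = mean_amp / sum(mean_amp))
}

mi_from_p <- function(p) {
  n <- length(p)
  nz <- p > 0
  h <- -sum(p[nz] * log(p[nz]))
  (log(n) - h) / log(n)
}

#' @export
print.pac_result <- function(x, ...) {
  cat(sprintf("<pac_result> MI = %.4f (phase %g-%g Hz, amp %g-%g Hz, %d bins, %d samples)\n",
              x$mi, x$phase_band[1], x$phase_band[2], x$amp_band[1],
              x$amp_band[2], x$n_bins, x$n_samples))
  invisible(x)
}

#' Phase-bin amplitude distribution of a PAC result
#' @param x A `pac_result`.
#' @param ... Unused.
#' @return Tibble with `bin_center_rad`, `bin_center_deg`, `mean_amp`,
#'   `p`.
#' @method tidy pac_result
#' @export
tidy.pac_result <- function(x, ...) {
  tibble(bin_center_rad = x$bin_centers,
         bin_center_deg = (x$bin_centers + pi) * 180 / pi,
         mean_amp = x$mean_amp, p = x$p)
}

#' One-row summary of a PAC result
#' @param x A `pac_result`.
#' @param ... Unused.
#' @return One-row tibble with the modulation index and its parameters.
#' @method glance pac_result
#' @export
glance.pac_result <- function(x, ...) {
  tibble(mi = x$mi, n_bins = x$n_bins, n_samples = x$n_samples,
         phase_low_hz = x$phase_band[1], phase_high_hz = x$phase_band[2],
         amp_low_hz = x$amp_band[1], amp_high_hz = x$amp_band[2],
         mi_surrogate_z = x$mi_surrogate_z %||% NA_real_)
}

#' Comodulogram: MI over a grid of phase and amplitude frequencies
#'
#' Evaluates the modulation index for every pair of a phase-frequency
#' grid and an amplitude-frequency grid, each taken as a band of the
#' stated bandwidth centred on the grid point. The amplitude bandwidth
#' must be wide enough that coupling side-bands (carrier +/- phase
#' frequency) fall well inside the amplitude band; see `amp_bw` below.
#'
#' @inheritParams pac_mi
#' @param phase_freqs Numeric grid of phase-band centers in Hz (default
#'   `seq(4, 12, by = 1)`).
#' @param amp_freqs Numeric grid of amplitude-band centers in Hz (default
#'   `seq(20, 100, by = 5)`).
#' @param phase_bw,amp_bw Full bandwidths in Hz (defaults 4 and 30).
#'   `phase_bw` must be >= 2. The amplitude bandwidth must comfortably
#'   exceed twice the highest phase frequency of interest (2 x 12 Hz
#'   here, plus filter transition width), otherwise the modulation
#'   side-bands of a correctly centred band are attenuated at the band
#'   edge and off-centre bands that capture a carrier-sideband beat can
#'   outscore it. Each band `center +/- bw/2` must stay inside
#'   `(0, fs/2)`.
#' @return An object of class `comodulogram`: `phase_freqs`, `amp_freqs`,
#'   `mi` (`amp x phase` matrix), `params`.
#' @export
comodulogram <- function(recording, phase_freqs = seq(4, 12, by = 1),
                         amp_freqs = seq(20, 100, by = 5),
                         phase_bw = 4, amp_bw = 30, n_bins = 18,
                         mask = NULL) {
  stopifnot(inherits(recording, "lfp_recording"))
  fs <- recording$sampling_rate
  if (length(phase_freqs) < 1 || length(amp_freqs) < 1 ||
      any(diff(phase_freqs) <= 0) || any(diff(amp_freqs) <= 0)) {
    abort("Frequency grids must be increasing and non-empty.",
          class = "ripplepac_parameter_error")
  }
  if (phase_bw < 2) abort("`phase_bw` must be at least 2 Hz.",
                          class = "ripplepac_parameter_error")
  if (min(phase_freqs) - phase_bw / 2 <= 0 ||
      max(amp_freqs) + amp_bw / 2 >= fs / 2) {
    abort("Grid bands exceed (0, Nyquist).", class = "ripplepac_parameter_error")
  }

  phases <- lapply(phase_freqs, function(f) {
    analytic_signal(recording$samples, c(f - phase_bw / 2, f + phase_bw / 2),
                    fs = fs)
  })
  amps <- lapply(amp_freqs, function(f) {
    analytic_signal(recording$samples, c(f - amp_bw / 2, f + amp_bw / 2),
                    fs = fs)
  })
  n_edge <- max(vapply(phases, function(a) a$n_edge, numeric(1)),
                vapply(amps, function(a) a$n_edge, numeric(1)))
  idx <- pac_sample_index(recording, n_edge, mask)

  mi <- matrix(NA_real_, length(amp_freqs), length(phase_freqs),
               dimnames = list(amp_freqs, phase_freqs))
  for (i in seq_along(amp_freqs)) {
    a <- amps[[i]]$envelope[idx]
    for (j in seq_along(phase_freqs)) {
      p <- phases[[j]]$phase[idx]
      mi[i, j] <- mi_from_p(bin_amplitude(p, a, n_bins)$p)
    }
  }
  structure(
    list(phase_freqs = phase_freqs, amp_freqs = amp_freqs, mi = mi,
         params = list(phase_bw = phase_bw, amp_bw = amp_bw,
                       n_bins = n_bins)),
    class = "comodulogram"
  )
}

#' @export
print.comodulogram <- function(x, ...) {
  pk <- arrayInd(which.max(x$mi), dim(x$mi))
  cat(sprintf("<comodulogram> %d amp x %d phase frequencies; max MI %.4f at (%g Hz phase, %g Hz amp)\n",
              length(x$amp_freqs), length(x$phase_freqs), max(x$mi),
              x$phase_freqs[pk[2]], x$amp_freqs[pk[1]]))
  invisible(x)
}

#' Long-format tibble of a comodulogram
#' @param x A `comodulogram`.
#' @param ... Unused.
#' @return Tibble with `phase_freq_hz`, `amp_freq_hz`, `mi`.
#' @method tidy comodulogram
#' @export
tidy.comodulogram <- function(x, ...) {
  tidyr::expand_grid(amp_freq_hz = x$amp_freqs,
                     phase_freq_hz = x$phase_freqs) |>
    dplyr::arrange(.data$phase_freq_hz, .data$amp_freq_hz) |>
    dplyr::mutate(mi = as.vector(x$mi))
}

#' Phase-amplitude distribution over two theta cycles
#'
#' The phase-binned mean-amplitude distribution replicated over
#' 0-720 degrees, the conventional display of theta-phase gamma-amplitude
#' coupling.
#'
#' @inheritParams pac_mi
#' @return A tibble of `2 * n_bins` rows with `phase_deg` (bin centers,
#'   0-720), `mean_amp` and `p` (each cycle's `p` sums to 1).
#' @export
phase_amp_distribution <- function(recording, phase_band = c(4, 12),
                                   amp_band = c(30, 50), n_bins = 18,
                                   mask = NULL) {
  res <- pac_mi(recording, phase_band = phase_band, amp_band = amp_band,
                n_bins = n_bins, mask = mask)
  d <- tidy(res)
  dplyr::bind_rows(d, dplyr::mutate(d, bin_center_deg = .data$bin_center_deg + 360)) |>
    dplyr::transmute(phase_deg = .data$bin_center_deg,
                     mean_amp = .data$mean_amp, p = .data$p)
}
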