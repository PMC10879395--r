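#' Sharp-wave-ripple detection parameters
#'
#' @param band Ripple band in Hz (default 150-250).
#' @param threshold_sd Detection threshold in SD units of the ripple-band
#'   envelope above its mean (default 5).
#' @param min_duration_ms Minimum time the envelope must stay above
#'   threshold for a candidate core (default 15 ms).
#' @param boundary_def Event-extension criterion; `"envelope_mean"`
#'   extends each core to the nearest crossings of the envelope mean.
#' @param reestimate If `TRUE`, one round of event-excluded re-estimation
#'   of the envelope mean/SD after an initial detection pass (sensitivity
#'   analysis; default `FALSE`).
#' @return A list of class `swr_params`.
#' @export
swr_params <- function(band = c(150, 250), threshold_sd = 5,
                       min_duration_ms = 15,
                       boundary_def = "envelope_mean",
                       reestimate = FALSE) {
  if (threshold_sd <= 0) abort("`threshold_sd` must be positive.",
                               class = "ripplepac_parameter_error")
  if (min_duration_ms <= 0) abort("`min_duration_ms` must be positive.",
                                  class = "ripplepac_parameter_error")
  boundary_def <- match.arg(boundary_def, "envelope_mean")
  structure(list(band = as.numeric(band), threshold_sd = threshold_sd,
                 min_duration_ms = min_duration_ms,
                 boundary_def = boundary_def, reestimate = reestimate),
            class = "swr_params")
}

new_swr_result <- function(events, params, analyzed_time_s, baseline,
                           envelope_sd, n_discarded = 0L) {
  incidence <- if (is.finite(analyzed_time_s) && analyzed_time_s > 0) {
    nrow(events) / analyzed_time_s
  } else NA_real_
  structure(
    list(events = events, params = params,
         analyzed_time_s = analyzed_time_s, incidence_hz = incidence,
         baseline = baseline, envelope_sd = envelope_sd,
         n_discarded = n_discarded),
    class = "swr_result"
  )
}

empty_events <- function() {
  tibble(onset_s = numeric(), offset_s = numeric(), peak_s = numeric(),
         duration_ms = numeric(), peak_z = numeric())
}

#' Detect sharp-wave ripples by envelope thresholding
#'
#' The trace is band-pass filtered to the ripple band and the Hilbert
#' envelope computed. With mean `m` and standard deviation `s` of the
#' envelope over immobility samples, candidate cores are maximal runs
#' where the envelope exceeds `m + threshold_sd * s` for at least
#' `min_duration_ms`. Each core is then extended backward and forward to
#' the nearest crossing of the baseline (the envelope mean), so the event
#' covers the full period during which the envelope exceeds baseline;
#' cores whose extensions meet are merged into one event. Events that
#' extend into masked-out time or into the filter's edge-transient region
#' are discarded (not truncated) and counted.
#'
#' @param recording An [lfp_recording()] of at least 2 s.
#' @param mask An [interval_mask()] of immobility periods; detection
#'   statistics and the incidence denominator use mask time only. Must be
#'   non-empty after clipping to the recording.
#' @param params An [swr_params()].
#' @return An object of class `swr_result`: list with `events` (tibble:
#'   `onset_s`, `offset_s`, `peak_s`, `duration_ms`, `peak_z`), `params`,
#'   `analyzed_time_s` (total immobility seconds), `incidence_hz`
#'   (`n_events / analyzed_time_s`), `baseline` and `envelope_sd`
#'   (microvolts), and `n_discarded` (events dropped at mask or edge
#'   boundaries).
#' @examples
#' cfg <- synth_config(duration_s = 30, seed = 1)
#' sim <- generate_lfp(cfg)
#' res <- detect_swr(sim$recording, sim$truth$immobility_mask)
#' res$incidence_hz
#' @export
detect_swr <- function(recording, mask = NULL, params = swr_params()) {
  stopifnot(inherits(recording, "lfp_recording"))
  fs <- recording$sampling_rate
  if (lfp_duration(recording) < 2) {
    abort("Detection requires at least 2 s of data.",
          class = "ripplepac_length_error")
  }
  if (is.null(mask)) {
    mask <- interval_mask(recording$start_time,
                          recording$start_time + lfp_duration(recording))
  }
  mask <- bind_mask(mask, recording)
  if (nrow(mask) == 0 || mask_duration(mask) <= 0) {
    abort("Immobility mask is empty within the recording span.",
          class = "ripplepac_parameter_error")
  }

  rng <- range(recording$samples)
  if (rng[1] == rng[2]) {
    # a silent (all-zero) trace simply has no events; any other constant
    # trace leaves the envelope threshold undefined
    if (rng[1] == 0) {
      return(new_swr_result(empty_events(), params,
                            analyzed_time_s = mask_duration(mask),
                            baseline = 0, envelope_sd = 0))
    }
    abort("Constant trace: envelope SD is zero, detection is degenerate.",
          class = "ripplepac_degenerate_error")
  }

  a <- analytic_signal(recording$samples, params$band, fs = fs)
  env <- a$envelope
  n <- length(env)
  n_edge <- a$n_edge
  ok_edge <- rep(TRUE, n)
  if (n_edge > 0) {
    ok_edge[seq_len(min(n_edge, n))] <- FALSE
    ok_edge[seq.int(max(1L, n - n_edge + 1L), n)] <- FALSE
  }
  inmask <- mask_sample_index(mask, recording)
  stat_idx <- inmask & ok_edge
  if (!any(stat_idx)) {
    abort("No usable immobility samples outside the filter transient.",
          class = "ripplepac_parameter_error")
  }

  stats_pair <- envelope_stats(env, stat_idx)
  if (params$reestimate) {
    first <- scan_events(env, stats_pair$mu, stats_pair$sd_, params, fs)
    excl <- stat_idx
    for (r in seq_len(nrow(first))) excl[first$i0[r]:first$i1[r]] <- FALSE
    if (any(excl)) stats_pair <- envelope_stats(env, excl)
  }
  mu <- stats_pair$mu; sd_ <- stats_pair$sd_
  if (sd_ == 0) {
    abort("Envelope SD is zero; detection is degenerate.",
          class = "ripplepac_degenerate_error")
  }

  ev <- scan_events(env, mu, sd_, params, fs)

  # drop events touching masked-out time or the edge-transient region
  usable <- inmask & ok_edge
  keep <- logical(nrow(ev))
  for (r in seq_len(nrow(ev))) keep[r] <- all(usable[ev$i0[r]:ev$i1[r]])
  n_disc <- sum(!keep)
  ev <- ev[keep, , drop = FALSE]

  t0 <- recording$start_time
  events <- if (nrow(ev) == 0) empty_events() else tibble(
    onset_s = t0 + (ev$i0 - 1) / fs,
    offset_s = t0 + ev$i1 / fs,
    peak_s = t0 + (ev$ipk - 0.5) / fs,
    duration_ms = (ev$i1 - ev$i0 + 1) / fs * 1000,
    peak_z = (env[ev$ipk] - mu) / sd_
  )
  new_swr_result(events, params, analyzed_time_s = mask_duration(mask),
                 baseline = mu, envelope_sd = sd_, n_discarded = n_disc)
}

envelope_stats <- function(env, idx) {
  list(mu = mean(env[idx]), sd_ = stats::sd(env[idx]))
}

# Core of the detection rule, on sample indices. Returns a data.frame of
# event spans i0..i1 (inclusive, samples where env > baseline) and the
# envelope-peak index ipk. Cores sharing a baseline run merge naturally.
scan_events <- function(env, mu, sd_, params, fs) {
  thr <- mu + params$threshold_sd * sd_
  min_len <- ceiling(params$min_duration_ms / 1000 * fs)

  above_thr <- env > thr
  r <- rle(above_thr)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  core_ok <- r$values & r$lengths >= min_len
  core_starts <- starts[core_ok]
  if (length(core_starts) == 0) {
    return(data.frame(i0 = integer(), i1 = integer(), ipk = integer()))
  }

  above_base <- env > mu
  rb <- rle(above_base)
  bends <- cumsum(rb$lengths)
  bstarts <- bends - rb$lengths + 1L
  bk <- rb$values
  run_of <- findInterval(core_starts, bstarts)  # baseline run containing core
  run_of <- unique(run_of)
  i0 <- bstarts[run_of]; i1 <- bends[run_of]
  stopifnot(all(bk[run_of]))
  ipk <- mapply(function(a, b) a - 1L + which.max(env[a:b]), i0, i1)
  data.frame(i0 = i0, i1 = i1, ipk = as.integer(ipk))
}

#' @export
print.swr_result <- function(x, ...) {
  cat(sprintf("<swr_result> %d events over %.1f s immobility (%.3f Hz); threshold %g SD, min %g ms; %d discarded at boundaries\n",
              nrow(x$events), x$analyzed_time_s, x$incidence_hz,
              x$params$threshold_sd, x$params$min_duration_ms, x$n_discarded))
  invisible(x)
}

#' Event table of an SWR detection result
#' @param x An `swr_result`.
#' @param ... Unused.
#' @return The events tibble (`onset_s`, `offset_s`, `peak_s`,
#'   `duration_ms`, `peak_z`).
#' @method tidy swr_result
#' @export
tidy.swr_result <- function(x, ...) x$events

#' One-row summary of an SWR detection result
#' @param x An `swr_result`.
#' @param ... Unused.
#' @return One-row tibble: event count, analyzed time, incidence, median
#'   duration, discard count.
#' @method glance swr_result
#' @export
glance.swr_result <- function(x, ...) {
  tibble(
    n_events = nrow(x$events),
    analyzed_time_s = x$analyzed_time_s,
    incidence_hz = x$incidence_hz,
    median_duration_ms = if (nrow(x$events)) median(x$events$duration_ms) else NA_real_,
    n_discarded = x$n_discarded
  )
}
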