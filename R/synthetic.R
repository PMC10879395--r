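#' Configuration for the synthetic LFP generator
#'
#' Defines a fully specified ground-truth recording: 1/f (pink) or white
#' background noise, a theta rhythm, a slow-gamma carrier whose envelope
#' is modulated by theta phase with programmable coupling strength, and
#' transient ripple bursts injected at a programmable rate during
#' immobility epochs. Defaults emulate a mouse hippocampal home-cage
#' recording at 1 kHz.
#'
#' @param duration_s Recording duration in seconds.
#' @param sampling_rate Hz (default 1000).
#' @param seed Integer seed; mandatory, all randomness derives from it.
#' @param noise_type `"pink"` (1/f power) or `"white"`.
#' @param noise_sd Background-noise standard deviation in microvolts
#'   (default 30).
#' @param theta_freq,theta_amp Theta rhythm frequency (Hz, default 8) and
#'   amplitude (microvolts, default 60).
#' @param gamma_freq Slow-gamma carrier frequency (Hz, default 40).
#' @param gamma_base_amp Gamma carrier base amplitude (microvolts,
#'   default 20).
#' @param gamma_coupling_k Coupling strength in `[0, 1]`: the gamma
#'   envelope is `gamma_base_amp * (1 + k * cos(theta_phase -
#'   preferred_phase))`, so `k = 0` is uncoupled and `k = 1` full
#'   modulation.
#' @param gamma_preferred_phase Theta phase (radians) at which gamma
#'   amplitude peaks (default 0).
#' @param ripple_rate Ripple event rate in Hz during immobility (default
#'   0.2).
#' @param ripple_freq Ripple carrier frequency in Hz (default 180, inside
#'   150-250).
#' @param ripple_amp_sd Ripple peak amplitude in multiples of `noise_sd`
#'   (default 8).
#' @param ripple_duration_ms If non-`NULL`, a fixed burst duration in ms;
#'   otherwise durations are drawn log-normally.
#' @param ripple_duration_meanlog,ripple_duration_sdlog Parameters of the
#'   log-normal duration distribution in ms (defaults `log(50)` and
#'   0.25).
#' @param ripple_refractory_s Minimum onset-to-onset gap (default 0.2 s);
#'   events are a renewal process with this hard refractory period and an
#'   exponential excess gap whose mean preserves `ripple_rate` exactly.
#' @param ripple_gamma_amp Peak amplitude (microvolts) of an extra
#'   slow-gamma burst co-injected in the first `ripple_gamma_dur_ms`
#'   after each ripple onset (default 0 = none); emulates transient
#'   slow-gamma engagement during ripples.
#' @param ripple_gamma_dur_ms,ripple_gamma_freq Duration (ms, default
#'   100) and frequency (Hz, default 40) of that burst.
#' @param immobility_fraction Fraction of the recording spent in
#'   immobility epochs (default 1 = the whole recording).
#' @param immobility_block_s Length of each immobility block when
#'   `immobility_fraction < 1` (default 30 s).
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(duration_s, sampling_rate = 1000, seed,
                         noise_type = c("pink", "white"), noise_sd = 30,
                         theta_freq = 8, theta_amp = 60,
                         gamma_freq = 40, gamma_base_amp = 20,
                         gamma_coupling_k = 0.7, gamma_preferred_phase = 0,
                         ripple_rate = 0.2, ripple_freq = 180,
                         ripple_amp_sd = 8,
                         ripple_duration_ms = NULL,
                         ripple_duration_meanlog = log(50),
                         ripple_duration_sdlog = 0.25,
                         ripple_refractory_s = 0.2,
                         ripple_gamma_amp = 0, ripple_gamma_dur_ms = 100,
                         ripple_gamma_freq = 40,
                         immobility_fraction = 1, immobility_block_s = 30) {
  noise_type <- match.arg(noise_type)
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    abort("`seed` is mandatory for the generator.",
          class = "ripplepac_parameter_error")
  }
  if (gamma_coupling_k < 0 || gamma_coupling_k > 1) {
    abort("`gamma_coupling_k` must lie in [0, 1].",
          class = "ripplepac_parameter_error")
  }
  if (ripple_rate < 0) abort("`ripple_rate` must be >= 0.",
                             class = "ripplepac_parameter_error")
  amps <- c(noise_sd, theta_amp, gamma_base_amp, ripple_amp_sd,
            ripple_gamma_amp)
  if (any(amps < 0)) abort("Amplitude parameters must be >= 0.",
                           class = "ripplepac_parameter_error")
  if (immobility_fraction <= 0 || immobility_fraction > 1) {
    abort("`immobility_fraction` must lie in (0, 1].",
          class = "ripplepac_parameter_error")
  }
  if (ripple_rate > 0 && 1 / ripple_rate <= ripple_refractory_s) {
    abort("`ripple_rate` too high for the refractory period.",
          class = "ripplepac_parameter_error")
  }
  cfg <- as.list(environment())
  cfg$amps <- NULL
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic LFP recording with ground truth
#'
#' Builds the trace `noise + theta + coupled gamma + ripple bursts`
#' described by a [synth_config()]. Ripples are Hann-windowed pure tones
#' whose onsets form a refractory renewal process confined to immobility
#' epochs, so onset, offset, amplitude and count are known exactly.
#' Identical config and seed give bit-identical output.
#'
#' @param config A [synth_config()].
#' @return A list with elements `recording` (an [lfp_recording()]) and
#'   `truth` (class `synth_truth`): `ripple_events` tibble (`onset_s`,
#'   `offset_s`, `freq_hz`, `amp_uv`), `theta_phase` (per-sample wrapped
#'   radians), `coupling_k`, `immobility_mask`, and the `config`.
#' @examples
#' sim <- generate_lfp(synth_config(duration_s = 20, seed = 42))
#' nrow(sim$truth$ripple_events)
#' @export
generate_lfp <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  fs <- config$sampling_rate
  n <- round(config$duration_s * fs)
  t <- (0:(n - 1)) / fs

  if (config$ripple_rate > 0 &&
      config$ripple_rate * config$duration_s * config$immobility_fraction < 1) {
    warn("Expected ripple count below 1 for this duration.")
  }

  mask <- immobility_epochs(config$duration_s, config$immobility_fraction,
                            config$immobility_block_s)

  out <- withr::with_seed(config$seed, {
    noise <- if (config$noise_type == "white") {
      rnorm(n, 0, config$noise_sd)
    } else {
      pink_noise(n, fs, config$noise_sd)
    }

    theta_arg <- 2 * pi * config$theta_freq * t
    theta <- config$theta_amp * cos(theta_arg)
    gamma_env <- config$gamma_base_amp *
      (1 + config$gamma_coupling_k *
         cos(theta_arg - config$gamma_preferred_phase))
    gamma <- gamma_env * cos(2 * pi * config$gamma_freq * t)

    ev <- draw_ripple_times(mask, config)
    ripples <- numeric(n)
    for (r in seq_len(nrow(ev))) {
      ripples <- ripples + tone_burst(n, fs, ev$onset_s[r], ev$offset_s[r],
                                      ev$freq_hz[r], ev$amp_uv[r])
      if (config$ripple_gamma_amp > 0) {
        ripples <- ripples +
          tone_burst(n, fs, ev$onset_s[r],
                     ev$onset_s[r] + config$ripple_gamma_dur_ms / 1000,
                     config$ripple_gamma_freq, config$ripple_gamma_amp)
      }
    }
    list(trace = noise + theta + gamma + ripples, events = ev,
         theta_phase = atan2(sin(theta_arg), cos(theta_arg)))
  })

  recording <- lfp_recording(out$trace, fs, label = "synthetic")
  truth <- structure(
    list(ripple_events = out$events, theta_phase = out$theta_phase,
         coupling_k = config$gamma_coupling_k, immobility_mask = mask,
         config = config),
    class = "synth_truth"
  )
  list(recording = recording, truth = truth)
}

# Pink noise by spectral shaping: white Gaussian spectrum with 1/sqrt(f)
# amplitude weights (1/f power), DC removed, rescaled to the target SD.
pink_noise <- function(n, fs, sd_target) {
  x <- rnorm(n)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n
  w <- ifelse(f > 0, 1 / sqrt(f), 0)
  y <- Re(fft(fft(x) * w, inverse = TRUE) / n)
  y * sd_target / stats::sd(y)
}

immobility_epochs <- function(duration_s, fraction, block_s) {
  if (fraction >= 1) return(interval_mask(0, duration_s))
  cycle <- block_s / fraction
  starts <- seq(0, duration_s, by = cycle)
  ends <- pmin(starts + block_s, duration_s)
  keep <- ends > starts
  interval_mask(starts[keep], ends[keep])
}

# Ripple onsets: renewal process per immobility epoch with hard
# refractory gap and exponential excess whose mean keeps the programmed
# onset rate exact. Bursts must fit inside their epoch and clear the
# recording edges.
draw_ripple_times <- function(mask, config) {
  rate <- config$ripple_rate
  empty <- tibble(onset_s = numeric(), offset_s = numeric(),
                  freq_hz = numeric(), amp_uv = numeric())
  if (rate <= 0) return(empty)
  refr <- config$ripple_refractory_s
  excess_mean <- 1 / rate - refr
  edge_margin <- 0.5
  dur_total <- config$duration_s
  onsets <- numeric(0)
  durs <- numeric(0)
  for (k in seq_len(nrow(mask))) {
    s <- mask$start_s[k]; e <- mask$end_s[k]
    t_on <- s + rexp(1, rate)
    repeat {
      if (t_on >= e) break
      d <- if (!is.null(config$ripple_duration_ms)) {
        config$ripple_duration_ms / 1000
      } else {
        rlnorm(1, config$ripple_duration_meanlog,
               config$ripple_duration_sdlog) / 1000
      }
      if (t_on + d < e && t_on > edge_margin &&
          t_on + d < dur_total - edge_margin) {
        onsets <- c(onsets, t_on)
        durs <- c(durs, d)
      }
      t_on <- t_on + refr + rexp(1, 1 / excess_mean)
    }
  }
  if (length(onsets) == 0) return(empty)
  tibble(onset_s = onsets, offset_s = onsets + durs,
         freq_hz = config$ripple_freq,
         amp_uv = config$ripple_amp_sd * config$noise_sd)
}

# Hann-windowed tone burst on the recording's sample grid.
tone_burst <- function(n, fs, onset_s, offset_s, freq, amp) {
  i0 <- max(1L, floor(onset_s * fs) + 1L)
  i1 <- min(n, ceiling(offset_s * fs))
  y <- numeric(n)
  if (i1 <= i0) return(y)
  tt <- ((i0:i1) - 1) / fs
  u <- (tt - onset_s) / (offset_s - onset_s)
  u <- pmin(pmax(u, 0), 1)
  y[i0:i1] <- amp * 0.5 * (1 - cos(2 * pi * u)) * sin(2 * pi * freq * (tt - onset_s))
  y
}

#' Group fixture profiles for in-silico comparisons
#'
#' Preset generator configurations emulating three groups ordered (on
#' ripple rate, ripple duration, gamma coupling and ripple-locked gamma
#' amplitude) wild-type > treated model > untreated model, with
#' per-subject jitter around the presets. The subject index and profile
#' are folded into the seed, so a fixed seed regenerates the identical
#' cohort.
#'
#' @param profiles Character vector of profiles to generate; any of
#'   `"WT-like"`, `"AD-like"`, `"AD-TMAS-like"` (default all three).
#' @param n_subjects Subjects per profile (>= 1).
#' @param seed Integer master seed.
#' @param duration_s Per-subject recording duration (default 240 s).
#' @return A tibble with one row per subject: `subject_id`, `profile`,
#'   `recording` and `truth` (list-columns), `config` (list-column).
#' @export
make_group_fixtures <- function(profiles = c("WT-like", "AD-like", "AD-TMAS-like"),
                                n_subjects = 7, seed = 0, duration_s = 240) {
  profiles <- match.arg(profiles, c("WT-like", "AD-like", "AD-TMAS-like"),
                        several.ok = TRUE)
  if (n_subjects < 1) abort("`n_subjects` must be >= 1.",
                            class = "ripplepac_parameter_error")
  presets <- group_presets()
  rows <- list()
  for (p in profiles) {
    pr <- presets[[p]]
    pidx <- match(p, names(presets))
    for (s in seq_len(n_subjects)) {
      subj_seed <- (abs(seed) %% 10000L) * 10000L + pidx * 1000L + s
      jit <- withr::with_seed(subj_seed, {
        list(rate = pr$ripple_rate * exp(rnorm(1, 0, 0.08)),
             meanlog = pr$dur_meanlog + rnorm(1, 0, 0.05),
             k = min(1, max(0, pr$coupling_k + rnorm(1, 0, 0.04))),
             gamma_amp = pr$ripple_gamma_amp * exp(rnorm(1, 0, 0.08)))
      })
      cfg <- synth_config(
        duration_s = duration_s, seed = subj_seed + 100000000L,
        ripple_rate = jit$rate,
        ripple_duration_meanlog = jit$meanlog,
        gamma_coupling_k = jit$k,
        ripple_gamma_amp = jit$gamma_amp
      )
      sim <- generate_lfp(cfg)
      rows[[length(rows) + 1L]] <- tibble(
        subject_id = sprintf("%s_%02d", gsub("-like$", "", p), s),
        profile = p,
        recording = list(sim$recording),
        truth = list(sim$truth),
        config = list(cfg)
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Preset generator parameters per group profile
#'
#' @return A named list of presets (`ripple_rate` Hz, `dur_meanlog`
#'   log-ms, `coupling_k`, `ripple_gamma_amp` microvolts), strictly
#'   ordered WT-like > AD-TMAS-like > AD-like on every field.
#' @export
group_presets <- function() {
  list(
    "WT-like" = list(ripple_rate = 0.30, dur_meanlog = log(60),
                     coupling_k = 0.75, ripple_gamma_amp = 12),
    "AD-TMAS-like" = list(ripple_rate = 0.20, dur_meanlog = log(45),
                          coupling_k = 0.50, ripple_gamma_amp = 8),
    "AD-like" = list(ripple_rate = 0.10, dur_meanlog = log(32),
                     coupling_k = 0.25, ripple_gamma_amp = 4)
  )
}
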