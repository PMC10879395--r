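# Independent reference implementations used as oracles. These share no
# code with the package paths they check.

# Brute-force SWR scan: explicit per-sample state machine over an
# envelope. Returns inclusive sample spans (above-baseline extent) of
# every supra-threshold core lasting >= min_dur_ms.
brute_swr_scan <- function(env, mu, sd_, threshold_sd, min_dur_ms, fs) {
  thr <- mu + threshold_sd * sd_
  min_n <- ceiling(min_dur_ms / 1000 * fs)
  n <- length(env)
  spans <- list()
  i <- 1L
  while (i <= n) {
    if (env[i] > thr) {
      j <- i
      while (j < n && env[j + 1L] > thr) j <- j + 1L
      if (j - i + 1L >= min_n) {
        a <- i
        while (a > 1L && env[a - 1L] > mu) a <- a - 1L
        b <- j
        while (b < n && env[b + 1L] > mu) b <- b + 1L
        spans[[length(spans) + 1L]] <- c(a, b)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(spans) == 0) return(data.frame(i0 = integer(), i1 = integer()))
  m <- unique(do.call(rbind, spans))
  data.frame(i0 = m[, 1], i1 = m[, 2])
}

# Full brute-force reference detection on a recording: envelope and
# baseline statistics computed the same way as the detector (shared
# inputs), but the event scan, boundary filtering and bookkeeping are
# this independent loop.
brute_detect <- function(recording, mask, params) {
  fs <- recording$sampling_rate
  a <- analytic_signal(recording$samples, params$band, fs = fs)
  env <- a$envelope
  n <- length(env)
  usable <- rep(TRUE, n)
  usable[seq_len(a$n_edge)] <- FALSE
  usable[(n - a$n_edge + 1L):n] <- FALSE
  tt <- lfp_times(recording)
  inm <- rep(FALSE, n)
  for (r in seq_len(nrow(mask))) {
    inm <- inm | (tt >= mask$start_s[r] & tt < mask$end_s[r])
  }
  usable <- usable & inm
  mu <- mean(env[usable])
  sd_ <- sd(env[usable])
  sp <- brute_swr_scan(env, mu, sd_, params$threshold_sd,
                       params$min_duration_ms, fs)
  keep <- vapply(seq_len(nrow(sp)),
                 function(r) all(usable[sp$i0[r]:sp$i1[r]]), logical(1))
  sp[keep, , drop = FALSE]
}

# Brute-force modulation index: direct histogram + entropy over given
# phase/amplitude sample vectors.
brute_mi <- function(phase, amp, n_bins) {
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  mean_amp <- numeric(n_bins)
  for (b in seq_len(n_bins)) {
    sel <- phase >= edges[b] &
      (phase < edges[b + 1] | (b == n_bins & phase <= pi))
    mean_amp[b] <- if (any(sel)) mean(amp[sel]) else 0
  }
  p <- mean_amp / sum(mean_amp)
  h <- 0
  for (b in seq_len(n_bins)) if (p[b] > 0) h <- h - p[b] * log(p[b])
  (log(n_bins) - h) / log(n_bins)
}

# A pink-noise recording with Hann-windowed ripple bursts injected at
# caller-chosen onsets (independent of the generator's event placement).
make_burst_recording <- function(duration_s, onsets_s, burst_ms, seed,
                                 amp_sd = 8, freq = 180, fs = 1000,
                                 noise_sd = 30) {
  base <- generate_lfp(synth_config(
    duration_s = duration_s, seed = seed, noise_sd = noise_sd,
    ripple_rate = 0, theta_amp = 60, gamma_base_amp = 20))
  x <- base$recording$samples
  for (on in onsets_s) {
    dur <- burst_ms / 1000
    i0 <- floor(on * fs) + 1L
    i1 <- ceiling((on + dur) * fs)
    tt <- ((i0:i1) - 1) / fs
    u <- pmin(pmax((tt - on) / dur, 0), 1)
    x[i0:i1] <- x[i0:i1] +
      amp_sd * noise_sd * 0.5 * (1 - cos(2 * pi * u)) *
      sin(2 * pi * freq * (tt - on))
  }
  lfp_recording(x, fs, label = "bursts")
}
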