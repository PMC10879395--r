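test_that("modulation index anchors: uniform gives 0, single-bin mass gives 1", {
  # constant amplitude across uniformly covered phases -> uniform p
  phase <- seq(-pi + 1e-6, pi, length.out = 36000)
  amp <- rep(2.5, 36000)
  b <- ripplepac:::bin_amplitude(phase, amp, 18)
  expect_equal(sum(b$p), 1, tolerance = 1e-12)
  expect_equal(ripplepac:::mi_from_p(b$p), 0, tolerance = 1e-12)

  # all amplitude mass in one bin
  b2 <- ripplepac:::bin_amplitude(rep(0.1, 500), rep(1, 500), 18)
  expect_equal(ripplepac:::mi_from_p(b2$p), 1, tolerance = 1e-12)

  # empty bins follow the 0 * log 0 = 0 convention
  b3 <- ripplepac:::bin_amplitude(c(rep(0.1, 50), rep(2.0, 50)),
                                  rep(1, 100), 18)
  mi3 <- ripplepac:::mi_from_p(b3$p)
  expect_true(is.finite(mi3) && mi3 > 0 && mi3 <= 1)
})

test_that("uncoupled signals give uniform distributions and near-zero MI", {
  # deterministic uncoupled tones
  fs <- 1000
  t <- seq(1 / fs, 120, by = 1 / fs)
  rec <- lfp_recording(60 * cos(2 * pi * 8 * t) + 20 * cos(2 * pi * 40 * t),
                       fs)
  res <- pac_mi(rec)
  expect_lt(res$mi, 1e-4)

  # simulated uncoupled signal with noise
  sim <- generate_lfp(synth_config(duration_s = 60, seed = 51,
                                   gamma_coupling_k = 0, ripple_rate = 0))
  expect_lt(pac_mi(sim$recording)$mi, 0.01)
})

test_that("MI matches an independent brute-force oracle to 1e-10", {
  sim <- generate_lfp(synth_config(duration_s = 120, seed = 52,
                                   gamma_coupling_k = 0.9, ripple_rate = 0))
  rec <- sim$recording
  res <- pac_mi(rec)

  ph <- analytic_signal(rec$samples, c(4, 12), fs = rec$sampling_rate)
  am <- analytic_signal(rec$samples, c(30, 50), fs = rec$sampling_rate)
  n <- length(rec$samples)
  n_edge <- max(ph$n_edge, am$n_edge)
  idx <- setdiff(seq_len(n), c(seq_len(n_edge), (n - n_edge + 1L):n))
  mi_ref <- brute_mi(ph$phase[idx], am$envelope[idx], 18)
  expect_equal(res$mi, mi_ref, tolerance = 1e-10)
})

test_that("MI is monotone in programmed coupling strength", {
  ks <- c(0, 0.1, 0.3, 0.5, 0.7, 0.9)
  mis <- vapply(ks, function(k) {
    sim <- generate_lfp(synth_config(duration_s = 120, seed = 53,
                                     gamma_coupling_k = k, ripple_rate = 0))
    pac_mi(sim$recording)$mi
  }, numeric(1))
  expect_true(all(diff(mis) > 0))
})

test_that("MI respects bounds and amplitude-scale invariance", {
  withr::local_seed(54)
  for (i in 1:5) {
    rec <- lfp_recording(rnorm(20000, sd = runif(1, 1, 100)), 1000)
    mi <- pac_mi(rec)$mi
    expect_gte(mi, 0)
    expect_lte(mi, 1)
  }
  sim <- generate_lfp(synth_config(duration_s = 30, seed = 55,
                                   gamma_coupling_k = 0.6, ripple_rate = 0))
  rec <- sim$recording
  scaled <- lfp_recording(7.3 * rec$samples, rec$sampling_rate)
  expect_equal(pac_mi(scaled)$mi, pac_mi(rec)$mi, tolerance = 1e-12)
})

test_that("bin count is recorded and MI varies smoothly with it", {
  sim <- generate_lfp(synth_config(duration_s = 60, seed = 56,
                                   gamma_coupling_k = 0.8, ripple_rate = 0))
  mis <- vapply(c(12, 18, 36), function(nb) {
    r <- pac_mi(sim$recording, n_bins = nb)
    expect_equal(r$n_bins, nb)
    r$mi
  }, numeric(1))
  expect_true(all(mis > 0))
  expect_lt(max(mis) / min(mis), 3)
})

test_that("surrogate z-scores are seeded, finite, and calibrated on noise", {
  rec <- lfp_recording(withr::with_seed(57, rnorm(60000, sd = 30)), 1000)
  a <- pac_mi(rec, n_surrogates = 200, seed = 1)
  b <- pac_mi(rec, n_surrogates = 200, seed = 1)
  expect_identical(a$mi_surrogate_z, b$mi_surrogate_z)
  expect_equal(a$n_surrogates, 200)
  # uncoupled noise: observed MI is typical of its own shift surrogates
  expect_lt(abs(a$mi_surrogate_z), 4)
})

test_that("pac_mi validates its inputs", {
  sim <- generate_lfp(synth_config(duration_s = 5, seed = 58))
  expect_error(pac_mi(sim$recording, n_bins = 4),
               class = "ripplepac_parameter_error")
  expect_error(pac_mi(sim$recording, phase_band = c(4, 40),
                      amp_band = c(30, 50)),
               class = "ripplepac_parameter_error")
  short <- lfp_recording(rnorm(1200), 1000)
  expect_error(pac_mi(short), class = "ripplepac_length_error")
})

test_that("comodulogram is deterministic and validates grids", {
  sim <- generate_lfp(synth_config(duration_s = 30, seed = 59,
                                   gamma_coupling_k = 0.8, ripple_rate = 0))
  cm1 <- comodulogram(sim$recording, phase_freqs = c(6, 8, 10),
                      amp_freqs = c(30, 40, 50))
  cm2 <- comodulogram(sim$recording, phase_freqs = c(6, 8, 10),
                      amp_freqs = c(30, 40, 50))
  expect_identical(cm1$mi, cm2$mi)
  expect_error(comodulogram(sim$recording, phase_freqs = c(8, 8)),
               class = "ripplepac_parameter_error")
  expect_error(comodulogram(sim$recording, amp_freqs = seq(20, 600, 20)),
               class = "ripplepac_parameter_error")
})

test_that("phase-amplitude distribution spans two cycles and peaks at the programmed phase", {
  sim <- generate_lfp(synth_config(duration_s = 120, seed = 60,
                                   gamma_coupling_k = 0.9, ripple_rate = 0,
                                   gamma_preferred_phase = 0))
  d <- phase_amp_distribution(sim$recording)
  expect_equal(nrow(d), 36)
  # preferred phase 0 rad maps to 180 deg under bins starting at -pi
  peak <- d$phase_deg[which.max(d$mean_amp)]
  expect_lte(min(abs(peak - c(180, 540))), 20 + 1e-9)

  sim0 <- generate_lfp(synth_config(duration_s = 120, seed = 61,
                                    gamma_coupling_k = 0, ripple_rate = 0))
  d0 <- phase_amp_distribution(sim0$recording)
  expect_lt(max(d0$mean_amp) / min(d0$mean_amp), 1.1)
})
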