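test_that("generation is deterministic in the seed", {
  cfg <- synth_config(duration_s = 10, seed = 7)
  a <- generate_lfp(cfg)
  b <- generate_lfp(cfg)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$truth$ripple_events, b$truth$ripple_events)

  c_ <- generate_lfp(synth_config(duration_s = 10, seed = 8))
  expect_false(identical(a$recording$samples, c_$recording$samples))
})

test_that("config validation enforces the contract", {
  expect_error(synth_config(duration_s = 10), class = "ripplepac_parameter_error")
  expect_error(synth_config(duration_s = 10, seed = 1, gamma_coupling_k = 1.2),
               class = "ripplepac_parameter_error")
  expect_error(synth_config(duration_s = 10, seed = 1, ripple_rate = -1),
               class = "ripplepac_parameter_error")
  expect_error(synth_config(duration_s = 10, seed = 1, ripple_rate = 10),
               class = "ripplepac_parameter_error")
  expect_warning(generate_lfp(synth_config(duration_s = 3, seed = 1,
                                           ripple_rate = 0.2)),
                 "Expected ripple count")
})

test_that("event count matches the programmed Poisson-like rate", {
  sim <- generate_lfp(synth_config(duration_s = 600, seed = 7,
                                   ripple_rate = 0.2))
  n <- nrow(sim$truth$ripple_events)
  # 99% interval around 120 expected events
  expect_gte(n, 120 - 2.58 * sqrt(120) - 3)
  expect_lte(n, 120 + 2.58 * sqrt(120) + 3)
  # refractory period respected
  expect_true(all(diff(sim$truth$ripple_events$onset_s) >= 0.2))
})

test_that("events lie inside immobility epochs and arrays match the trace", {
  sim <- generate_lfp(synth_config(duration_s = 120, seed = 9,
                                   immobility_fraction = 0.5,
                                   ripple_rate = 0.4))
  ev <- sim$truth$ripple_events
  msk <- sim$truth$immobility_mask
  expect_gt(nrow(ev), 0)
  inside <- vapply(seq_len(nrow(ev)), function(i) {
    any(ev$onset_s[i] >= msk$start_s & ev$offset_s[i] <= msk$end_s)
  }, logical(1))
  expect_true(all(inside))
  expect_equal(length(sim$truth$theta_phase),
               length(sim$recording$samples))
  expect_equal(mask_duration(msk), 60, tolerance = 0.01)
})

test_that("spectral content matches the programmed components", {
  sim <- generate_lfp(synth_config(duration_s = 60, seed = 10,
                                   ripple_rate = 0.3))
  p <- psd_welch(sim$recording, freq_range = c(2, 20))
  expect_equal(p$freq_hz[which.max(p$power)], 8, tolerance = 1)

  # ripple-band power is transient: envelope inside ground-truth events
  # dwarfs the background
  a <- analytic_signal(sim$recording, c(150, 250))
  tt <- lfp_times(sim$recording)
  ev <- sim$truth$ripple_events
  in_ev <- rep(FALSE, length(tt))
  for (i in seq_len(nrow(ev))) {
    in_ev <- in_ev | (tt >= ev$onset_s[i] & tt < ev$offset_s[i])
  }
  expect_gt(mean(a$envelope[in_ev]), 5 * mean(a$envelope[!in_ev]))
})

test_that("pink-noise PSD slope is near -1", {
  sim <- generate_lfp(synth_config(duration_s = 120, seed = 11,
                                   theta_amp = 0, gamma_base_amp = 0,
                                   ripple_rate = 0))
  p <- psd_welch(sim$recording, freq_range = c(1, 100))
  fit <- stats::lm(log(power) ~ log(freq_hz), data = p[p$freq_hz > 0, ])
  expect_equal(unname(stats::coef(fit)[2]), -1, tolerance = 0.3)
})

test_that("detector recall and precision reach 0.95 at 8 SD bursts", {
  sim <- generate_lfp(synth_config(duration_s = 300, seed = 12,
                                   ripple_rate = 0.3, ripple_amp_sd = 8))
  det <- detect_swr(sim$recording, sim$truth$immobility_mask)
  ev <- sim$truth$ripple_events
  matched_truth <- vapply(seq_len(nrow(ev)), function(i) {
    any(abs(det$events$onset_s - ev$onset_s[i]) < 0.05)
  }, logical(1))
  matched_det <- vapply(seq_len(nrow(det$events)), function(i) {
    any(abs(ev$onset_s - det$events$onset_s[i]) < 0.05)
  }, logical(1))
  expect_gte(mean(matched_truth), 0.95)  # recall
  expect_gte(mean(matched_det), 0.95)    # precision
})

test_that("group presets are strictly ordered and fixtures reproducible", {
  pr <- group_presets()
  expect_gt(pr[["WT-like"]]$ripple_rate, pr[["AD-TMAS-like"]]$ripple_rate)
  expect_gt(pr[["AD-TMAS-like"]]$ripple_rate, pr[["AD-like"]]$ripple_rate)
  expect_gt(pr[["WT-like"]]$dur_meanlog, pr[["AD-TMAS-like"]]$dur_meanlog)
  expect_gt(pr[["AD-TMAS-like"]]$dur_meanlog, pr[["AD-like"]]$dur_meanlog)
  expect_gt(pr[["WT-like"]]$coupling_k, pr[["AD-TMAS-like"]]$coupling_k)
  expect_gt(pr[["AD-TMAS-like"]]$coupling_k, pr[["AD-like"]]$coupling_k)
  expect_gt(pr[["WT-like"]]$ripple_gamma_amp, pr[["AD-TMAS-like"]]$ripple_gamma_amp)
  expect_gt(pr[["AD-TMAS-like"]]$ripple_gamma_amp, pr[["AD-like"]]$ripple_gamma_amp)

  f1 <- make_group_fixtures(profiles = "WT-like", n_subjects = 2, seed = 5,
                            duration_s = 10)
  f2 <- make_group_fixtures(profiles = "WT-like", n_subjects = 2, seed = 5,
                            duration_s = 10)
  expect_identical(f1$recording[[1]]$samples, f2$recording[[1]]$samples)
  expect_error(make_group_fixtures(n_subjects = 0),
               class = "ripplepac_parameter_error")
})
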