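fs <- 1000

test_that("bandpass passes the band and rejects outside it", {
  t <- seq(0, 4, by = 1 / fs)
  x <- sin(2 * pi * 200 * t)
  y <- bandpass(x, c(150, 250), fs = fs)
  mid <- y[(fs):(3 * fs)]
  expect_gte(max(mid), 0.95)
  expect_lte(max(mid), 1.05)

  # out-of-band tone: measured rejection agrees with the designed
  # filter's frequency response (forward-backward => squared gain)
  x50 <- sin(2 * pi * 50 * t)
  y50 <- bandpass(x50, c(150, 250), fs = fs)
  ratio <- sqrt(mean(y50[(fs):(3 * fs)]^2)) / sqrt(mean(x50^2))
  ord <- ripplepac:::fir_order(c(150, 250), fs)
  h <- signal::fir1(ord, c(150, 250) / (fs / 2), type = "pass")
  fr <- signal::freqz(as.numeric(h), 1, n = 2048, Fs = fs)
  g50 <- abs(fr$h)[which.min(abs(fr$f - 50))]^2
  expect_lt(ratio, 0.1)
  expect_lt(abs(log10(ratio) - log10(g50)), 1)

  expect_equal(bandpass(numeric(2000), c(150, 250), fs = fs),
               numeric(2000), ignore_attr = TRUE)

  expect_error(bandpass(x, c(150, 600), fs = fs),
               class = "ripplepac_parameter_error")
  expect_error(bandpass(x[1:30], c(150, 250), fs = fs),
               class = "ripplepac_length_error")
})

test_that("forward-backward filtering is zero-phase", {
  n <- 4000
  x <- numeric(n)
  tt <- (0:399) / fs
  x[1801:2200] <- sin(2 * pi * 200 * tt) * sin(pi * (0:399) / 399)^2
  y <- bandpass(x, c(150, 250), fs = fs)
  cc <- stats::ccf(y, x, lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("analytic signal recovers amplitude and phase convention", {
  t <- seq(0, 5, length.out = 5 * fs + 1)[-1]
  x <- 3 * sin(2 * pi * 8 * t)
  a <- analytic_signal(x, c(4, 12), fs = fs)
  interior <- (fs):(4 * fs)
  expect_true(all(abs(a$envelope[interior] - 3) < 0.06))
  # phase(cos) = 0 convention: sin = cos(theta - pi/2)
  i_cross <- which.min(abs(t - 2))  # t = 2 s: positive-going zero crossing
  expect_equal(a$phase[i_cross], -pi / 2, tolerance = 0.02)

  # envelope modulus property
  expect_true(all(a$envelope >= abs(a$filtered) - 1e-9))

  # a distant tone does not perturb the in-band envelope
  x2 <- x + sin(2 * pi * 200 * t)
  a2 <- analytic_signal(x2, c(4, 12), fs = fs)
  expect_lt(max(abs(a2$envelope[interior] - a$envelope[interior])), 0.03)
})

test_that("constant traces are flagged degenerate", {
  expect_warning(a <- analytic_signal(rep(2, 3000), c(4, 12), fs = fs),
                 "Constant")
  expect_true(a$degenerate)
  expect_equal(max(a$envelope), 0)
})

test_that("Welch PSD satisfies Parseval and locates tones", {
  withr::local_seed(5)
  x <- rnorm(2^16)
  p <- psd_welch(x, fs = fs)
  integral <- sum(p$power) * attr(p, "df")
  expect_equal(integral, 1.0, tolerance = 0.1)

  t <- seq(0, 8, by = 1 / fs)[-1]
  tone <- sin(2 * pi * 180 * t)
  pt <- psd_welch(tone, fs = fs)
  expect_equal(pt$freq_hz[which.max(pt$power)], 180,
               tolerance = attr(pt, "df") + 1e-9)
  pt2 <- psd_welch(2 * tone, fs = fs)
  expect_equal(max(pt2$power) / max(pt$power), 4, tolerance = 1e-6)

  expect_error(psd_welch(x, freq_range = c(100, 900), fs = fs),
               class = "ripplepac_parameter_error")
  expect_error(psd_welch(x[1:500], fs = fs), class = "ripplepac_length_error")
})

test_that("DPSS tapers are orthonormal and bounded in number", {
  tap <- dpss_tapers(100, 3, 5)
  expect_equal(dim(tap), c(100, 5))
  expect_equal(crossprod(tap), diag(5), tolerance = 1e-8)
  expect_error(dpss_tapers(100, 3, 6), class = "ripplepac_parameter_error")
  expect_error(dpss_tapers(4, 3, 5), class = "ripplepac_parameter_error")
})

test_that("multitaper spectrogram localizes tones in time and frequency", {
  t <- seq(0, 3, by = 1 / fs)[-1]
  x <- rep(0, length(t))
  sel <- t > 1 & t <= 2
  x[sel] <- sin(2 * pi * 40 * t[sel])
  sp <- mt_spectrogram(x + 0.01 * withr::with_seed(1, rnorm(length(t))),
                       fs = fs)
  i40 <- which.min(abs(sp$freqs - 40))

  stationary <- mt_spectrogram(sin(2 * pi * 40 * t), fs = fs)
  argmax_f <- sp$freqs[apply(stationary$power, 2, which.max)]
  expect_true(all(abs(argmax_f - 40) <= 10))

  inside <- sp$times > 1.06 & sp$times < 1.94
  outside <- sp$times < 0.9
  expect_gt(mean(sp$power[i40, inside]), 10 * mean(sp$power[i40, outside]))

  # single-taper oracle: plain Hann periodogram spectrogram shows the
  # same contrast, so the localization is not a taper artifact
  hann_pow <- vapply(seq(1, length(x) - 99, by = 10), function(s) {
    seg <- x[s:(s + 99)] * (0.5 - 0.5 * cos(2 * pi * (0:99) / 100))
    Mod(fft(seg))[5]^2  # index 5 = bin 4 = 40 Hz at 10 Hz resolution
  }, numeric(1))
  hann_t <- (seq(1, length(x) - 99, by = 10) - 1 + 49.5) / fs
  expect_gt(mean(hann_pow[hann_t > 1.06 & hann_t < 1.94]),
            10 * mean(hann_pow[hann_t < 0.9]))

  expect_error(mt_spectrogram(x[1:50], fs = fs),
               class = "ripplepac_length_error")
})

test_that("white-noise spectrogram is flat and K tapers cut variance", {
  withr::local_seed(8)
  x <- rnorm(2^15)
  sp5 <- mt_spectrogram(x, fs = fs, nw = 3, k = 5)
  row_means <- rowMeans(sp5$power)
  interior <- sp5$freqs > 20 & sp5$freqs < 480
  expect_lt(stats::sd(row_means[interior]) / mean(row_means[interior]), 0.15)

  sp1 <- mt_spectrogram(x, fs = fs, nw = 1, k = 1)
  i100 <- which.min(abs(sp5$freqs - 100))
  expect_lt(var(sp5$power[i100, ]), var(sp1$power[i100, ]))
})
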