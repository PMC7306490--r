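fs <- 31.25

test_that("MBLL conversion: constants, scaling and superposition", {
  n <- 300
  h <- mbll_convert(rep(1234, n), rep(987, n))
  expect_equal(h$hbo, numeric(n))
  expect_equal(h$hbr, numeric(n))

  hbo <- generate_source_lfo(30, fs, seed = 1) * 1e-6
  hbr <- -0.25 * hbo
  I <- forward_intensity_model(hbo, hbr)
  # doubling both DPFs halves both concentration series exactly
  opt2 <- optics_constants(dpf = c(`660` = 2 * 6.51, `920` = 2 * 5.86))
  h1 <- mbll_convert(I[, "660"], I[, "920"])
  h2 <- mbll_convert(I[, "660"], I[, "920"], opt2)
  expect_equal(h2$hbo, h1$hbo / 2, tolerance = 1e-12)
  expect_equal(h2$hbr, h1$hbr / 2, tolerance = 1e-12)

  # linearity in log-intensity: converting I and I' and the sample-wise
  # geometric mixture is additive to machine precision
  Ib <- forward_intensity_model(0.5e-6 * sin(seq_len(length(hbo)) / 50),
                                numeric(length(hbo)))
  ha <- mbll_convert(I[, "660"], I[, "920"])
  hb <- mbll_convert(Ib[, "660"], Ib[, "920"])
  hs <- mbll_convert(I[, "660"] * Ib[, "660"] / 1000,
                     I[, "920"] * Ib[, "920"] / 1000)
  expect_equal(hs$hbo, ha$hbo + hb$hbo, tolerance = 1e-10)

  expect_error(mbll_convert(c(1, -1), c(1, 1)), "positive")
  expect_error(optics_constants(extinction = matrix(1, 2, 2)), "singular")
})

test_that("spike detector flags injected spikes and nothing else", {
  t <- (0:3124) / fs
  clean <- sin(2 * pi * 0.08 * t)
  expect_equal(nrow(detect_spikes(clean, fs)), 0)
  expect_equal(nrow(detect_spikes(rep(3, 100), fs)), 0)

  x <- clean
  d_sd <- mad(diff(x))
  x[1000] <- x[1000] + 10 * d_sd * 10
  m1 <- detect_spikes(x, fs)
  expect_equal(nrow(m1), 1)
  expect_true(m1$start[1] <= 1000 && m1$end[1] >= 1000)

  x[1100] <- x[1100] - 10 * d_sd * 10
  m2 <- detect_spikes(x, fs)
  expect_equal(nrow(m2), 2)
  expect_true(all(m2$end >= m2$start))
})

test_that("spline correction restores masked content", {
  x <- sin(2 * pi * 0.05 * (0:999) / fs)
  empty <- detect_spikes(x, fs)
  expect_identical(spline_correct(x, empty), x)

  # exact on linear data
  lin <- seq(0, 10, length.out = 500)
  mask <- slfomark:::artifact_mask_from_indices(200:210, 500)
  expect_lt(max(abs(spline_correct(lin, mask) - lin)), 1e-10)

  # improves RMSE on a spiked sinusoid
  spiked <- x
  spiked[400] <- spiked[400] + 8
  m <- detect_spikes(spiked, fs)
  expect_gt(nrow(m), 0)
  fixed <- spline_correct(spiked, m)
  expect_lt(sqrt(mean((fixed - x)^2)), sqrt(mean((spiked - x)^2)))

  full <- slfomark:::artifact_mask_from_indices(1:500, 500)
  expect_error(spline_correct(lin, full), "entire")
})

test_that("kurtosis wavelet filter: Gaussian passes, spikes shrink, energy bounded", {
  # Gaussian input passes unchanged (no level flagged) in >= 19/20 seeds
  fails <- 0
  for (k in 1:20) {
    set.seed(k)
    x <- rnorm(2048)
    if (max(abs(kurtosis_wavelet_filter(x) - x)) > 1e-10) fails <- fails + 1
  }
  expect_lte(fails, 1)

  set.seed(5)
  x <- rnorm(4096)
  idx <- sample(4096, 12)
  x[idx] <- x[idx] + 15
  k_in <- slfomark:::moment_kurtosis(x)
  y <- kurtosis_wavelet_filter(x)
  expect_gt(k_in, 13)
  expect_lt(abs(slfomark:::moment_kurtosis(y) - 3), abs(k_in - 3))
  expect_lte(sum(y^2), sum(x^2))

  expect_equal(kurtosis_wavelet_filter(numeric(512)), numeric(512))
  expect_error(kurtosis_wavelet_filter(rnorm(32), levels = 6), "2\\^6")
})

test_that("wavelet pyramid reconstructs exactly (orthonormal perfect reconstruction)", {
  set.seed(2)
  x <- rnorm(1024)
  p <- slfomark:::dwt_pyramid(x, 5)
  expect_lt(max(abs(slfomark:::idwt_pyramid(p) - x)), 1e-12)
  # Parseval: coefficient energy equals signal energy
  expect_equal(sum(p$a^2) + sum(unlist(p$d)^2), sum(x^2), tolerance = 1e-12)
})

test_that("band-pass is zero-phase with the specified pass/stop behavior", {
  t <- seq(0, 600 - 1 / fs, by = 1 / fs)
  # DC rejection
  ydc <- bandpass_slfo(rep(5, length(t)), fs)
  expect_lt(mean(abs(ydc)), 1e-3 * 5)
  # in-band tone: amplitude in [0.9, 1.0], zero lag
  x <- sin(2 * pi * 0.08 * t)
  y <- bandpass_slfo(x, fs)
  mid <- 4000:14000
  expect_gt(max(abs(y[mid])), 0.9)
  expect_lte(max(abs(y[mid])), 1.0 + 1e-6)
  cc <- ccf(x, y, lag.max = 30, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  expect_lt(abs(mean(y)), 1e-3)
  # cardiac tone rejected by > 20 dB
  yc <- bandpass_slfo(sin(2 * pi * 1.1 * t), fs)
  expect_lt(max(abs(yc[mid])), 0.1)
  expect_error(bandpass_slfo(x, fs, band = c(0.1, 20)), "band")
})

test_that("full per-site preprocessing: provenance, no-op on clean data, recovery", {
  src <- generate_source_lfo(300, fs, seed = 7)
  I <- forward_intensity_model(1e-6 * src, -0.25e-6 * src)
  set.seed(41)
  I <- I + matrix(rnorm(length(I)), nrow(I)) * 0.1  # sensor noise floor

  a <- preprocess_site(I[, "660"], I[, "920"], fs)
  b <- preprocess_site(I[, "660"], I[, "920"], fs, spike = FALSE, wavelet = FALSE)
  expect_lt(sqrt(mean((a$hbo - b$hbo)^2)) / sqrt(mean(b$hbo^2)), 1e-6)
  expect_length(a$provenance, 4)  # mbll, spike, wavelet, bandpass
  expect_length(b$provenance, 2)

  # artifact-laden subject: homologous MCCC after the full chain stays
  # within 0.05 of the value on the noise-free ground-truth sLFOs
  set.seed(91)
  cfg <- vascular_config()
  sig <- slfomark:::simulate_subject_signals(cfg, duration = 300, fs = fs)
  truth <- mccc_delay(sig$slfo_truth$LE, sig$slfo_truth$RE, fs)
  est <- local({
    pa <- preprocess_site(sig$intensity$LE[, "660"], sig$intensity$LE[, "920"], fs)
    pb <- preprocess_site(sig$intensity$RE[, "660"], sig$intensity$RE[, "920"], fs)
    mccc_delay(pa$hbo, pb$hbo, fs)
  })
  expect_lt(abs(est$mccc - truth$mccc), 0.05)
})
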