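fs <- 31.25

test_that("moving-window arithmetic matches the recording durations", {
  x600 <- rnorm(round(600 * fs))
  w <- segment_windows(x600, fs)
  expect_length(w, 11)
  expect_equal(attr(w, "starts"), seq(0, 300, by = 30))
  expect_true(all(lengths(w) == round(300 * fs)))

  w480 <- segment_windows(rnorm(round(480 * fs)), fs)
  expect_length(w480, 7)

  one <- segment_windows(rnorm(round(300 * fs)), fs)
  expect_length(one, 1)
  expect_error(segment_windows(rnorm(100), fs), "shorter")
  expect_error(window_scheme(300, 0), "step")
})

test_that("mccc_delay: identity, constructed shifts, and the stated sign convention", {
  x <- generate_source_lfo(300, fs, seed = 3)
  same <- mccc_delay(x, x, fs)
  expect_equal(same$mccc, 1.0, tolerance = 1e-12)
  expect_equal(same$delay, 0)

  # y advanced by 2 s (y(t) = x(t + 2)): x lags y, delay(x, y) = +2
  k <- round(2 * fs)  # realized shift on the sample grid
  y <- c(x[-(1:k)], x[1:k])
  md <- mccc_delay(x[1:8000], y[1:8000], fs)
  expect_lt(abs(md$delay - k / fs), 1 / fs + 1e-9)
  expect_gt(md$mccc, 0.99)

  expect_error(mccc_delay(rep(1, 100), rnorm(100), fs, max_lag = 1),
               "zero-variance")
})

test_that("mccc_delay agrees exactly with the brute-force lag scan", {
  set.seed(8)
  for (rep in 1:5) {
    x <- rnorm(50); y <- rnorm(50)
    fast <- mccc_delay(x, y, fs = 1, max_lag = 10)
    slow <- brute_mccc(x, y, fs = 1, max_lag = 10)
    expect_equal(fast$mccc, slow$mccc, tolerance = 1e-12)
    expect_identical(fast$delay, slow$delay)
  }
  # and on band-limited signals at the native rate
  x <- generate_source_lfo(60, fs, seed = 4)
  y <- generate_source_lfo(60, fs, seed = 5)
  fast <- mccc_delay(x, y, fs, max_lag = 5)
  slow <- brute_mccc(x, y, fs, max_lag = 5)
  expect_equal(fast$mccc, slow$mccc, tolerance = 1e-12)
  expect_identical(fast$delay, slow$delay)
})

test_that("mccc_delay symmetry and affine invariance", {
  x <- generate_source_lfo(120, fs, seed = 6)
  y <- generate_source_lfo(120, fs, seed = 7)
  ab <- mccc_delay(x, y, fs)
  ba <- mccc_delay(y, x, fs)
  expect_equal(ab$mccc, ba$mccc, tolerance = 1e-12)
  expect_equal(ab$delay, -ba$delay)
  sc <- mccc_delay(3.7 * x + 11, 0.2 * y - 5, fs)
  expect_equal(sc$mccc, ab$mccc, tolerance = 1e-10)
  expect_equal(sc$delay, ab$delay)
})

test_that("noise-free delay recovery is within one sample across +/- 10 s", {
  src <- generate_source_lfo(340, fs, seed = 10)
  n <- round(300 * fs)
  base <- src[round(12 * fs) + (1:n)]
  for (shift in c(-10, -4.8, -1.27, 0.5, 3.04, 10)) {
    # reference(t) = base(t + shift), so base lags it by `shift`
    reference <- src[round((12 + shift) * fs) + (1:n)]
    md <- mccc_delay(base, reference, fs)
    expect_lt(abs(md$delay - round(shift * fs) / fs), 1 / fs + 1e-12)
  }
})

test_that("pair metrics: aggregation and significance gating", {
  x <- generate_source_lfo(600, fs, seed = 11)
  pm <- pair_metrics(x, x, fs, pair = c("LE", "RE"))
  expect_equal(nrow(pm$windows), 11)
  expect_true(all(pm$windows$mccc > 1 - 1e-12))
  expect_true(all(pm$windows$delay == 0))
  expect_equal(pm$mccc_summary, 1, tolerance = 1e-12)
  expect_equal(pm$delay_summary, 0)
  expect_equal(pm$abs_delay_variance, 0)
  expect_equal(pm$n_significant, 11)

  # 2 s injected asymmetry recovered in the summary
  k <- round(2 * fs)
  y <- c(x[-(1:k)], x[1:k])
  pm2 <- pair_metrics(x, y, fs)
  expect_lt(abs(abs(pm2$delay_summary) - 2), 1 / fs + 1e-12)

  # sub-threshold windows are excluded from delay summaries
  set.seed(12)
  a <- rnorm(round(600 * fs))
  pm3 <- pair_metrics(a, rev(a) + rnorm(length(a)), fs, mccc_threshold = 1.1)
  expect_equal(pm3$n_significant, 0)
  expect_true(is.na(pm3$delay_summary))
})

test_that("window-level null exceedance matches the calibrated null distribution", {
  null <- null_mccc_threshold(n_sim = 1000, duration_s = 300, seed = 101)
  p_null <- mean(null$mccc >= 0.3)
  # fresh independent low-passed pairs, windowed exactly like the pipeline
  set.seed(102)
  hits <- 0; tot <- 0
  for (k in 1:30) {
    x <- slfomark:::band_limited_noise(round(300 * fs), fs, c(0, 0.1))
    y <- slfomark:::band_limited_noise(round(300 * fs), fs, c(0, 0.1))
    pm <- pair_metrics(x, y, fs, scheme = window_scheme(300, 300))
    hits <- hits + pm$n_significant
    tot <- tot + nrow(pm$windows)
  }
  expect_lt(abs(hits / tot - p_null), 0.12)
})

test_that("null threshold: broadband below filtered, non-increasing in duration", {
  filt <- null_mccc_threshold(n_sim = 1000, duration_s = 300, seed = 55)
  broad <- null_mccc_threshold(n_sim = 1000, duration_s = 300,
                               band = c(0, 12), seed = 55)
  expect_lt(broad$threshold, filt$threshold)

  long <- null_mccc_threshold(n_sim = 1000, duration_s = 600, seed = 55)
  expect_lte(long$threshold, filt$threshold)

  # seed-to-seed reproducibility of the quantile
  rep2 <- null_mccc_threshold(n_sim = 2000, duration_s = 300, seed = 56)
  rep3 <- null_mccc_threshold(n_sim = 2000, duration_s = 300, seed = 57)
  expect_lt(abs(rep2$threshold - rep3$threshold), 0.02)
  expect_error(null_mccc_threshold(n_sim = 10), "1000")
})

test_that("Welch PSD: peak location, Parseval, flat-spectrum width", {
  t <- seq(0, 600 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 0.05 * t)
  prof <- compute_psd(x, fs)
  expect_equal(prof$freqs[which.max(prof$psd)], 0.05, tolerance = prof$df)
  expect_true(all(prof$psd >= 0))

  # total Welch power approximates the variance within 5%
  y <- generate_source_lfo(600, fs, seed = 14)
  p <- compute_psd(y, fs)
  expect_lt(abs(sum(p$psd) * p$df - var(y)) / var(y), 0.05)

  # in-band white noise: width near 0.95 x band occupancy, and
  # fraction 1 forced to the upper band edge
  w <- spectral_width(p)
  expect_lt(abs(w - (0.01 + 0.95 * 0.14)), 2 * p$df + 1e-9)
  expect_equal(spectral_width(p, 1.0), 0.15, tolerance = p$df + 1e-9)
})

test_that("spectral width: edge cases and distortion sensitivity", {
  t <- seq(0, 600 - 1 / fs, by = 1 / fs)
  prof <- compute_psd(sin(2 * pi * 0.05 * t), fs)
  expect_lt(abs(spectral_width(prof, 0.95) - 0.05), prof$df + 1e-9)

  full <- generate_source_lfo(600, fs, seed = 15)
  low <- lowpass_zero_phase(full, fs, corner = 0.04)
  expect_lt(spectral_width(compute_psd(low, fs)),
            spectral_width(compute_psd(full, fs)))
  expect_error(spectral_width(compute_psd(numeric(10000) + 1, fs)), "power")
})
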