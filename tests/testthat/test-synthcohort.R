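fs <- 31.25

test_that("source sLFO is deterministic, correctly sized and band-limited", {
  expect_identical(generate_source_lfo(60, fs, seed = 5),
                   generate_source_lfo(60, fs, seed = 5))
  src <- generate_source_lfo(600, fs, seed = 3)
  expect_length(src, 18750)
  expect_equal(mean(src), 0, tolerance = 1e-12)
  expect_equal(sd(src), 1, tolerance = 1e-12)
  # spectral mass inside the band, against a direct DFT power sum
  P <- Mod(fft(src))^2
  f <- (seq_along(src) - 1) * fs / length(src)
  inband <- (f >= 0.01 & f <= 0.15) | (f >= fs - 0.15 & f <= fs - 0.01)
  expect_gte(sum(P[inband]) / sum(P[-1]), 0.95)
  expect_error(generate_source_lfo(60, fs, band = c(0.01, 20)), "band")
})

test_that("propagation: identity with trivial config, exact homologous MCCC", {
  src <- generate_source_lfo(120, fs, seed = 9)
  cfg0 <- vascular_config(
    site_delays = setNames(rep(0, 6), SLFO_SITES),
    noise_sd = 0)
  sig <- propagate_to_sites(src, cfg0, fs)
  for (s in SLFO_SITES[-1]) expect_identical(sig[[s]], sig$LE)

  cfg <- vascular_config(noise_sd = 0)
  sig <- propagate_to_sites(src, cfg, fs)
  md <- mccc_delay(sig$LF, sig$RF, fs)
  expect_equal(md$mccc, 1.0, tolerance = 1e-9)
  expect_equal(md$delay, 0)
})

test_that("an injected 3.04 s homologous delay is recovered within one sample", {
  src <- generate_source_lfo(300, fs, seed = 12)
  cfg <- vascular_config(
    site_delays = c(LT = 3.04, RT = 0), noise_sd = 0)
  sig <- propagate_to_sites(src, cfg, fs)
  md <- mccc_delay(sig$LT, sig$RT, fs)
  expect_gt(md$mccc, 0.98)
  expect_lt(abs(md$delay - 3.04), 1 / fs)
})

test_that("arrival order earlobe <= finger <= toe holds on noise-free draws", {
  for (k in 1:3) {
    src <- generate_source_lfo(200, fs, seed = 40 + k)
    cfg <- vascular_config(noise_sd = 0)
    set.seed(50 + k)
    delays <- cfg$site_delays + rnorm(6, 0, cfg$lr_jitter_sd)
    cfg$site_delays <- pmax(delays, 0)
    sig <- propagate_to_sites(src, cfg, fs)
    d_ef <- mccc_delay(sig$LE, sig$LF, fs)$delay
    d_ft <- mccc_delay(sig$LF, sig$LT, fs)$delay
    expect_lte(d_ef, 1 / fs)   # earlobe arrives before finger
    expect_lte(d_ft, 1 / fs)   # finger arrives before toe
  }
})

test_that("embolism perturbation: identity at severity 0, delay shift, distortion", {
  src <- generate_source_lfo(300, fs, seed = 21)
  cfg <- vascular_config(noise_sd = 0)
  sig <- propagate_to_sites(src, cfg, fs)

  expect_identical(apply_embolism(sig, embolism_spec("LE", severity = 0), fs),
                   sig)
  expect_error(apply_embolism(sig, embolism_spec("XX")), "XX")

  # +2 s on LE shifts the (LE, RE) delay estimate by 2 s
  pert <- apply_embolism(sig, embolism_spec(
    "LE", extra_delay = 2, attenuation = 1, severity = 1), fs)
  d0 <- mccc_delay(sig$LE, sig$RE, fs)$delay
  d1 <- mccc_delay(pert$LE, pert$RE, fs)$delay
  expect_lt(abs((d1 - d0) - 2), 1 / fs)
  # only affected sites change
  expect_identical(pert$RF, sig$RF)

  # waveform distortion strictly lowers MCCC on the same draw
  cfgn <- vascular_config(noise_sd = 0.4, seed = 77)
  sign <- propagate_to_sites(src, cfgn, fs)
  dist <- apply_embolism(sign, embolism_spec(
    "LE", extra_delay = 0, attenuation = 1, distortion_corner = 0.05,
    severity = 1), fs)
  expect_lt(mccc_delay(dist$LE, dist$RE, fs)$mccc,
            mccc_delay(sign$LE, sign$RE, fs)$mccc)
})

test_that("forward intensity model is the exact inverse of the MBLL conversion", {
  n <- 400
  expect_equal(unname(forward_intensity_model(numeric(n), numeric(n))),
               unname(cbind(rep(1000, n), rep(1000, n))))
  hbo <- generate_source_lfo(60, fs, seed = 31) * 1e-6
  hbr <- -0.3 * hbo + 0.2e-6 * generate_source_lfo(60, fs, seed = 32)
  I <- forward_intensity_model(hbo, hbr)
  h <- mbll_convert(I[, "660"], I[, "920"], fs = fs)
  expect_lt(max(abs(h$hbo - hbo)) / sd(hbo), 1e-8)
  expect_lt(max(abs(h$hbr - hbr)) / sd(hbr), 1e-8)

  # linearity: doubling hbo doubles the optical-density change predicted
  # by the 2x2 system at each wavelength
  opt <- optics_constants()
  I2 <- forward_intensity_model(2 * hbo, hbr)
  dod1 <- -log10(I[, "660"] / 1000)
  dod2 <- -log10(I2[, "660"] / 1000)
  pred <- opt$extinction["660", "HbO"] * hbo * opt$dpf[["660"]]
  expect_equal(dod2 - dod1, unname(pred), tolerance = 1e-10)
  expect_error(forward_intensity_model(c(1, NA), c(0, 0)), "non-finite")
})

test_that("cohort simulation bookkeeping, labels and byte determinism", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  man <- simulate_cohort(3, 2, dir1, duration = 40, seed = 5)
  expect_equal(nrow(man$entries), 5)
  expect_equal(sum(man$entries$group == "healthy"), 3)
  expect_equal(sum(man$entries$group == "stroke"), 2)
  man2 <- simulate_cohort(3, 2, dir2, duration = 40, seed = 5)
  for (i in seq_len(5)) {
    expect_identical(readLines(man$entries$file[i]),
                     readLines(man2$entries$file[i]))
  }
  expect_error(simulate_cohort(-1, 2, dir1), ">= 0")
})

test_that("healthy cohort matches the reference homologous MCCC level and stroke degrades it", {
  fx <- cohort_fixture()
  feat <- fx$analysis$features
  healthy <- feat$group == "healthy"
  m <- feat[["mccc_LE-RE"]]
  # healthy homologous-pair MCCC centers on 0.78 +/- 0.15
  expect_gt(mean(m[healthy]), 0.78 - 0.15)
  expect_lt(mean(m[healthy]), 0.78 + 0.15)
  # stroke distribution stochastically below healthy
  expect_lt(ranksum_test(m[healthy], m[!healthy])$p_value, 0.05)
  expect_lt(median(m[!healthy]), median(m[healthy]))
})
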