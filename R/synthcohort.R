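# Synthetic vascular-propagation cohort generator.
#
# The generator emulates the statistical structure the analysis relies
# on: a single aperiodic cardiac-origin source oscillation in the sLFO
# band travels through the vasculature and arrives at the six
# peripheral sites with path-specific delays (earlobes first, then
# fingers, then toes), gains and waveform distortion; embolism-like
# perturbations add delay, attenuation and low-pass distortion on
# affected paths; site-local in-band noise, cardiac pulsation and
# motion artifacts complete the raw dual-wavelength intensities.

#' Vascular propagation configuration
#'
#' Defaults encode the healthy arrival-order assumption (earlobes
#' 0.8 s, fingers 1.6 s, toes 2.4 s from the common source) with a
#' left/right transit jitter of SD 0.15 s, so homologous-pair delays
#' are near zero. Site noise is band-limited to the sLFO analysis band
#' (local vasomotion plus in-band instrument noise); its default SD of
#' 0.55 relative to the unit-SD source puts healthy homologous-pair
#' MCCC near 0.78. The 1.1-Hz cardiac component must be rejected by the
#' sLFO band-pass and doubles as a filter check.
#'
#' @param site_delays named numeric, transit delay in seconds per site.
#' @param site_gains named numeric, amplitude scale per site.
#' @param path_lowpass named list, optional corner frequency in Hz per
#'   site modeling waveform distortion (NULL entries = no distortion).
#' @param noise_sd SD of site-local in-band noise relative to the
#'   unit-SD source sLFO.
#' @param noise_band band of the site-local noise in Hz.
#' @param lr_jitter_sd SD in seconds of the per-subject left/right
#'   transit-time jitter.
#' @param cardiac_freq,cardiac_amp cardiac pulsation frequency (Hz) and
#'   amplitude relative to the source SD.
#' @param artifact_spec list: `spike_rate_per_min`, `spike_amp_sd`
#'   (multiples of the intensity-fluctuation SD), `quiver_rate_per_min`,
#'   `quiver_band` (Hz), `quiver_amp_sd`, `quiver_dur_s` (range).
#' @param sensor_noise_sd SD of broadband (white) instrument noise at
#'   the intensity level, as a fraction of the baseline intensity
#'   (default 1e-4; photodetector shot/quantization floor).
#' @param band source sLFO band in Hz.
#' @param seed optional seed making [propagate_to_sites()] reproducible.
#' @export
vascular_config <- function(
    site_delays = c(LE = 0.8, RE = 0.8, LF = 1.6, RF = 1.6, LT = 2.4, RT = 2.4),
    site_gains = c(LE = 1, RE = 1, LF = 1, RF = 1, LT = 1, RT = 1),
    path_lowpass = NULL,
    noise_sd = 0.55,
    noise_band = c(0.01, 0.15),
    lr_jitter_sd = 0.15,
    cardiac_freq = 1.1,
    cardiac_amp = 0.6,
    artifact_spec = list(spike_rate_per_min = 0.3, spike_amp_sd = 10,
                         quiver_rate_per_min = 0.2, quiver_band = c(2, 8),
                         quiver_amp_sd = 2, quiver_dur_s = c(1, 5)),
    sensor_noise_sd = 1e-4,
    band = c(0.01, 0.15),
    seed = NULL) {
  if (any(site_delays < 0)) stop_param("site delays must be >= 0")
  if (any(site_gains <= 0)) stop_param("site gains must be > 0")
  if (noise_sd < 0) stop_param("noise_sd must be >= 0")
  structure(list(site_delays = site_delays, site_gains = site_gains,
                 path_lowpass = path_lowpass, noise_sd = noise_sd,
                 noise_band = noise_band, lr_jitter_sd = lr_jitter_sd,
                 cardiac_freq = cardiac_freq, cardiac_amp = cardiac_amp,
                 artifact_spec = artifact_spec,
                 sensor_noise_sd = sensor_noise_sd,
                 band = band, seed = seed),
            class = "vascular_config")
}

#' Embolism perturbation specification
#'
#' Models a vascular lesion on the paths to `affected_sites` as an
#' added transit delay, a multiplicative attenuation and a low-pass
#' waveform distortion, all scaled by `severity`: at severity 0 the
#' perturbation is the identity (no delay, gain 1, distortion corner
#' pushed to infinity); at severity 1 the nominal values apply.
#'
#' @param affected_sites character vector of site labels.
#' @param extra_delay seconds added on the affected path (at severity 1).
#' @param attenuation multiplicative gain in (0, 1] (at severity 1).
#' @param distortion_corner optional low-pass corner in Hz (at
#'   severity 1); NULL disables distortion.
#' @param severity scalar in \[0, 1\].
#' @export
embolism_spec <- function(affected_sites, extra_delay = 2,
                          attenuation = 0.7, distortion_corner = NULL,
                          severity = 1) {
  if (!(severity >= 0 && severity <= 1)) stop_param("severity must lie in [0, 1]")
  if (extra_delay < 0) stop_param("extra_delay must be >= 0")
  if (!(attenuation > 0 && attenuation <= 1))
    stop_param("attenuation must lie in (0, 1]")
  structure(list(affected_sites = affected_sites, extra_delay = extra_delay,
                 attenuation = attenuation,
                 distortion_corner = distortion_corner, severity = severity),
            class = "embolism_spec")
}

#' Generate the common source sLFO
#'
#' The source oscillation is stationary Gaussian noise band-limited to
#' `band` (zero-phase Butterworth, steady-state draw), standardized to
#' zero mean and unit SD: aperiodic and inharmonic, with no phase, as
#' systemic LFOs are.
#'
#' @param duration seconds.
#' @param fs sampling rate in Hz.
#' @param band in Hz, default `c(0.01, 0.15)`.
#' @param seed RNG seed (same seed, same signal).
#' @return numeric vector of `round(duration * fs)` samples.
#' @export
generate_source_lfo <- function(duration, fs = 31.25, band = c(0.01, 0.15),
                                seed = NULL) {
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < fs / 2))
    stop_param("band must satisfy 0 < band[1] < band[2] < fs/2")
  n <- round(duration * fs)
  with_seed(seed, {
    y <- band_limited_noise(n, fs, band, burn_s = max(60, 1.5 / band[1]))
    (y - mean(y)) / sd(y)
  })
}

# Fractional-sample shift by linear interpolation on the native grid;
# delays of interest (0.1-5 s) dwarf the 32-ms sample period, so linear
# interpolation loses no relevant accuracy. Edge values are held.
fractional_shift <- function(x, delay_samples) {
  if (delay_samples == 0) return(x)
  approx(seq_along(x), x, xout = seq_along(x) - delay_samples, rule = 2)$y
}

#' Propagate the source sLFO to the peripheral sites
#'
#' Each site receives `gain * source(t - delay)`, optionally low-passed
#' (path distortion), plus site-local band-limited noise. Delays are
#' realized as fractional-sample shifts; the first
#' `ceiling(max(delay) * fs)` samples, where shifted signals depend on
#' unobserved history, are trimmed identically from every site so all
#' outputs share a common time base.
#'
#' @param source numeric source signal (see [generate_source_lfo()]).
#' @param cfg a [vascular_config()].
#' @param fs sampling rate in Hz.
#' @return named list of site signals (equal lengths).
#' @export
propagate_to_sites <- function(source, cfg, fs = 31.25) {
  stopifnot(inherits(cfg, "vascular_config"))
  check_series(source)
  delays <- cfg$site_delays
  if (max(delays) * fs >= length(source))
    stop_param("delay (%g s) must be shorter than the source duration (%g s)",
               max(delays), length(source) / fs)
  n_trim <- ceiling(max(delays) * fs)
  keep <- seq(n_trim + 1L, length(source))
  with_seed(cfg$seed, {
    out <- lapply(names(delays), function(s) {
      y <- fractional_shift(source, delays[[s]] * fs)[keep]
      corner <- cfg$path_lowpass[[s]]
      if (!is.null(corner) && corner < fs / 2)
        y <- lowpass_zero_phase(y, fs, corner)
      y <- cfg$site_gains[[s]] * y
      if (cfg$noise_sd > 0) {
        nz <- band_limited_noise(length(y), fs, cfg$noise_band)
        y <- y + cfg$noise_sd * nz / sd(nz)
      }
      y
    })
    setNames(out, names(delays))
  })
}

#' Apply an embolism perturbation to propagated site signals
#'
#' Only the affected sites change; severity 0 returns the input
#' unchanged. The effective perturbation is
#' `delay = severity * extra_delay`,
#' `gain = 1 - severity * (1 - attenuation)`, and a low-pass at
#' `distortion_corner / severity` Hz (so the corner recedes to infinity
#' as severity vanishes).
#'
#' @param site_signals named list of site series.
#' @param spec an [embolism_spec()].
#' @param fs sampling rate in Hz.
#' @export
apply_embolism <- function(site_signals, spec, fs = 31.25) {
  stopifnot(inherits(spec, "embolism_spec"))
  unknown <- setdiff(spec$affected_sites, names(site_signals))
  if (length(unknown))
    stop_param("unknown affected site(s): %s", paste(unknown, collapse = ", "))
  if (spec$severity == 0) return(site_signals)
  for (s in spec$affected_sites) {
    y <- site_signals[[s]]
    d <- spec$severity * spec$extra_delay * fs
    if (d > 0) y <- fractional_shift(y, d)
    if (!is.null(spec$distortion_corner)) {
      corner <- spec$distortion_corner / spec$severity
      if (corner < fs / 2) y <- lowpass_zero_phase(y, fs, corner)
    }
    y <- (1 - spec$severity * (1 - spec$attenuation)) * y
    site_signals[[s]] <- y
  }
  site_signals
}

#' Forward model: concentration changes to dual-wavelength intensities
#'
#' Exact inverse of [mbll_convert()]: the optical-density change at
#' each wavelength is assembled from the extinction coefficients and
#' DPFs, and intensities are emitted as
#' `I(lambda, t) = baseline(lambda) * 10^(-dOD(lambda, t))`. Feeding
#' the result back through [mbll_convert()] recovers zero-mean inputs
#' to machine precision (the conversion references intensities to
#' their temporal geometric mean).
#'
#' @param hbo,hbr concentration-change series (equal length; units
#'   consistent with `optics`).
#' @param optics an [optics_constants()].
#' @param baseline named numeric, baseline intensity per wavelength in
#'   device units.
#' @return numeric matrix with columns `"660"` and `"920"`.
#' @export
forward_intensity_model <- function(hbo, hbr, optics = optics_constants(),
                                    baseline = c(`660` = 1000, `920` = 1000)) {
  stopifnot(inherits(optics, "optics_constants"))
  check_series(hbo, "hbo"); check_series(hbr, "hbr")
  if (length(hbo) != length(hbr)) stop_param("hbo and hbr must have equal length")
  conc <- rbind(HbO = hbo, HbR = hbr)
  dod <- (optics$extinction %*% conc) * (optics$dpf * optics$separation)
  i <- 10^(-t(dod))
  cbind(`660` = baseline[["660"]] * i[, 1], `920` = baseline[["920"]] * i[, 2])
}

# Motion artifacts injected at the intensity level (sudden light-level
# changes). Spikes: 1-3 sample excursions; quivers: Hann-enveloped
# band-limited bursts. Amplitudes are multiples of the channel's own
# fluctuation SD. Uses the current RNG stream.
add_motion_artifacts <- function(intensity, fs, spec) {
  n <- nrow(intensity)
  dur_min <- n / fs / 60
  n_spike <- stats::rpois(1, (spec$spike_rate_per_min %||% 0) * dur_min)
  n_quiver <- stats::rpois(1, (spec$quiver_rate_per_min %||% 0) * dur_min)
  sds <- apply(intensity, 2, sd)
  if (n_spike > 0) {
    for (i in seq_len(n_spike)) {
      at <- sample.int(n - 3L, 1L)
      width <- sample.int(3L, 1L)
      amp <- runif(1, 5, spec$spike_amp_sd %||% 15) * sample(c(-1, 1), 1)
      idx <- at:(at + width - 1L)
      intensity[idx, ] <- intensity[idx, ] + rep(amp * sds, each = width)
    }
  }
  if (n_quiver > 0) {
    qb <- spec$quiver_band %||% c(2, 8)
    qd <- spec$quiver_dur_s %||% c(1, 5)
    for (i in seq_len(n_quiver)) {
      len <- round(runif(1, qd[1], qd[2]) * fs)
      at <- sample.int(max(1L, n - len), 1L)
      burst <- band_limited_noise(len, fs, qb, burn_s = 2)
      burst <- burst / max(sd(burst), 1e-12)
      env <- 0.5 - 0.5 * cos(2 * pi * seq(0, len - 1) / (len - 1))
      amp <- runif(1, 0.5, spec$quiver_amp_sd %||% 2)
      idx <- at:(at + len - 1L)
      intensity[idx, ] <- intensity[idx, ] + (amp * burst * env) %o% sds
    }
  }
  # intensities must stay strictly positive for the log downstream
  pmax(intensity, 1e-9)
}

# Render one subject: source -> sites -> (embolism) -> cardiac ->
# intensities -> artifacts. Uses the current RNG stream.
simulate_subject_signals <- function(cfg, embolism = NULL, duration = 600,
                                     fs = 31.25, optics = optics_constants(),
                                     hbo_amp = 1e-6, hbr_ratio = -0.25,
                                     baseline = c(`660` = 1000, `920` = 1000)) {
  jitter <- rnorm(length(cfg$site_delays), 0, cfg$lr_jitter_sd)
  delays <- pmax(cfg$site_delays + jitter, 0)
  cfg_j <- cfg
  cfg_j$site_delays <- delays
  cfg_j$seed <- NULL
  margin_s <- max(delays) + 1
  n <- round(duration * fs)
  src <- band_limited_noise(n + ceiling(margin_s * fs), fs, cfg$band,
                            burn_s = max(60, 1.5 / cfg$band[1]))
  src <- (src - mean(src)) / sd(src)
  sites <- propagate_to_sites(src, cfg_j, fs)
  sites <- lapply(sites, function(y) y[seq_len(n)])
  if (!is.null(embolism)) sites <- apply_embolism(sites, embolism, fs)
  t <- (seq_len(n) - 1) / fs
  intensity <- lapply(names(sites), function(s) {
    card <- cfg$cardiac_amp *
      (1 + 0.3 * sin(2 * pi * 0.05 * t + runif(1, 0, 2 * pi))) *
      sin(2 * pi * cfg$cardiac_freq * t + runif(1, 0, 2 * pi))
    hbo <- hbo_amp * (sites[[s]] + card)
    hbr <- hbr_ratio * hbo
    im <- forward_intensity_model(hbo, hbr, optics, baseline)
    if ((cfg$sensor_noise_sd %||% 0) > 0)
      im <- im + matrix(rnorm(length(im)), nrow(im)) *
        rep(cfg$sensor_noise_sd * baseline[c("660", "920")], each = nrow(im))
    add_motion_artifacts(im, fs, cfg$artifact_spec)
  })
  list(intensity = setNames(intensity, names(sites)),
       slfo_truth = sites, delays = delays)
}

# Default per-subject embolism distribution for stroke subjects: one
# carotid-territory path (an ear) is always affected, each limb site
# with probability 0.25; nominal delay 1-3 s, attenuation 0.5-0.85,
# distortion corner 0.04-0.08 Hz, severity 0.5-1.
default_embolism_sampler <- function() {
  affected <- c(sample(c("LE", "RE"), 1),
                c("LF", "RF", "LT", "RT")[runif(4) < 0.25])
  embolism_spec(affected_sites = affected,
                extra_delay = runif(1, 1, 3),
                attenuation = runif(1, 0.5, 0.85),
                distortion_corner = runif(1, 0.04, 0.08),
                severity = runif(1, 0.5, 1))
}

#' Simulate a healthy/stroke cohort and write it to disk
#'
#' Healthy subjects are drawn from the symmetric propagation model
#' (near-zero homologous delays, high homologous MCCC); stroke subjects
#' additionally receive a per-subject random [embolism_spec()] from
#' `embolism_sampler`. Output is fully deterministic given `seed`.
#'
#' @param n_healthy,n_stroke subject counts (>= 0).
#' @param out_dir output directory (created if needed); one recording
#'   file per subject plus `manifest.yaml`.
#' @param cfg a [vascular_config()].
#' @param embolism_sampler zero-argument function returning an
#'   [embolism_spec()]; default [default_embolism_sampler] behaviour.
#' @param duration recording length in seconds (default 600).
#' @param fs sampling rate in Hz.
#' @param optics an [optics_constants()] for the forward model.
#' @param hbo_amp Delta\[HbO\] amplitude in mol/L per unit source SD
#'   (default 1e-6, i.e. 1 uM).
#' @param seed integer seed.
#' @return the [cohort_manifest()] (invisibly written to
#'   `out_dir/manifest.yaml`).
#' @export
simulate_cohort <- function(n_healthy, n_stroke, out_dir,
                            cfg = vascular_config(),
                            embolism_sampler = NULL,
                            duration = 600, fs = 31.25,
                            optics = optics_constants(),
                            hbo_amp = 1e-6, seed = 1) {
  if (n_healthy < 0 || n_stroke < 0) stop_param("counts must be >= 0")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sampler <- embolism_sampler %||% default_embolism_sampler
  groups <- c(rep("healthy", n_healthy), rep("stroke", n_stroke))
  entries <- with_seed(seed, {
    lapply(seq_along(groups), function(k) {
      grp <- groups[k]
      id <- sprintf("S%03d", k)
      emb <- if (grp == "stroke") sampler() else NULL
      sig <- simulate_subject_signals(cfg, emb, duration = duration, fs = fs,
                                      optics = optics, hbo_amp = hbo_amp)
      rec <- raw_recording(subject_id = id, group_label = grp, fs = fs,
                           intensity = sig$intensity)
      fname <- paste0(id, ".csv")
      write_recording(rec, file.path(out_dir, fname))
      list(subject_id = id, group = grp, file = fname)
    })
  })
  man <- cohort_manifest(
    do.call(rbind.data.frame, c(entries, stringsAsFactors = FALSE)),
    metadata = list(n_healthy = n_healthy, n_stroke = n_stroke,
                    duration = duration, fs = fs, seed = seed,
                    generator = "slfomark::simulate_cohort"))
  write_manifest(man, file.path(out_dir, "manifest.yaml"))
  # re-read so entry paths are resolved like any other manifest
  read_manifest(file.path(out_dir, "manifest.yaml"))
}
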