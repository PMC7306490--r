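# Shared fixtures. The full-size cohort is simulated once per test run
# and cached, since several test files exercise different aspects of
# the same end-to-end analysis.

.fixtures <- new.env(parent = emptyenv())

# Small helper: a raw_recording with smooth positive traces.
make_recording <- function(n = 200, fs = 31.25, sites = SLFO_SITES,
                           subject = "S001", group = "healthy") {
  t <- (seq_len(n) - 1) / fs
  intensity <- setNames(lapply(seq_along(sites), function(i) {
    m <- cbind(1000 + 5 * sin(2 * pi * 0.05 * t + i),
               800 + 4 * cos(2 * pi * 0.07 * t + i))
    colnames(m) <- c("660", "920")
    m
  }), sites)
  raw_recording(subject, group, fs = fs, intensity = intensity)
}

# Default-model cohort, 25 healthy vs 25 stroke, 600-s recordings,
# analyzed with the default pipeline. Simulated and analyzed once.
cohort_fixture <- function() {
  if (!is.null(.fixtures$cohort)) return(.fixtures$cohort)
  dir <- file.path(tempdir(), "slfomark_cohort")
  man <- simulate_cohort(25, 25, dir, seed = 777)
  res <- run_analyze(pipeline_config(), man)
  .fixtures$cohort <- list(manifest = man, analysis = res, dir = dir)
  .fixtures$cohort
}

# Small cohort whose embolism affects only the LE path, for the
# targeted comparison (LE-RE degraded, LT-RT untouched).
le_cohort_fixture <- function() {
  if (!is.null(.fixtures$le_cohort)) return(.fixtures$le_cohort)
  dir <- file.path(tempdir(), "slfomark_le_cohort")
  sampler <- function() {
    embolism_spec("LE", extra_delay = runif(1, 1, 3),
                  attenuation = runif(1, 0.5, 0.85),
                  distortion_corner = runif(1, 0.04, 0.08),
                  severity = runif(1, 0.5, 1))
  }
  man <- simulate_cohort(25, 25, dir, embolism_sampler = sampler, seed = 314)
  res <- run_analyze(pipeline_config(), man)
  .fixtures$le_cohort <- list(manifest = man, analysis = res, dir = dir)
  .fixtures$le_cohort
}
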