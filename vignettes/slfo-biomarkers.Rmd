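---
title: "Peripheral sLFO biomarkers: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peripheral sLFO biomarkers: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The signal and the biomarkers

Systemic low-frequency oscillations (sLFOs) are blood-borne hemodynamic
fluctuations in the 0.01–0.15 Hz band. They originate centrally, travel
with the bloodstream, and arrive at peripheral sites in the order of
their vascular path lengths: earlobes first, then fingertips, then
toes. In a healthy circulation the left and right members of a
homologous site pair (LE–RE, LF–RF, LT–RT) receive nearly identical
copies of the signal with near-zero mutual delay; a vascular lesion on
one path perturbs that symmetry — it delays, attenuates and distorts
the transmitted waveform.

`slfomark` turns this into two windowed biomarkers per site pair:

* **MCCC** — the maximum of the normalized cross-correlation over lags
  |τ| ≤ 20 s. The ±20 s search range covers the span of human global
  circulation times (about 10–18 s).
* **Time delay** — the argmax lag, in seconds. The sign convention is
  that `delay > 0` for pair (A, B) means A's signal arrives later
  than B's.

sLFOs are aperiodic and inharmonic, so they carry no phase, only a
transit delay: the cross-correlation peak is well defined even where a
phase spectrum would not be.

## From raw intensities to sLFOs

Each site is recorded at 660 and 920 nm at 31.25 Hz. The chain is:

1. **Modified Beer–Lambert conversion.** ΔOD(λ, t) = −log10(I(λ, t)/I0(λ))
   with I0 the *temporal geometric mean* of the intensity, i.e. the
   mean of log10 I. The 2×2 extinction system is then solved per
   sample for Δ[HbO], Δ[HbR]. DPFs default to 6.51 (660 nm) and 5.86
   (920 nm). Using the geometric rather than arithmetic mean for I0
   makes the conversion exactly linear in log-intensity, gives both
   concentration series exactly zero mean, and makes the forward
   model/conversion pair invertible to machine precision; with an
   arithmetic-mean reference the round trip is only approximate
   (relative error of order the squared OD amplitude, ~1e-3 at
   physiological modulation depths). Extinction coefficients are not
   part of the acquisition standard, so they are explicit fields of
   `optics_constants()`, defaulting to the widely used compiled
   hemoglobin tabulation (Gratzer/Prahl), with the 920 nm entry
   interpolated between its 900 and 940 nm rows. With
   `separation = 1` the outputs are distance-scaled concentration
   changes; every downstream analysis (correlation, delay, spectral
   shape) is invariant to that scale.
2. **Spike correction.** Sudden movements produce isolated intensity
   jumps. Samples whose first difference exceeds 5 robust SDs
   (MAD × 1.4826) are masked with a 3-sample guard and replaced by a
   natural cubic spline through the unmasked data. On spike-free
   signals the mask is empty and the step is an exact no-op.
3. **Kurtosis-based wavelet filtering.** Quivers (tremor bursts,
   roughly 2–8 Hz) spread over too many samples for spline repair but
   concentrate into few large wavelet coefficients. The signal is
   decomposed by an orthonormal Daubechies-4 (4-tap) pyramid,
   implemented in the package since no wavelet library ships with this
   R stack; levels whose coefficient kurtosis is incompatible with
   Gaussianity are hard-thresholded at the universal level
   σ√(2 ln N). Three numerical choices matter here:
   * **Depth 6, not deeper.** At 31.25 Hz, six levels leave the
     0–0.244 Hz approximation untouched, so the whole sLFO band passes
     through; a seventh or eighth detail level would reach into
     0.06–0.12 Hz and thresholding it destroys genuine sLFO content
     (~30 % RMS on clean data in our checks).
   * **Sampling-error allowance.** Sample kurtosis of a Gaussian level
     with n coefficients has SD ≈ √(24/n); coarse levels have few
     dozen coefficients, so a fixed cut at 3.3 would fire on perfectly
     clean data roughly a quarter of the time. The working cut is
     `k_thresh + 3√(24/n_eff)`.
   * **Mirror extension.** The pyramid is periodized; without making
     the sequence continuous across the circular wrap, the x[n] → x[1]
     jump masquerades as a large coefficient at every scale. The
     input is therefore reflected in full before the transform.
4. **Zero-phase band-pass, 0.01–0.15 Hz.** Butterworth order 4,
   applied forward–backward so the net phase is identically zero —
   non-negotiable, since the delay *is* the biomarker. At these
   normalized frequencies (6×10⁻⁴ of Nyquist) direct polynomial filter
   realizations fail — an order-4 band-pass is numerically unstable
   outright, and even the high-pass stage amplifies round-off by
   ~10¹⁴ — so the package designs the filter analytically (prototype
   poles, pre-warping, bilinear transform) and applies it as a cascade
   of second-order sections, with demeaning and odd-reflection padding
   of 1.5 filter time constants against edge transients.

Artifact correction defaults to operating on the concentration series
(after the Beer–Lambert step, mirroring the narrative order of the
processing standard); `artifact_domain = "intensity"` applies it to
raw intensities first for sensitivity analyses. Provenance of every
step is recorded in the output object.

Analyses use Δ[HbO]; Δ[HbR] is processed identically and carried
along, but its lower SNR keeps it out of the headline metrics.

## Windowing and the significance threshold

Recordings are split into 300-s windows advanced by 30 s (a 600-s
record gives 11 windows, a 480-s record 7). Windowed estimates give a
stability measure for the delay: the across-window median is the
per-subject summary (the mean is available by option), and the
variance of |delay| over significant windows quantifies delay
stability.

Band limiting plus maximization over lags inflates correlation between
unrelated signals, so a window's delay only counts when its MCCC
clears a null-calibrated threshold. `null_mccc_threshold()` simulates
independent Gaussian pairs low-passed below 0.1 Hz (the calibration
convention), applies the exact pipeline lag search, and returns the
95 % quantile. Two details are easy to get wrong:

* The null series must be drawn in **steady state** (filter a longer
  run, discard a 60-s burn-in at each end). Reflect-padding raw white
  noise instead pins the filtered series to its raw high-variance edge
  samples and inflates the quantile by ~50 %.
* The critical value scales like 1/√duration. At the 300-s window
  length used here the 95 % value is ≈ 0.34 (10 000 pairs); at 480 s
  it is ≈ 0.27 and at 600 s ≈ 0.25 (`analysis/05_null_calibration.R`
  computes this table). The pipeline's working threshold of 0.3 is
  the conventional round value adopted in this literature, which was
  derived from a reported critical value of 0.28; our own 300-s
  calibration places the 95 % point somewhat higher, so 0.3 should be
  read as an approximate, slightly permissive gate at the window
  length used here.

## Spectral characterization

`compute_psd()` is a one-sided Welch estimate: 100-s Hann segments
with 50 % overlap give ≥ 3 segments per 300-s window and a 0.01-Hz
grid that matches the lower band edge; in-band power agrees with the
band-limited variance to within 5 % (Parseval check in the tests).
`spectral_width()` reports the frequency below which 95 % (by default;
exposed) of the in-band power lies — a scalar for the observation that
earlobe sLFOs occupy roughly 0–0.1 Hz while finger and toe sLFOs
concentrate below ~0.08 Hz. The published comparisons are qualitative,
so the power fraction is a configuration choice, not a claim.

## Group statistics and clustering

Per-pair MCCC and delay summaries are compared between groups with the
two-sided Wilcoxon rank-sum test (exact enumeration for tie-free
samples with min(n) ≤ 8, midrank normal approximation with tie
correction otherwise; the groups are independent cohorts, so the
independent-samples test is the right one even though the source
material's figure caption says "paired-sample"). Each 11-comparison
family (one per metric type) is corrected by Benjamini–Hochberg.
`bh_adjust()` has two dialects: textbook step-up (`p.adjust`-style,
with the cumulative-minimum pass), and a reproduction dialect that
reports raw p·m/rank without monotonization — the published
multiple-comparison table in this literature is internally consistent
only with the latter (a later-ranked value can be printed smaller
than an earlier-ranked one), so the reproduction dialect is the
default and the textbook form the alternative.

Fuzzy c-means minimizes J_f = Σ_j Σ_i μ_j(x_i)^b ‖x_i − m_j‖² under
Σ_j μ_j(x_i) = 1, alternating the two stationarity updates until the
largest membership change drops below ε = 1e-5 (cap 300 iterations,
10 restarts, best final J_f kept, b = 2). Centers are initialized at
k distinct randomly chosen data points: initializing a random
membership matrix instead places every initial center at the global
mean — the symmetric saddle of J_f — where the membership-change
criterion stops the iteration immediately; center initialization is
also what the algorithm's standard description prescribes. Coincident
point/center cases take the zero-distance limit (full membership).
With n = 50-ish subjects, supervised classifiers would be data-starved,
which is the case for unsupervised clustering here.

Two feature sets are clustered separately, mirroring the study design:
the LE–RE MCCC summary, and the four finger–toe delay summaries
(which of the four F–T delays enter, and whether features are
standardized, is configurable; defaults use all four, unstandardized).
The stroke-like cluster is identified purely from center geometry
(lower MCCC / larger delay), keeping labels out of the fit; the
membership in that cluster is the ROC score. AUC uses the
Mann–Whitney identity with half credit for ties. Subjects lacking a
delay summary (no significant window for that pair) are dropped from
the affected feature set only, with the count reported.

## What the synthetic cohort does and does not emulate

The generator exists so that every stage is testable without patient
data. It emulates: a common aperiodic band-limited source (stationary
Gaussian noise, zero-phase filtered to 0.01–0.15 Hz, drawn in steady
state); site arrival order and near-symmetric homologous delays
(0.8/1.6/2.4 s with 0.15-s left/right jitter); site-local in-band
noise whose default SD (0.55 of the source SD) puts healthy LE–RE
MCCC near the reference healthy level of 0.78; embolism-like path
perturbations (delay + attenuation + low-pass distortion, scaled by a
severity in [0, 1]); a 1.1-Hz amplitude-modulated cardiac tone (which
doubles as a band-pass rejection check); a broadband sensor-noise
floor (10⁻⁴ of baseline intensity — real photodetectors have one, and
its absence makes wavelet detail scales of a purely band-limited
signal numerically degenerate); and the two motion-artifact classes,
spikes (1–3 samples, 5–15 fluctuation SDs) and quivers (2–8 Hz bursts
of 1–5 s).

It does **not** model pulse-wave propagation or Windkessel dynamics,
respiration or CO₂ reactivity, oxygen saturation, site-specific tissue
optics, or any population distribution of stroke lesions (the
published per-patient delays are single values; the stroke samplers
here are documented assumptions). Passing tests therefore demonstrate
that the machinery recovers known structure under this model — not
that the clinical effect sizes would reproduce on real recordings.
Delays are realized by linear interpolation on the native 31.25-Hz
grid; with delays of interest 0.1–5 s against a 32-ms sample period,
interpolation error is irrelevant, and delay estimation works on
integer-sample lags without resampling.

## Problem sizes and reproducibility

The packaged analyses use 25 + 25 subjects at 600 s — the scale of the
study cohorts this design mirrors — and the null calibration uses
10 000 pairs (quantile reproducible to about ±0.005 across seeds);
the test suite exercises the same code at the same or reduced sizes.
All randomness flows from explicit integer seeds: identical
configuration and seed give byte-identical cohorts and reports.

## Known limitations

* The raw text format carries no missing-data convention; gaps must be
  handled before import.
* The MCCC normalization follows the common `xcorr`-style convention
  (demeaned, full-window energy in the denominator), which slightly
  shrinks values at large lags relative to per-overlap Pearson
  normalization.
* The null-threshold calibration depends on the assumed record length
  and filter; both are arguments, and the packaged default states its
  choice (300 s, order-4 zero-phase low-pass below 0.1 Hz).
* Δ[HbR]-based metrics are computed but not analyzed further.
* The clustering decision boundaries are reported in feature space;
  no attempt is made to reproduce published boundary-line equations
  whose axes are not defined.
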