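# Zero-phase Butterworth filtering for sLFO extraction.
#
# The analysis band (0.01-0.15 Hz at fs = 31.25 Hz) sits at normalized
# frequencies of 6.4e-4 to 9.6e-3, where polynomial (direct-form)
# filter realizations fall apart: a single order-4 band-pass is
# outright unstable (poles cluster at z = 1 and the 8th-order
# coefficients lose all precision), and even an order-4 high-pass
# amplifies round-off by ~1e14. The filters here are therefore designed
# analytically -- Butterworth prototype pole pairs, frequency
# pre-warping, bilinear transform -- and applied as a cascade of
# second-order sections (biquads), the standard numerically robust
# realization. The band-pass is an order-`order` high-pass cascade
# followed by an order-`order` low-pass cascade, each applied
# forward-backward for zero phase.

# Biquad cascade for an order-`order` (even) Butterworth low- or
# high-pass with cutoff fc at sampling rate fs. Each analog prototype
# pole pair s^2 + 2 sin(theta) s + 1 is frequency-scaled (pre-warped)
# and mapped by the bilinear transform.
butter_sos <- function(order, fc, fs, type = c("low", "high")) {
  type <- match.arg(type)
  stopifnot(order %% 2 == 0, fc > 0, fc < fs / 2)
  wc <- 2 * fs * tan(pi * fc / fs)
  K <- 2 * fs
  lapply(pi * (2 * seq_len(order / 2) - 1) / (2 * order), function(theta) {
    a <- c(1 / wc^2, 2 * sin(theta) / wc, 1)
    b <- if (type == "low") c(0, 0, 1) else c(1 / wc^2, 0, 0)
    B <- c(b[1] * K^2 + b[2] * K + b[3], -2 * b[1] * K^2 + 2 * b[3],
           b[1] * K^2 - b[2] * K + b[3])
    A <- c(a[1] * K^2 + a[2] * K + a[3], -2 * a[1] * K^2 + 2 * a[3],
           a[1] * K^2 - a[2] * K + a[3])
    list(b = B / A[1], a = A / A[1])
  })
}

apply_sos <- function(sos, x) {
  for (s in sos) x <- as.numeric(signal::filter(s$b, s$a, x))
  x
}

# Odd (point-symmetric) reflection about both end samples; standard
# edge-transient suppression for forward-backward IIR filtering.
reflect_pad <- function(x, n_pad) {
  n <- length(x)
  n_pad <- min(n - 1L, n_pad)
  pre <- 2 * x[1L] - x[seq(n_pad + 1L, 2L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - n_pad)]
  list(x = c(pre, x, post), n_pad = n_pad)
}

# Zero-phase (forward-backward) application of a biquad cascade with
# reflective padding.
filtfilt_pad <- function(sos, x, n_pad) {
  p <- reflect_pad(x, n_pad)
  y <- apply_sos(sos, p$x)
  y <- rev(apply_sos(sos, rev(y)))
  y[seq(p$n_pad + 1L, p$n_pad + length(x))]
}

#' Zero-phase band-pass filter for sLFO extraction
#'
#' Extracts the systemic low-frequency oscillation band from a time
#' series with a zero-phase Butterworth filter: an order-`order`
#' high-pass at `band[1]` cascaded with an order-`order` low-pass at
#' `band[2]`, each applied forward and backward (`signal::filtfilt`)
#' so the net phase response is identically zero and time delays between
#' channels are not distorted. The input is demeaned and padded by odd
#' reflection (1.5 filter time constants, `1.5 * fs / band[1]` samples)
#' before filtering to suppress edge transients.
#'
#' @param x numeric series.
#' @param fs sampling rate in Hz.
#' @param band two-element numeric, pass band in Hz (default
#'   `c(0.01, 0.15)`, the sLFO analysis band). `band[1] = 0` gives a
#'   pure low-pass.
#' @param order Butterworth order of each cascade stage (default 4; the
#'   forward-backward pass doubles the effective order).
#' @return filtered series, same length as `x`, mean approximately 0.
#' @examples
#' fs <- 31.25
#' t <- seq(0, 60 - 1 / fs, by = 1 / fs)
#' y <- bandpass_slfo(sin(2 * pi * 0.08 * t) + 5, fs)
#' @export
bandpass_slfo <- function(x, fs, band = c(0.01, 0.15), order = 4) {
  check_series(x, "x", min_len = 12L)
  if (!is.numeric(band) || length(band) != 2L || band[1] < 0 ||
      band[2] <= band[1] || band[2] >= fs / 2)
    stop_param("band must satisfy 0 <= band[1] < band[2] < fs/2 = %g", fs / 2)
  x0 <- x - mean(x)
  f_ref <- if (band[1] > 0) band[1] else band[2]
  n_pad <- ceiling(1.5 * fs / f_ref)
  if (band[1] > 0)
    x0 <- filtfilt_pad(butter_sos(order, band[1], fs, "high"), x0, n_pad)
  filtfilt_pad(butter_sos(order, band[2], fs, "low"), x0, n_pad)
}

#' Zero-phase low-pass filter
#'
#' Order-`order` Butterworth low-pass applied forward-backward with
#' reflective padding. Used for the path-distortion model of the
#' synthetic generator and for the null-threshold calibration, which
#' follows the "< 0.1 Hz" convention.
#'
#' @inheritParams bandpass_slfo
#' @param corner corner frequency in Hz.
#' @export
lowpass_zero_phase <- function(x, fs, corner, order = 4) {
  check_series(x, "x", min_len = 12L)
  if (corner <= 0 || corner >= fs / 2)
    stop_param("corner must lie in (0, fs/2)")
  filtfilt_pad(butter_sos(order, corner, fs, "low"), x,
               ceiling(1.5 * fs / corner))
}

# Stationary band-limited Gaussian noise. White noise is filtered with a
# burn-in of `burn_s` seconds at each end which is then discarded, so the
# retained segment is a steady-state draw from the filtered process (no
# edge transients and no coupling to raw edge samples). `band[1] = 0`
# gives low-passed noise.
band_limited_noise <- function(n, fs, band, order = 4, burn_s = 60) {
  n_burn <- round(burn_s * fs)
  w <- rnorm(n + 2L * n_burn)
  y <- if (band[1] > 0) {
    bandpass_slfo(w, fs, band = band, order = order)
  } else {
    lowpass_zero_phase(w, fs, corner = band[2], order = order)
  }
  y[seq(n_burn + 1L, n_burn + n)]
}
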