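## Small signal-processing primitives used by the generator and preprocessing.

#' Analytic signal via the frequency domain
#'
#' Returns `x + i * H(x)` where `H` is the Hilbert transform, computed by
#' zeroing negative frequencies of the FFT. Instantaneous phase is `Arg()` of
#' the result and the envelope is `Mod()`.
#'
#' @param x real numeric vector.
#' @return complex vector of the same length.
#' @keywords internal
analyticSignal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Power-law (1/f^alpha) background noise
#'
#' Spectrally shaped Gaussian noise: white noise whose Fourier amplitudes are
#' scaled by `f^(-alpha/2)`, normalised to a target RMS. The DC bin is zeroed.
#'
#' @param n number of samples.
#' @param alpha power-law exponent of the power spectrum (power ~ 1/f^alpha).
#' @param sRate sampling rate (Hz).
#' @param rms target root-mean-square amplitude.
#' @return numeric vector of length `n`.
#' @keywords internal
pinkNoise <- function(n, alpha = 1, sRate = 1000, rms = 1) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(0, seq_len(n - 1)) * sRate / n
  f[f > sRate / 2] <- sRate - f[f > sRate / 2]   # fold to physical frequency
  g <- c(0, f[-1]^(-alpha / 2))
  x <- Re(stats::fft(W * g, inverse = TRUE) / n)
  x * rms / stats::sd(x)
}

#' Band-limited Gaussian noise oscillator
#'
#' Narrowband-filtered white noise (4th-order Butterworth band-pass, applied
#' forward and backward), normalised to a target RMS. Used as the latent
#' oscillator of coupled channel pairs: its analytic phase is well defined
#' because the signal is narrowband.
#'
#' @param n samples; @param band `c(lo, hi)` Hz; @param sRate Hz; @param rms
#'   target RMS.
#' @return numeric vector.
#' @keywords internal
bandNoise <- function(n, band, sRate, rms = 1) {
  stopifnot(band[1] > 0, band[2] < sRate / 2, band[1] < band[2])
  bf <- signal::butter(4, band / (sRate / 2), type = "pass")
  pad <- min(n, 3L * ceiling(sRate / band[1]))
  x <- stats::rnorm(n + 2L * pad)
  y <- signal::filtfilt(bf, x)[(pad + 1L):(pad + n)]
  y * rms / stats::sd(y)
}

#' Gaussian smoothing kernel
#'
#' @param widthMs kernel width in ms; interpreted as full width at half maximum
#'   when `widthIs = "fwhm"` (the default) or as the standard deviation when
#'   `widthIs = "sd"`.
#' @param binMs bin width in ms.
#' @param widthIs convention for `widthMs`.
#' @return numeric kernel summing to 1, truncated at +/- 3 sd.
#' @keywords internal
gaussianKernel <- function(widthMs, binMs, widthIs = c("fwhm", "sd")) {
  widthIs <- match.arg(widthIs)
  sdMs <- if (widthIs == "fwhm") widthMs / (2 * sqrt(2 * log(2))) else widthMs
  sdBins <- sdMs / binMs
  half <- ceiling(3 * sdBins)
  k <- stats::dnorm(seq(-half, half), sd = sdBins)
  k / sum(k)
}

## Cosine on/off ramped epoch window on a time grid: 1 inside [t0, t1],
## 0 outside, 50 ms (default) raised-cosine ramps centred on the edges.
epochWindow <- function(tGrid, t0, t1, rampS = 0.05) {
  w <- numeric(length(tGrid))
  up <- tGrid >= (t0 - rampS / 2) & tGrid < (t0 + rampS / 2)
  on <- tGrid >= (t0 + rampS / 2) & tGrid <= (t1 - rampS / 2)
  dn <- tGrid > (t1 - rampS / 2) & tGrid <= (t1 + rampS / 2)
  w[on] <- 1
  w[up] <- 0.5 * (1 - cos(pi * (tGrid[up] - t0 + rampS / 2) / rampS))
  w[dn] <- 0.5 * (1 + cos(pi * (tGrid[dn] - t1 + rampS / 2) / rampS))
  w
}

## Column standard deviations without forming an intermediate matrix copy per
## column; x is a numeric matrix.
.colSds <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  sqrt(pmax(0, colSums(x^2) / n - mu^2) * n / (n - 1))
}

## Derive a 32-bit sub-seed from a master seed and stream labels, so each
## (channel, trial) pair owns an independent reproducible RNG stream.
.subSeed <- function(master, ...) {
  ids <- c(master, ...)
  s <- 0
  for (v in ids) s <- (s * 69069 + as.numeric(v) + 1) %% 2147483647
  as.integer(s)
}
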