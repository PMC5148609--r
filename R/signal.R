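## LFP preprocessing and Morlet wavelet decomposition.

#' Preprocess raw LFPs
#'
#' Zero-phase 10th-order Butterworth band-stop at 59-61 Hz (applied forward
#' and backward), anti-alias low-pass, decimation from 1 kHz to 333.33 Hz
#' (factor 3), and removal of the stimulus-evoked component by subtracting
#' each channel's cross-trial mean at every time sample. After evoked
#' removal the residuals have zero cross-trial mean by construction, which
#' isolates induced (non-phase-locked) oscillations.
#'
#' @param session a [SessionRecording-class] (or a channel x trial x sample
#'   array with attributes supplied via `time`/`sRate`).
#' @param notchBand band-stop edges in Hz.
#' @param notchOrder total band-stop filter order (even).
#' @param decimate integer decimation factor.
#' @param evokedRemoval subtract the cross-trial mean (requires >= 2 trials).
#' @param time,sRate required only when `session` is a bare array.
#' @return a [CleanLFP-class].
#' @export
preprocessLfp <- function(session, notchBand = c(59, 61), notchOrder = 10,
                          decimate = 3L, evokedRemoval = TRUE,
                          time = NULL, sRate = NULL) {
  if (is(session, "SessionRecording")) {
    x <- session@lfp; time <- session@time; sRate <- session@sRate
    channels <- session@channels; trials <- session@trials
  } else {
    x <- session
    if (is.null(time) || is.null(sRate))
      stop("time and sRate are required for array input")
    channels <- data.frame(id = seq_len(dim(x)[1]),
                           area = NA_character_)
    trials <- data.frame(trial = seq_len(dim(x)[2]))
  }
  nyq <- sRate / 2
  stopifnot(notchBand[1] > 0, notchBand[2] < nyq, notchOrder %% 2 == 0)
  nTrial <- dim(x)[2]
  if (evokedRemoval && nTrial < 2)
    stop("evoked removal requires at least 2 trials")
  bStop <- signal::butter(notchOrder / 2, notchBand / nyq, type = "stop")
  fsOut <- sRate / decimate
  bLow <- signal::butter(8, 0.8 * (fsOut / 2) / nyq, type = "low")
  keep <- seq(1, dim(x)[3], by = decimate)
  out <- array(0, dim = c(dim(x)[1], nTrial, length(keep)))
  for (ch in seq_len(dim(x)[1])) {
    for (tr in seq_len(nTrial)) {
      v <- signal::filtfilt(bStop, x[ch, tr, ])
      v <- signal::filtfilt(bLow, v)
      out[ch, tr, ] <- v[keep]
    }
    if (evokedRemoval) {
      mu <- colMeans(out[ch, , , drop = TRUE])
      out[ch, , ] <- sweep(out[ch, , , drop = TRUE], 2, mu)
    }
  }
  methods::new("CleanLFP", lfp = out, time = time[keep], sRate = fsOut,
               channels = channels, trials = trials)
}

#' The 61-bin log-spaced frequency grid
#'
#' Six octaves from 2 to 128 Hz at 0.1-octave resolution:
#' `f_k = 2 * 2^(0.1 k)`, k = 0..60.
#' @return numeric vector of 61 frequencies (Hz).
#' @export
morletFrequencyGrid <- function() 2 * 2^(0.1 * (0:60))

#' Morlet wavelet decomposition
#'
#' Complex wavelet coefficients by FFT convolution with the analytic Morlet
#' wavelet (nondimensional frequency `omega0`, Torrence-Compo normalisation).
#' Linear in the input. Bins inside the cone of influence of the record edges
#' (within the e-folding time `sqrt(2) * s(f)` of either edge) are flagged in
#' the `coi` slot but retained.
#'
#' @param clean a [CleanLFP-class], or a trial x sample matrix with `time` and
#'   `sRate` supplied.
#' @param freq frequencies to decompose (Hz); defaults to the full 61-bin
#'   grid. All must lie strictly below the Nyquist frequency.
#' @param omega0 Morlet nondimensional frequency (default 6).
#' @param channels channel ids to decompose (default all).
#' @param time,sRate required for matrix input.
#' @param timeRange optional `c(t0, t1)`: the transform is computed on the
#'   full record (so edges stay outside the window) and the coefficients are
#'   then restricted to this window.
#' @return a [SpectralDecomposition-class].
#' @export
morletTransform <- function(clean, freq = morletFrequencyGrid(), omega0 = 6,
                            channels = NULL, time = NULL, sRate = NULL,
                            timeRange = NULL) {
  if (is(clean, "CleanLFP")) {
    time <- clean@time; sRate <- clean@sRate
    chTab <- clean@channels; trials <- clean@trials
    if (is.null(channels)) channels <- seq_len(dim(clean@lfp)[1])
    getChan <- function(ch) clean@lfp[ch, , , drop = TRUE]
  } else {
    if (is.null(time) || is.null(sRate))
      stop("time and sRate are required for matrix input")
    if (is.null(dim(clean))) clean <- matrix(clean, nrow = 1)
    chTab <- data.frame(id = 1L, area = NA_character_)
    trials <- data.frame(trial = seq_len(nrow(clean)))
    channels <- 1L
    getChan <- function(ch) clean
  }
  if (any(freq >= sRate / 2))
    stop("requested frequency at or above Nyquist (", sRate / 2, " Hz)")
  if (is.unsorted(freq, strictly = TRUE)) stop("freq must be strictly increasing")

  n <- length(time)
  dt <- 1 / sRate
  nfft <- stats::nextn(n, 2)
  omegaK <- 2 * pi * c(0:(nfft / 2), -((nfft / 2 - 1):1)) / (nfft * dt)
  scale <- (omega0 + sqrt(2 + omega0^2)) / (4 * pi * freq)

  coefs <- vector("list", length(channels))
  names(coefs) <- as.character(channels)
  for (ci in seq_along(channels)) {
    X <- getChan(channels[ci])
    if (is.null(dim(X))) X <- matrix(X, nrow = 1)
    nTrial <- nrow(X)
    Xhat <- stats::mvfft(t(cbind(X, matrix(0, nTrial, nfft - n))))  # nfft x trials
    W <- array(0i, dim = c(nTrial, length(freq), n))
    for (k in seq_along(freq)) {
      s <- scale[k]
      psiHat <- sqrt(2 * pi * s / dt) * pi^(-1 / 4) *
        exp(-((s * omegaK - omega0)^2) / 2) * (omegaK > 0)
      Wk <- stats::mvfft(Xhat * psiHat, inverse = TRUE) / nfft  # nfft x trials
      W[, k, ] <- t(Wk[seq_len(n), , drop = FALSE])
    }
    coefs[[ci]] <- W
  }

  ## cone of influence: e-folding time sqrt(2)*s from either record edge
  efold <- sqrt(2) * scale
  tl <- time - time[1]
  tr <- time[n] - time
  coi <- outer(efold, tl, function(e, d) d < e) |
    outer(efold, tr, function(e, d) d < e)

  if (!is.null(timeRange)) {
    sel <- time >= timeRange[1] & time <= timeRange[2]
    coefs <- lapply(coefs, function(W) W[, , sel, drop = FALSE])
    coi <- coi[, sel, drop = FALSE]
    time <- time[sel]
  }

  methods::new("SpectralDecomposition", coef = coefs, freq = freq, time = time,
               sRate = sRate, omega0 = omega0, coi = coi,
               channels = chTab, trials = trials)
}

#' 1/f-normalized time-frequency power
#'
#' Power at (f, t) is the across-trial mean of `|W|^2`, multiplied by
#' `f / fRef` to correct the power-law decay of the LFP spectrum.
#'
#' @param decomposition a [SpectralDecomposition-class].
#' @param trials trial indices to average (default all); must be non-empty.
#' @param normalize multiply power by `f / fRef` (disable to inspect raw
#'   wavelet power).
#' @param fRef reference frequency (Hz).
#' @return named list of numeric matrices (frequency x time), one per channel.
#' @export
normalizedPower <- function(decomposition, trials = NULL, normalize = TRUE,
                            fRef = 1) {
  stopifnot(is(decomposition, "SpectralDecomposition"))
  lapply(decomposition@coef, function(W) {
    nTrial <- dim(W)[1]
    idx <- if (is.null(trials)) seq_len(nTrial) else trials
    if (!length(idx)) stop("empty trial subset")
    P <- apply(Mod(W[idx, , , drop = FALSE])^2, c(2, 3), mean)
    if (normalize) P <- P * (decomposition@freq / fRef)
    dimnames(P) <- NULL
    P
  })
}

#' Band- and epoch-averaged power
#'
#' Averages a power map over a named frequency band and epoch window,
#' excluding cone-of-influence bins at frequencies below 4 Hz (where the cone
#' is widest).
#'
#' @param powerMap frequency x time matrix from [normalizedPower()].
#' @param decomposition the decomposition that produced it (for grids/coi).
#' @param band "beta" or "delta"; @param epoch "category", "shift",
#'   "fixation" or "baseline".
#' @param timeline event times for epoch lookup.
#' @return scalar mean power.
#' @export
epochBandPower <- function(powerMap, decomposition, band, epoch,
                           timeline = defaultTimeline()) {
  bl <- bandLimits(band)
  win <- epochWindowFor(epoch, timeline)
  fSel <- decomposition@freq >= bl[1] & decomposition@freq <= bl[2]
  tSel <- decomposition@time >= win[1] & decomposition@time <= win[2]
  sub <- powerMap[fSel, tSel, drop = FALSE]
  coi <- decomposition@coi[fSel, tSel, drop = FALSE]
  lowF <- decomposition@freq[fSel] < 4
  sub[lowF & coi] <- NA
  mean(sub, na.rm = TRUE)
}
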