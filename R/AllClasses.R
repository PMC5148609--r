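## S4 classes for the pipeline's central data objects.

#' TaskGeometry: spatial layout of the category-matching task
#'
#' Holds the sample grid (base positions plus discrete per-axis jitter), the
#' test-stimulus grid, the magnitude of the clockwise/counter-clockwise
#' boundary shift and the fixation window radius. All coordinates are degrees
#' of visual angle, x positive rightward, y positive upward, origin at
#' fixation.
#'
#' @slot basePositions numeric matrix (n x 2) of base sample positions.
#' @slot jitterLevels numeric vector of per-axis jitter offsets (degrees);
#'   odd length, symmetric about 0.
#' @slot testPositions numeric matrix (m x 2) of test locations.
#' @slot shiftMagnitude boundary shift in degrees (each hemi-boundary moves by
#'   this amount, in opposite directions on the two sides).
#' @slot fixationRadius radius of the fixation window (degrees).
#' @export
setClass("TaskGeometry", representation(
  basePositions = "matrix",
  jitterLevels = "numeric",
  testPositions = "matrix",
  shiftMagnitude = "numeric",
  fixationRadius = "numeric"
))

setValidity("TaskGeometry", function(object) {
  b <- object@basePositions
  j <- object@jitterLevels
  msg <- character(0)
  if (ncol(b) != 2) msg <- c(msg, "basePositions must have 2 columns (x, y)")
  if (any(b[, 1] == 0) || any(b[, 2] == 0))
    msg <- c(msg, "base sample positions must not lie on a meridian")
  if (any(sqrt(rowSums(b^2)) <= object@fixationRadius))
    msg <- c(msg, "base sample positions must lie outside the fixation window")
  if (anyDuplicated(b)) msg <- c(msg, "base positions must be distinct")
  ## mirror symmetry across both meridians
  key <- function(m) paste(round(m[, 1], 9), round(m[, 2], 9))
  if (!setequal(key(b), key(cbind(-b[, 1], b[, 2]))) ||
      !setequal(key(b), key(cbind(b[, 1], -b[, 2]))))
    msg <- c(msg, "base grid must be mirror-symmetric across both meridians")
  if (length(j) < 1 || length(j) %% 2 == 0)
    msg <- c(msg, "jitterLevels must have odd length")
  if (!isTRUE(all.equal(sort(j), sort(-j))))
    msg <- c(msg, "jitterLevels must be symmetric about 0")
  if (ncol(object@testPositions) != 2)
    msg <- c(msg, "testPositions must have 2 columns")
  if (length(object@shiftMagnitude) != 1 || object@shiftMagnitude <= 0)
    msg <- c(msg, "shiftMagnitude must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' GeneratorConfig: parameters of the synthetic-session generator
#'
#' @slot nChannels named integer vector of channel counts per area
#'   (names among AIP, cPFC, lPFC).
#' @slot nTrials number of trials.
#' @slot timeline named numeric vector of event times (s) relative to sample
#'   onset: baselineStart, fixOn, gapOn, sampleOn, sampleOff, shiftOn, testOn,
#'   end. Strictly increasing except that `end` may coincide with `testOn`.
#' @slot sRate LFP sampling rate (Hz).
#' @slot pinkExponent exponent alpha of the 1/f^alpha LFP background.
#' @slot noiseRms RMS of the background noise (mV).
#' @slot lineNoiseAmplitude amplitude of the 60 Hz line component (mV).
#' @slot evokedAmplitude amplitude of the stimulus-locked evoked transient
#'   added at sample onset and boundary shift (mV); identical across trials.
#' @slot couplingSpec data.frame with columns chanA, chanB, band
#'   ("beta"/"delta"), epoch ("category"/"shift"/"fixation"), kappaAbove,
#'   kappaBelow, amplitude (mV RMS of the oscillator).
#' @slot spikeSpec data.frame with columns electrode, nUnits, rate (Hz per
#'   unit), gainAbove, gainBelow, modDepth, prefPhase, targetChannel,
#'   targetBand.
#' @slot lapseRate probability that the behavioral agent's Go/No-go response
#'   is a lapse (response flipped).
#' @slot seed master RNG seed.
#' @export
setClass("GeneratorConfig", representation(
  nChannels = "integer",
  nTrials = "integer",
  timeline = "numeric",
  sRate = "numeric",
  pinkExponent = "numeric",
  noiseRms = "numeric",
  lineNoiseAmplitude = "numeric",
  evokedAmplitude = "numeric",
  couplingSpec = "data.frame",
  spikeSpec = "data.frame",
  lapseRate = "numeric",
  seed = "integer"
))

setValidity("GeneratorConfig", function(object) {
  msg <- character(0)
  tl <- object@timeline
  need <- c("baselineStart", "fixOn", "gapOn", "sampleOn", "sampleOff",
            "shiftOn", "testOn", "end")
  if (!all(need %in% names(tl))) {
    msg <- c(msg, "timeline must name all trial events")
  } else {
    ev <- tl[c("baselineStart", "fixOn", "gapOn", "sampleOn", "sampleOff",
               "shiftOn", "testOn")]
    if (any(diff(ev) <= 0)) msg <- c(msg, "timeline markers must be strictly increasing")
    if (tl["end"] < tl["testOn"]) msg <- c(msg, "recording must extend to the test display")
  }
  cs <- object@couplingSpec
  if (nrow(cs)) {
    if (any(cs$kappaAbove < 0) || any(cs$kappaBelow < 0))
      msg <- c(msg, "von Mises concentrations must be >= 0")
    nc <- sum(object@nChannels)
    if (any(cs$chanA > nc) || any(cs$chanB > nc) || any(cs$chanA < 1) || any(cs$chanB < 1))
      msg <- c(msg, "couplingSpec references an unknown channel")
    if (!all(cs$band %in% c("beta", "delta")))
      msg <- c(msg, "couplingSpec band must be 'beta' or 'delta'")
    if (!all(cs$epoch %in% c("category", "shift", "fixation")))
      msg <- c(msg, "couplingSpec epoch must be 'category', 'shift' or 'fixation'")
  }
  ss <- object@spikeSpec
  if (nrow(ss)) {
    if (any(ss$rate <= 0)) msg <- c(msg, "baseline spike rates must be > 0")
    if (any(ss$modDepth < 0 | ss$modDepth >= 1))
      msg <- c(msg, "phase modulation depth must lie in [0, 1)")
    if (any(ss$gainAbove <= 0) || any(ss$gainBelow <= 0))
      msg <- c(msg, "category gains must be > 0")
    nc <- sum(object@nChannels)
    if (any(ss$targetChannel > nc | ss$targetChannel < 1))
      msg <- c(msg, "spikeSpec references an unknown target channel")
  }
  if (object@lapseRate < 0 || object@lapseRate >= 1)
    msg <- c(msg, "lapseRate must lie in [0, 1)")
  if (object@sRate <= 0) msg <- c(msg, "sRate must be positive")
  if (length(msg)) msg else TRUE
})

#' SessionRecording: one simulated recording day
#'
#' @slot lfp numeric array channel x trial x sample (mV).
#' @slot time numeric vector of sample times (s) relative to sample onset.
#' @slot sRate sampling rate (Hz).
#' @slot spikes data.frame (electrode, unit, trial, time) of spike times (s).
#' @slot channels data.frame (id, area).
#' @slot trials data.frame, one row per trial (labels, locations, response,
#'   correctness).
#' @slot groundTruth the [GeneratorConfig-class] that produced the session.
#' @export
setClass("SessionRecording", representation(
  lfp = "array",
  time = "numeric",
  sRate = "numeric",
  spikes = "data.frame",
  channels = "data.frame",
  trials = "data.frame",
  groundTruth = "GeneratorConfig"
))

setValidity("SessionRecording", function(object) {
  msg <- character(0)
  d <- dim(object@lfp)
  if (length(d) != 3) msg <- c(msg, "lfp must be a 3-D array (channel x trial x sample)")
  if (!all(is.finite(object@lfp))) msg <- c(msg, "LFP must be finite everywhere")
  if (length(d) == 3 && d[3] != length(object@time))
    msg <- c(msg, "lfp sample dimension must match the time grid")
  if (nrow(object@spikes)) {
    rng <- range(object@time)
    if (any(object@spikes$time < rng[1] | object@spikes$time > rng[2]))
      msg <- c(msg, "all spike times must fall inside the trial window")
  }
  if (length(d) == 3 && nrow(object@channels) != d[1])
    msg <- c(msg, "channels table must match the lfp channel dimension")
  if (length(msg)) msg else TRUE
})

#' CleanLFP: preprocessed (notched, decimated, evoked-removed) LFP
#'
#' @slot lfp numeric array channel x trial x sample at the decimated rate.
#' @slot time numeric vector (s).
#' @slot sRate decimated sampling rate (Hz).
#' @slot channels,trials carried over from the session.
#' @export
setClass("CleanLFP", representation(
  lfp = "array",
  time = "numeric",
  sRate = "numeric",
  channels = "data.frame",
  trials = "data.frame"
))

#' SpectralDecomposition: complex Morlet wavelet coefficients
#'
#' Coefficients W(channel, trial, frequency, time) on a log-spaced frequency
#' grid, stored as one complex array (trial x frequency x time) per channel.
#'
#' @slot coef named list, one complex array per decomposed channel.
#' @slot freq frequency grid (Hz), strictly increasing.
#' @slot time time grid (s).
#' @slot sRate sampling rate of the time grid (Hz).
#' @slot omega0 Morlet nondimensional frequency.
#' @slot coi logical matrix (frequency x time); TRUE where a bin lies inside
#'   the cone of influence of the record edges.
#' @slot channels,trials carried over from the session.
#' @export
setClass("SpectralDecomposition", representation(
  coef = "list",
  freq = "numeric",
  time = "numeric",
  sRate = "numeric",
  omega0 = "numeric",
  coi = "matrix",
  channels = "data.frame",
  trials = "data.frame"
))

setValidity("SpectralDecomposition", function(object) {
  msg <- character(0)
  if (is.unsorted(object@freq, strictly = TRUE))
    msg <- c(msg, "freq grid must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' PPCMap: time-frequency pairwise phase consistency of a channel pair
#'
#' @slot chanA,chanB channel ids.
#' @slot areaPair area pair class, e.g. "AIP-cPFC".
#' @slot ppcRaw,ppcCorrected numeric matrices (frequency x time).
#' @slot freq,time grids.
#' @slot nTrials trials used; @slot nSurrogates surrogate shuffles used for
#'   the bias correction (0 if uncorrected).
#' @export
setClass("PPCMap", representation(
  chanA = "integer", chanB = "integer", areaPair = "character",
  ppcRaw = "matrix", ppcCorrected = "matrix",
  freq = "numeric", time = "numeric",
  nTrials = "integer", nSurrogates = "integer"
))

setValidity("PPCMap", function(object) {
  msg <- character(0)
  if (any(object@ppcRaw > 1 + 1e-9 | object@ppcRaw < -1 - 1e-9, na.rm = TRUE))
    msg <- c(msg, "raw PPC must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' SelectivityZMap: permutation z-scores of category-selective synchrony
#'
#' @slot D absolute PPC difference between the two categories (freq x time).
#' @slot z permutation z-scores; @slot p one-sided permutation p-values
#'   (rank-based).
#' @slot nPerm number of label permutations.
#' @slot dimension "AboveBelow" or "RightLeft".
#' @slot clusterMask logical matrix of bins surviving the cluster rule.
#' @slot flagged logical matrix of bins where the permutation spread was zero
#'   (z undefined there).
#' @slot freq,time grids; @slot chanA,chanB,areaPair pair identity.
#' @export
setClass("SelectivityZMap", representation(
  D = "matrix", z = "matrix", p = "matrix",
  nPerm = "integer", dimension = "character",
  clusterMask = "matrix", flagged = "matrix",
  freq = "numeric", time = "numeric",
  chanA = "integer", chanB = "integer", areaPair = "character"
))

#' RateSeries: binned, smoothed, baseline z-scored firing rates
#'
#' @slot id unit or electrode label.
#' @slot rate numeric matrix (trial x bin), spikes/s.
#' @slot zRate matrix of baseline z-scored rates.
#' @slot binCenters bin centre times (s); @slot binMs bin width (ms).
#' @slot kernel descriptor of the smoothing kernel.
#' @export
setClass("RateSeries", representation(
  id = "character",
  rate = "matrix", zRate = "matrix",
  binCenters = "numeric", binMs = "numeric",
  kernel = "character"
))

#' PLVSpectrum: spike-field phase locking of one directed pair
#'
#' @slot spikeElectrode,lfpChannel electrode ids; @slot direction label such
#'   as "cPFC spikes -> AIP LFP".
#' @slot epoch epoch name.
#' @slot plv raw phase-locking value per frequency, in `[0, 1]`.
#' @slot z permutation z-score per frequency (vs LFP trial permutations).
#' @slot freq frequency grid; @slot nSpikes spikes used per trial;
#'   @slot nPerm permutations.
#' @export
setClass("PLVSpectrum", representation(
  spikeElectrode = "integer", lfpChannel = "integer", direction = "character",
  epoch = "character",
  plv = "numeric", z = "numeric",
  freq = "numeric", nSpikes = "integer", nPerm = "integer"
))

setValidity("PLVSpectrum", function(object) {
  if (any(object@plv < -1e-9 | object@plv > 1 + 1e-9, na.rm = TRUE))
    "raw PLV must lie in [0, 1]" else TRUE
})
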