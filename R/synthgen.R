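## Synthetic session generator. Every downstream analysis is exercised on
## sessions from this module, whose injected structure (coupling strength,
## category gain, phase-modulation depth) is known exactly.

.BANDS <- list(beta = c(16, 32), delta = c(2, 4))

#' Frequency band limits by name
#' @param band "beta" (16-32 Hz) or "delta" (2-4 Hz).
#' @return numeric `c(lo, hi)` in Hz.
#' @export
bandLimits <- function(band) {
  b <- .BANDS[[match.arg(band, names(.BANDS))]]
  b
}

#' Epoch window by name
#'
#' Category epoch: sample onset to boundary shift (0-1.3 s). Shift epoch:
#' boundary shift to test display (1.3-2.3 s). Fixation: the fixation window
#' before the pre-sample gap. Baseline: the 3 s pre-trial window.
#'
#' @param epoch epoch name.
#' @param timeline named event-time vector (see [generatorConfig()]).
#' @return numeric `c(t0, t1)` in seconds relative to sample onset.
#' @export
epochWindowFor <- function(epoch = c("category", "shift", "fixation", "baseline"),
                           timeline = defaultTimeline()) {
  switch(match.arg(epoch),
         category = c(timeline[["sampleOn"]], timeline[["shiftOn"]]),
         shift = c(timeline[["shiftOn"]], timeline[["testOn"]]),
         fixation = c(timeline[["fixOn"]], timeline[["gapOn"]]),
         baseline = c(timeline[["baselineStart"]], timeline[["fixOn"]]))
}

#' Default trial timeline
#'
#' Times in seconds relative to sample onset: 3 s pre-trial baseline, 1 s
#' fixation, 0.2 s pre-sample gap, 0.8 s sample display, boundary shift at
#' 1.3 s, test display at 2.3 s (recording end).
#' @return named numeric vector.
#' @export
defaultTimeline <- function() {
  c(baselineStart = -4.2, fixOn = -1.2, gapOn = -0.2, sampleOn = 0,
    sampleOff = 0.8, shiftOn = 1.3, testOn = 2.3, end = 2.3)
}

#' Construct a generator configuration
#'
#' The defaults produce a six-channel session (two electrodes in each of AIP,
#' cPFC and lPFC) whose injected structure mirrors the effects the analyses
#' are designed to detect: beta-band (Category epoch) and delta-band (Shift
#' epoch) phase coupling between a frontoparietal pair that is stronger for
#' Above than Below trials, category-dependent spiking gain in cPFC, and
#' beta-phase-locked cPFC spiking targeting an AIP channel.
#'
#' @param nChannels named integer vector of channels per area.
#' @param nTrials trials per session.
#' @param timeline named event times, see [defaultTimeline()].
#' @param sRate LFP sampling rate (Hz).
#' @param pinkExponent exponent of the 1/f^alpha background.
#' @param noiseRms background RMS (mV).
#' @param lineNoiseAmplitude 60 Hz line amplitude (mV).
#' @param evokedAmplitude evoked transient amplitude (mV).
#' @param couplingSpec data.frame of coupled pairs; see
#'   [GeneratorConfig-class].
#' @param spikeSpec data.frame of spiking electrodes; see
#'   [GeneratorConfig-class].
#' @param lapseRate behavioral lapse probability; the default reproduces the
#'   published overall accuracy of 92.77% correct.
#' @param seed master seed.
#' @return a [GeneratorConfig-class].
#' @export
generatorConfig <- function(nChannels = c(AIP = 2L, cPFC = 2L, lPFC = 2L),
                            nTrials = 120L,
                            timeline = defaultTimeline(),
                            sRate = 1000,
                            pinkExponent = 1,
                            noiseRms = 0.1,
                            lineNoiseAmplitude = 0.02,
                            evokedAmplitude = 0.05,
                            couplingSpec = NULL,
                            spikeSpec = NULL,
                            lapseRate = 0.0723,
                            seed = 1L) {
  nChannels <- stats::setNames(as.integer(nChannels), names(nChannels))
  if (is.null(couplingSpec)) {
    ## AIP channel 1 with cPFC channel 3: beta coupling in the Category epoch
    ## and delta coupling in the Shift epoch, both Above-selective.
    couplingSpec <- data.frame(
      chanA = c(1L, 1L), chanB = c(3L, 3L),
      band = c("beta", "delta"), epoch = c("category", "shift"),
      kappaAbove = c(2, 2), kappaBelow = c(0.3, 0.3),
      amplitude = c(0.06, 0.12), stringsAsFactors = FALSE)
  }
  if (is.null(spikeSpec)) {
    spikeSpec <- data.frame(
      electrode = 1:6, nUnits = 2L,
      rate = c(6, 6, 8, 8, 7, 7),
      gainAbove = c(1.2, 1.0, 2.0, 1.5, 1.3, 1.0),
      gainBelow = 1.0,
      modDepth = c(0, 0, 0.4, 0.3, 0, 0),
      prefPhase = 0,
      targetChannel = c(1L, 2L, 1L, 1L, 5L, 6L),
      targetBand = "beta", stringsAsFactors = FALSE)
  }
  methods::new("GeneratorConfig",
               nChannels = nChannels, nTrials = as.integer(nTrials),
               timeline = timeline, sRate = sRate,
               pinkExponent = pinkExponent, noiseRms = noiseRms,
               lineNoiseAmplitude = lineNoiseAmplitude,
               evokedAmplitude = evokedAmplitude,
               couplingSpec = couplingSpec, spikeSpec = spikeSpec,
               lapseRate = lapseRate, seed = as.integer(seed))
}

## Evoked transient template: brief damped 8 Hz wavelet following an event,
## deterministic, hence identical across trials.
.evokedTemplate <- function(tGrid, t0, amplitude) {
  u <- tGrid - t0
  a <- amplitude * exp(-((u - 0.12) / 0.05)^2 / 2) * cos(2 * pi * 8 * (u - 0.12))
  a[u < 0 | u > 0.4] <- 0
  a
}

#' Generate a synthetic session
#'
#' Deterministic given the config seed. Each channel's LFP is the sum of
#' 1/f^alpha background noise, a 60 Hz line component, evoked transients
#' locked to sample onset and boundary shift (identical across trials), and
#' the contributions of any coupled latent oscillators. A coupled pair shares
#' a band-limited latent oscillator per trial; each channel receives it with
#' an independent von Mises phase offset whose concentration is chosen by the
#' trial's category (kappaAbove vs kappaBelow), windowed to the coupling's
#' epoch with 50 ms cosine ramps. Spikes are inhomogeneous Poisson with
#' category-dependent gain after sample onset and sinusoidal modulation by the
#' designated channel's oscillatory phase.
#'
#' @param config a [GeneratorConfig-class].
#' @param geometry task geometry for the behavioral table.
#' @return a [SessionRecording-class].
#' @export
generateSession <- function(config, geometry = taskGeometry()) {
  methods::validObject(config)
  tl <- config@timeline
  fs <- config@sRate
  tGrid <- seq(tl[["baselineStart"]], tl[["end"]], by = 1 / fs)
  n <- length(tGrid)
  nChan <- sum(config@nChannels)
  nTrial <- config@nTrials
  areas <- rep(names(config@nChannels), config@nChannels)
  channels <- data.frame(id = seq_len(nChan), area = areas,
                         stringsAsFactors = FALSE)

  trials <- simulateBehavior(geometry, nTrial, config@lapseRate,
                             seed = .subSeed(config@seed, 9001))
  trials <- trials[seq_len(nTrial), ]
  trials$trial <- seq_len(nTrial)

  ## --- background + line noise + evoked -------------------------------------
  lfpArr <- array(0, dim = c(nChan, nTrial, n))
  evoked <- .evokedTemplate(tGrid, tl[["sampleOn"]], config@evokedAmplitude) +
    .evokedTemplate(tGrid, tl[["shiftOn"]], config@evokedAmplitude)
  for (ch in seq_len(nChan)) {
    for (tr in seq_len(nTrial)) {
      set.seed(.subSeed(config@seed, ch, tr))
      bg <- pinkNoise(n, config@pinkExponent, fs, config@noiseRms)
      line <- config@lineNoiseAmplitude *
        sin(2 * pi * 60 * tGrid + stats::runif(1, 0, 2 * pi))
      lfpArr[ch, tr, ] <- bg + line + evoked
    }
  }

  ## --- coupled latent oscillators -------------------------------------------
  cs <- config@couplingSpec
  oscPhase <- vector("list", nChan)   # per channel: list of band -> phase mat
  for (ch in seq_len(nChan)) oscPhase[[ch]] <- list()
  if (nrow(cs)) {
    for (k in seq_len(nrow(cs))) {
      band <- bandLimits(cs$band[k])
      win <- epochWindowFor(cs$epoch[k], tl)
      w <- epochWindow(tGrid, win[1], win[2])
      chA <- cs$chanA[k]; chB <- cs$chanB[k]
      phA <- matrix(NA_real_, nTrial, n)
      phB <- matrix(NA_real_, nTrial, n)
      for (tr in seq_len(nTrial)) {
        set.seed(.subSeed(config@seed, 7000L + k, tr))
        latent <- bandNoise(n, band, fs, rms = 1)
        z <- analyticSignal(latent)
        kap <- if (trials$categoryAB[tr] == "Above") cs$kappaAbove[k] else cs$kappaBelow[k]
        thA <- rVonMises(1, 0, kap)
        thB <- rVonMises(1, 0, kap)
        sigA <- w * Re(z * exp(1i * thA)) * cs$amplitude[k] / stats::sd(latent)
        sigB <- w * Re(z * exp(1i * thB)) * cs$amplitude[k] / stats::sd(latent)
        lfpArr[chA, tr, ] <- lfpArr[chA, tr, ] + sigA
        lfpArr[chB, tr, ] <- lfpArr[chB, tr, ] + sigB
        phA[tr, ] <- Arg(z) + thA
        phB[tr, ] <- Arg(z) + thB
      }
      ## windowed phase availability for spike modulation
      msk <- w > 0.5
      phA[, !msk] <- NA; phB[, !msk] <- NA
      oscPhase[[chA]][[cs$band[k]]] <- .mergePhase(oscPhase[[chA]][[cs$band[k]]], phA)
      oscPhase[[chB]][[cs$band[k]]] <- .mergePhase(oscPhase[[chB]][[cs$band[k]]], phB)
    }
  }

  ## --- spikes ----------------------------------------------------------------
  ss <- config@spikeSpec
  spk <- list()
  if (nrow(ss)) {
    gainOn <- tGrid >= tl[["sampleOn"]]
    for (e in seq_len(nrow(ss))) {
      elec <- ss$electrode[e]
      ph <- oscPhase[[ss$targetChannel[e]]][[ss$targetBand[e]]]
      for (u in seq_len(ss$nUnits[e])) {
        for (tr in seq_len(nTrial)) {
          set.seed(.subSeed(config@seed, 50000L + 100L * elec + u, tr))
          g <- if (trials$categoryAB[tr] == "Above") ss$gainAbove[e] else ss$gainBelow[e]
          phase <- if (is.null(ph)) rep(NA_real_, n) else ph[tr, ]
          lam <- ss$rate[e] * ifelse(gainOn, g, 1)
          mod <- 1 + ss$modDepth[e] * cos(phase - ss$prefPhase[e])
          mod[is.na(phase)] <- 1
          times <- synthSpikeTrain(tGrid, lam * mod)
          if (length(times))
            spk[[length(spk) + 1L]] <- data.frame(
              electrode = elec, unit = u, trial = tr, time = times)
        }
      }
    }
  }
  spikesDf <- if (length(spk)) do.call(rbind, spk) else
    data.frame(electrode = integer(0), unit = integer(0),
               trial = integer(0), time = numeric(0))

  methods::new("SessionRecording", lfp = lfpArr, time = tGrid, sRate = fs,
               spikes = spikesDf, channels = channels, trials = trials,
               groundTruth = config)
}

.mergePhase <- function(old, new) {
  if (is.null(old)) return(new)
  sel <- is.na(old) & !is.na(new)
  old[sel] <- new[sel]
  old
}

#' Inhomogeneous Poisson spike train by thinning
#'
#' Realises spike times on `[min(tGrid), max(tGrid)]` for a rate function
#' given by samples `lambda` on `tGrid` (Hz), via thinning of a homogeneous
#' Poisson process at `max(lambda)`. With the canonical sinusoidal phase
#' modulation, `lambda(t) = lambda0 * g * (1 + m cos(phase(t) - prefPhase))`;
#' pass that product directly, or use the convenience arguments.
#'
#' @param tGrid sample times (s), equally spaced.
#' @param lambda rate samples (Hz), same length as `tGrid`; all `>= 0`.
#' @param gain multiplies `lambda` (category gain).
#' @param modDepth,prefPhase,phase optional sinusoidal modulation
#'   `1 + modDepth * cos(phase - prefPhase)` applied on top of `lambda`;
#'   `modDepth < 1` keeps the rate nonnegative. `NA` phases mean no
#'   modulation at that sample.
#' @return numeric vector of spike times (s), sorted.
#' @export
synthSpikeTrain <- function(tGrid, lambda, gain = 1, modDepth = 0,
                            prefPhase = 0, phase = NULL) {
  stopifnot(length(lambda) == length(tGrid), modDepth >= 0, modDepth < 1)
  lam <- lambda * gain
  if (!is.null(phase)) {
    m <- 1 + modDepth * cos(phase - prefPhase)
    m[is.na(phase)] <- 1
    lam <- lam * m
  }
  if (any(lam < 0)) stop("negative rate encountered")
  lamMax <- max(lam)
  if (lamMax == 0) return(numeric(0))
  t0 <- tGrid[1]; t1 <- tGrid[length(tGrid)]
  nCand <- stats::rpois(1, lamMax * (t1 - t0))
  if (nCand == 0) return(numeric(0))
  cand <- sort(stats::runif(nCand, t0, t1))
  idx <- pmin(length(tGrid), pmax(1L, round((cand - t0) * (length(tGrid) - 1) /
                                              (t1 - t0)) + 1L))
  keep <- stats::runif(nCand) < lam[idx] / lamMax
  cand[keep]
}
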