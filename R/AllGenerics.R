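## Generics and accessors.

#' @name accessors
#' @title Accessors for catsync objects
#' @description Slot accessors for the S4 data objects; prefer these over
#'   direct slot access.
#' @param x an object.
#' @return the requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("lfp", function(x) standardGeneric("lfp"))
#' @rdname accessors
#' @export
setGeneric("spikes", function(x) standardGeneric("spikes"))
#' @rdname accessors
#' @export
setGeneric("trialTable", function(x) standardGeneric("trialTable"))
#' @rdname accessors
#' @export
setGeneric("channelTable", function(x) standardGeneric("channelTable"))
#' @rdname accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))
#' @rdname accessors
#' @export
setGeneric("timeGrid", function(x) standardGeneric("timeGrid"))
#' @rdname accessors
#' @export
setGeneric("freqGrid", function(x) standardGeneric("freqGrid"))
#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setGeneric("ppcRaw", function(x) standardGeneric("ppcRaw"))
#' @rdname accessors
#' @export
setGeneric("ppcCorrected", function(x) standardGeneric("ppcCorrected"))
#' @rdname accessors
#' @export
setGeneric("zScores", function(x) standardGeneric("zScores"))
#' @rdname accessors
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))
#' @rdname accessors
#' @export
setGeneric("clusterMask", function(x) standardGeneric("clusterMask"))
#' @rdname accessors
#' @export
setGeneric("plv", function(x) standardGeneric("plv"))

#' @rdname accessors
#' @export
setMethod("lfp", "SessionRecording", function(x) x@lfp)
#' @rdname accessors
#' @export
setMethod("lfp", "CleanLFP", function(x) x@lfp)
#' @rdname accessors
#' @export
setMethod("spikes", "SessionRecording", function(x) x@spikes)
#' @rdname accessors
#' @export
setMethod("trialTable", "SessionRecording", function(x) x@trials)
#' @rdname accessors
#' @export
setMethod("trialTable", "CleanLFP", function(x) x@trials)
#' @rdname accessors
#' @export
setMethod("trialTable", "SpectralDecomposition", function(x) x@trials)
#' @rdname accessors
#' @export
setMethod("channelTable", "SessionRecording", function(x) x@channels)
#' @rdname accessors
#' @export
setMethod("channelTable", "CleanLFP", function(x) x@channels)
#' @rdname accessors
#' @export
setMethod("channelTable", "SpectralDecomposition", function(x) x@channels)
#' @rdname accessors
#' @export
setMethod("sampleRate", "SessionRecording", function(x) x@sRate)
#' @rdname accessors
#' @export
setMethod("sampleRate", "CleanLFP", function(x) x@sRate)
#' @rdname accessors
#' @export
setMethod("sampleRate", "SpectralDecomposition", function(x) x@sRate)
#' @rdname accessors
#' @export
setMethod("timeGrid", "SessionRecording", function(x) x@time)
#' @rdname accessors
#' @export
setMethod("timeGrid", "CleanLFP", function(x) x@time)
#' @rdname accessors
#' @export
setMethod("timeGrid", "SpectralDecomposition", function(x) x@time)
#' @rdname accessors
#' @export
setMethod("freqGrid", "SpectralDecomposition", function(x) x@freq)
#' @rdname accessors
#' @export
setMethod("freqGrid", "PLVSpectrum", function(x) x@freq)
#' @rdname accessors
#' @export
setMethod("groundTruth", "SessionRecording", function(x) x@groundTruth)
#' @rdname accessors
#' @export
setMethod("ppcRaw", "PPCMap", function(x) x@ppcRaw)
#' @rdname accessors
#' @export
setMethod("ppcCorrected", "PPCMap", function(x) x@ppcCorrected)
#' @rdname accessors
#' @export
setMethod("zScores", "SelectivityZMap", function(x) x@z)
#' @rdname accessors
#' @export
setMethod("zScores", "PLVSpectrum", function(x) x@z)
#' @rdname accessors
#' @export
setMethod("pValues", "SelectivityZMap", function(x) x@p)
#' @rdname accessors
#' @export
setMethod("clusterMask", "SelectivityZMap", function(x) x@clusterMask)
#' @rdname accessors
#' @export
setMethod("plv", "PLVSpectrum", function(x) x@plv)

## -- show methods ------------------------------------------------------------

setMethod("show", "TaskGeometry", function(object) {
  cat("TaskGeometry:", nrow(object@basePositions), "base sample positions x",
      length(object@jitterLevels), "jitter levels/axis;",
      nrow(object@testPositions), "test locations; shift",
      object@shiftMagnitude, "deg\n")
})

setMethod("show", "GeneratorConfig", function(object) {
  cat("GeneratorConfig:", sum(object@nChannels), "channels (",
      paste(names(object@nChannels), object@nChannels, collapse = ", "), "),",
      object@nTrials, "trials,", nrow(object@couplingSpec),
      "coupling rows,", nrow(object@spikeSpec), "spike rows, seed",
      object@seed, "\n")
})

setMethod("show", "SessionRecording", function(object) {
  d <- dim(object@lfp)
  cat("SessionRecording:", d[1], "channels x", d[2], "trials x", d[3],
      "samples @", object@sRate, "Hz;", nrow(object@spikes), "spikes\n")
})

setMethod("show", "SpectralDecomposition", function(object) {
  cat("SpectralDecomposition:", length(object@coef), "channels,",
      length(object@freq), "frequencies (", min(object@freq), "-",
      max(object@freq), "Hz ),", length(object@time), "time points @",
      round(object@sRate, 2), "Hz, omega0 =", object@omega0, "\n")
})

setMethod("show", "PPCMap", function(object) {
  cat("PPCMap", paste0(object@chanA, "-", object@chanB), "(", object@areaPair,
      "):", length(object@freq), "x", length(object@time),
      "bins, N =", object@nTrials, "trials,", object@nSurrogates,
      "surrogates\n")
})

setMethod("show", "SelectivityZMap", function(object) {
  cat("SelectivityZMap", paste0(object@chanA, "-", object@chanB),
      object@dimension, ":", length(object@freq), "x", length(object@time),
      "bins,", object@nPerm, "permutations,",
      sum(object@clusterMask), "cluster bins\n")
})

setMethod("show", "PLVSpectrum", function(object) {
  cat("PLVSpectrum", object@direction, "[", object@epoch, "]:",
      length(object@freq), "frequencies,", sum(object@nSpikes), "spikes\n")
})
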