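## Session container I/O. A session is stored as a directory of plain-text
## files: meta.json (schema version, sampling info, generator config),
## channels.csv, trials.csv, spikes.csv and one lfp_<channel>.csv matrix
## (trials x samples) per channel. fwrite/fread round-trip doubles exactly.

.SCHEMA_VERSION <- "catsync-session-1"

.configToList <- function(cfg) {
  list(nChannels = as.list(cfg@nChannels), nTrials = cfg@nTrials,
       timeline = as.list(cfg@timeline), sRate = cfg@sRate,
       pinkExponent = cfg@pinkExponent, noiseRms = cfg@noiseRms,
       lineNoiseAmplitude = cfg@lineNoiseAmplitude,
       evokedAmplitude = cfg@evokedAmplitude,
       couplingSpec = cfg@couplingSpec, spikeSpec = cfg@spikeSpec,
       lapseRate = cfg@lapseRate, seed = cfg@seed)
}

.configFromList <- function(x) {
  generatorConfig(nChannels = unlist(x$nChannels), nTrials = x$nTrials,
                  timeline = unlist(x$timeline), sRate = x$sRate,
                  pinkExponent = x$pinkExponent, noiseRms = x$noiseRms,
                  lineNoiseAmplitude = x$lineNoiseAmplitude,
                  evokedAmplitude = x$evokedAmplitude,
                  couplingSpec = as.data.frame(x$couplingSpec),
                  spikeSpec = as.data.frame(x$spikeSpec),
                  lapseRate = x$lapseRate, seed = x$seed)
}

#' Write a session to a directory
#'
#' @param session a [SessionRecording-class].
#' @param path directory to create (must not already contain a session unless
#'   `overwrite = TRUE`).
#' @param overwrite replace an existing session directory.
#' @return `path`, invisibly.
#' @export
writeSession <- function(session, path, overwrite = FALSE) {
  stopifnot(is(session, "SessionRecording"))
  if (dir.exists(path) && length(dir(path)) && !overwrite)
    stop("path exists and is not empty; use overwrite = TRUE")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(schema = .SCHEMA_VERSION,
               sRate = session@sRate,
               nChannels = dim(session@lfp)[1],
               nTrials = dim(session@lfp)[2],
               nSamples = dim(session@lfp)[3],
               timeStart = session@time[1],
               config = .configToList(session@groundTruth))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  data.table::fwrite(session@channels, file.path(path, "channels.csv"))
  data.table::fwrite(session@trials, file.path(path, "trials.csv"))
  ## %.17g guarantees exact double round-trip for spike times and LFP samples
  spk <- session@spikes
  spk$time <- sprintf("%.17g", spk$time)
  data.table::fwrite(spk, file.path(path, "spikes.csv"), quote = FALSE)
  for (ch in seq_len(dim(session@lfp)[1])) {
    m <- session@lfp[ch, , , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    txt <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = ","))
    writeLines(txt, file.path(path, sprintf("lfp_%03d.csv", ch)))
  }
  invisible(path)
}

#' Read a session from a directory
#'
#' Validates the schema version and array dimensions; a truncated or
#' inconsistent store raises an error rather than returning a partial
#' session. Electrodes with zero recorded spikes are flagged with a warning.
#'
#' @param path session directory written by [writeSession()].
#' @return a [SessionRecording-class].
#' @export
readSession <- function(path) {
  metaPath <- file.path(path, "meta.json")
  if (!file.exists(metaPath)) stop("not a session directory: ", path)
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  if (!identical(meta$schema, .SCHEMA_VERSION))
    stop("unsupported session schema '", meta$schema, "'; expected '",
         .SCHEMA_VERSION, "'")
  channels <- as.data.frame(data.table::fread(file.path(path, "channels.csv")))
  trials <- as.data.frame(data.table::fread(file.path(path, "trials.csv")))
  spikes <- as.data.frame(data.table::fread(
    file.path(path, "spikes.csv"),
    colClasses = c(electrode = "integer", unit = "integer",
                   trial = "integer", time = "numeric")))
  nChan <- meta$nChannels; nTrial <- meta$nTrials; nSamp <- meta$nSamples
  lfpArr <- array(NA_real_, dim = c(nChan, nTrial, nSamp))
  for (ch in seq_len(nChan)) {
    m <- as.matrix(data.table::fread(file.path(path, sprintf("lfp_%03d.csv", ch)),
                                     header = FALSE))
    if (!all(dim(m) == c(nTrial, nSamp)))
      stop("lfp_", sprintf("%03d", ch), ".csv is truncated or inconsistent (",
           nrow(m), "x", ncol(m), ", expected ", nTrial, "x", nSamp, ")")
    lfpArr[ch, , ] <- m
  }
  tGrid <- meta$timeStart + (seq_len(nSamp) - 1) / meta$sRate
  silent <- setdiff(seq_len(nChan), unique(spikes$electrode))
  if (length(silent))
    warning("electrode(s) without spikes: ", paste(silent, collapse = ", "))
  methods::new("SessionRecording", lfp = lfpArr, time = tGrid,
               sRate = meta$sRate, spikes = spikes, channels = channels,
               trials = trials, groundTruth = .configFromList(meta$config))
}
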