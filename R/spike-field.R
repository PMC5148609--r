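## Spike-field synchrony: phase-locking values with LFP-permutation z-scores,
## directionality contrasts, decile conditioning and selectivity-synchrony
## correlation.

#' Raw phase-locking value of a set of phases
#'
#' Resultant length `|mean(exp(1i * phi))|`: 1 when all phases coincide,
#' 0 for phases spread uniformly.
#' @param phi angles in radians (>= 1).
#' @return scalar in `[0, 1]`.
#' @export
plvOfPhases <- function(phi) resultantLength(phi)

## Spike-phase extraction: per trial, the wavelet phase of the LFP channel at
## each spike time, for every frequency. Returns list(trials = trial ids,
## idx = list of sample indices per trial).
.spikeSampleIdx <- function(spikeTimes, timeGrid) {
  dt <- stats::median(diff(timeGrid))
  idx <- round((spikeTimes - timeGrid[1]) / dt) + 1L
  idx[idx >= 1L & idx <= length(timeGrid)]
}

#' Spike-field phase-locking spectrum with LFP-permutation z-scores
#'
#' For each frequency, the phases of the LFP channel's wavelet coefficients
#' at the spike times of the spiking electrode (pooled across units) are
#' collected within the epoch. The single-trial PLV is the resultant length
#' of each trial's spike phases; trials are combined by a spike-count
#' weighted average (a config switch pools all spikes across trials
#' instead). The z-score is computed against `nPerm` permutations that
#' reassign the LFP trial traces across trials while keeping each trial's
#' series of spikes, so it discounts locking that arises solely from spike
#' count and temporal pattern.
#'
#' @param session the [SessionRecording-class] providing the spikes.
#' @param spikeElectrode spiking electrode id.
#' @param decomposition [SpectralDecomposition-class] containing the LFP
#'   channel.
#' @param lfpChannel LFP channel id.
#' @param epoch epoch name ("category"/"shift"/"fixation"/"baseline");
#'   spikes outside the epoch never contribute.
#' @param trials optional trial subset.
#' @param nPerm LFP permutations (default 200).
#' @param pooling "trialwise" (default) or "pooled".
#' @param timeline event times for the epoch window.
#' @param seed RNG seed.
#' @return a [PLVSpectrum-class].
#' @export
plvZ <- function(session, spikeElectrode, decomposition, lfpChannel,
                 epoch = "category", trials = NULL, nPerm = 200,
                 pooling = c("trialwise", "pooled"),
                 timeline = defaultTimeline(), seed = 1) {
  pooling <- match.arg(pooling)
  key <- as.character(lfpChannel)
  if (!key %in% names(decomposition@coef))
    stop("LFP channel not present in the decomposition")
  W <- decomposition@coef[[key]]
  nTrial <- dim(W)[1]
  if (is.null(trials)) trials <- seq_len(nTrial)
  win <- epochWindowFor(epoch, timeline)
  sp <- session@spikes
  sp <- sp[sp$electrode == spikeElectrode & sp$trial %in% trials &
             sp$time >= win[1] & sp$time < win[2], ]
  if (!nrow(sp)) stop("no spikes in the epoch for this electrode")
  spikeIdx <- lapply(trials, function(tr)
    .spikeSampleIdx(sp$time[sp$trial == tr], decomposition@time))
  nSpk <- lengths(spikeIdx)
  if (sum(nSpk > 0) < 2)
    stop("spikes on fewer than 2 trials; permutation degenerate")

  freqN <- length(decomposition@freq)
  plvFor <- function(assign) {
    ## assign[i]: which trial's LFP serves trial i's spikes
    num <- matrix(0, freqN, 1)
    if (pooling == "pooled") {
      S <- matrix(0i, freqN, 1)
      for (i in seq_along(trials)) {
        if (!nSpk[i]) next
        ph <- W[assign[i], , spikeIdx[[i]], drop = FALSE]
        ph <- matrix(ph, freqN)
        S <- S + rowSums(ph / Mod(ph))
      }
      as.vector(Mod(S) / sum(nSpk))
    } else {
      acc <- numeric(freqN)
      for (i in seq_along(trials)) {
        if (!nSpk[i]) next
        ph <- matrix(W[assign[i], , spikeIdx[[i]], drop = FALSE], freqN)
        acc <- acc + nSpk[i] * Mod(rowMeans(ph / Mod(ph)))
      }
      acc / sum(nSpk)
    }
  }
  obs <- plvFor(trials)
  set.seed(seed)
  permMat <- matrix(0, nPerm, freqN)
  for (s in seq_len(nPerm)) {
    permMat[s, ] <- plvFor(trials[sample.int(length(trials))])
  }
  mu <- colMeans(permMat)
  sdv <- .colSds(permMat)
  z <- (obs - mu) / sdv
  z[sdv == 0] <- NA
  areas <- session@channels$area
  dir <- paste0(areas[match(spikeElectrode, session@channels$id)],
                " spikes -> ",
                areas[match(lfpChannel, session@channels$id)], " LFP")
  methods::new("PLVSpectrum",
               spikeElectrode = as.integer(spikeElectrode),
               lfpChannel = as.integer(lfpChannel),
               direction = dir, epoch = epoch,
               plv = obs, z = z, freq = decomposition@freq,
               nSpikes = as.integer(nSpk), nPerm = as.integer(nPerm))
}

#' Directionality contrast of spike-field synchrony
#'
#' Per frequency (and for a band average), a two-tailed paired t-test across
#' session pairs of `z_PLV(A spikes -> B LFP)` versus
#' `z_PLV(B spikes -> A LFP)`. Swapping the arguments flips the sign of every
#' difference.
#'
#' @param plvAB,plvBA lists of [PLVSpectrum-class], matched element-wise to
#'   the same session pairs.
#' @param band `c(lo, hi)` Hz for the band-average test (default 22-32 Hz,
#'   the band of the published directional contrast).
#' @param alpha significance threshold for the per-frequency marks.
#' @return list with `perFrequency` (data.frame: freq, meanDiff, t, p, sig)
#'   and `bandTest` (band-averaged paired t-test).
#' @export
directionalityContrast <- function(plvAB, plvBA, band = c(22, 32),
                                   alpha = 0.05) {
  if (length(plvAB) != length(plvBA) || length(plvAB) < 2)
    stop("need matched lists of >= 2 pairs in both directions")
  freq <- plvAB[[1]]@freq
  zAB <- t(vapply(plvAB, function(p) p@z, numeric(length(freq))))
  zBA <- t(vapply(plvBA, function(p) p@z, numeric(length(freq))))
  if (!all(vapply(plvBA, function(p) identical(p@freq, freq), logical(1))))
    stop("mismatched frequency grids")
  d <- zAB - zBA
  tt <- apply(d, 2, function(v) {
    if (stats::sd(v) == 0) return(c(0, 1))   # no difference at all
    r <- stats::t.test(v)
    c(r$statistic, r$p.value)
  })
  perFreq <- data.frame(freq = freq, meanDiff = colMeans(d),
                        t = tt[1, ], p = tt[2, ], sig = tt[2, ] < alpha)
  inBand <- freq >= band[1] & freq <= band[2]
  bAB <- rowMeans(zAB[, inBand, drop = FALSE])
  bBA <- rowMeans(zBA[, inBand, drop = FALSE])
  bt <- if (stats::sd(bAB - bBA) == 0) list(statistic = 0, p.value = 1) else
    stats::t.test(bAB, bBA, paired = TRUE)
  list(perFrequency = perFreq,
       bandTest = data.frame(bandLo = band[1], bandHi = band[2],
                             meanAB = mean(bAB), meanBA = mean(bBA),
                             t = bt$statistic, p = bt$p.value))
}

#' Top/bottom-decile selection by a selectivity score
#'
#' Selects `ceiling(fraction * n)` ids with the largest (or smallest) scores.
#' Ties are broken deterministically by id order and flagged.
#'
#' @param scores named numeric vector (ids in names).
#' @param fraction selected fraction (default 0.10).
#' @param side "top" or "bottom".
#' @return list with `ids`, `scores`, `tieFlag`, `smallN` (TRUE when fewer
#'   than 10 scored ids were available; a warning is emitted).
#' @export
topDecileSelection <- function(scores, fraction = 0.10,
                               side = c("top", "bottom")) {
  side <- match.arg(side)
  n <- length(scores)
  if (is.null(names(scores))) names(scores) <- seq_len(n)
  smallN <- n < 10
  if (smallN) warning("fewer than 10 scored ids; decile selection is degenerate")
  k <- max(1L, ceiling(fraction * n))
  ord <- order(if (side == "top") -scores else scores,
               seq_len(n))              # stable: ties broken by id order
  sel <- ord[seq_len(k)]
  cutoff <- scores[sel[k]]
  tieFlag <- sum(scores == cutoff) > sum(scores[sel] == cutoff)
  list(ids = names(scores)[sel], scores = scores[sel],
       tieFlag = tieFlag, smallN = smallN)
}

#' Group comparison of spike-field synchrony by spiking selectivity
#'
#' Given per-electrode mean z-PLV spectra (each electrode's spikes against
#' all simultaneously recorded LFPs of the target area, averaged), compares
#' two selection groups (e.g. Above/Below-selective vs Right/Left-selective
#' top deciles) with a two-tailed two-sample t-test per frequency.
#'
#' @param zGroupA,zGroupB numeric matrices (electrode x frequency) of mean
#'   z-PLV spectra for the two groups; both non-empty.
#' @param freq frequency grid.
#' @param alpha significance threshold.
#' @return data.frame: freq, meanA, meanB, diff, t, p, sig.
#' @export
selectiveSpikePlvAnalysis <- function(zGroupA, zGroupB, freq, alpha = 0.05) {
  if (!nrow(zGroupA) || !nrow(zGroupB)) stop("empty selection group")
  stopifnot(ncol(zGroupA) == length(freq), ncol(zGroupB) == length(freq))
  res <- vapply(seq_along(freq), function(k) {
    r <- stats::t.test(zGroupA[, k], zGroupB[, k])
    c(r$statistic, r$p.value)
  }, numeric(2))
  data.frame(freq = freq, meanA = colMeans(zGroupA), meanB = colMeans(zGroupB),
             diff = colMeans(zGroupA) - colMeans(zGroupB),
             t = res[1, ], p = res[2, ], sig = res[2, ] < alpha)
}

#' Correlation between spiking selectivity and spike-field synchrony
#'
#' Across electrodes, Pearson and Spearman correlations between the
#' epoch-averaged spiking selectivity (omega-PEV) and the electrode's mean
#' beta-band spike-to-target-LFP z-PLV.
#'
#' @param pev numeric vector of per-electrode epoch-averaged omega-PEV.
#' @param zPlv numeric vector of per-electrode mean beta-band z-PLV.
#' @return data.frame with rows "pearson" and "spearman" (estimate, p).
#' @export
pevPlvCorrelation <- function(pev, zPlv) {
  stopifnot(length(pev) == length(zPlv))
  if (length(pev) < 3) stop("need at least 3 electrodes")
  if (stats::sd(pev) == 0 || stats::sd(zPlv) == 0)
    stop("zero variance in one of the variables; correlation undefined")
  pe <- stats::cor.test(pev, zPlv, method = "pearson")
  sp <- suppressWarnings(stats::cor.test(pev, zPlv, method = "spearman"))
  data.frame(method = c("pearson", "spearman"),
             estimate = c(unname(pe$estimate), unname(sp$estimate)),
             p = c(pe$p.value, sp$p.value))
}
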