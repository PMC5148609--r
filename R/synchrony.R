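## LFP-LFP synchrony: pairwise phase consistency, surrogate bias correction,
## category-selectivity permutation z-maps, cluster significance, summaries.

## Unit cross-phasors exp(i * dphi) of a channel pair: trial x freq x time.
.pairPhasors <- function(decomposition, chanA, chanB, trials = NULL) {
  kA <- as.character(chanA); kB <- as.character(chanB)
  if (!kA %in% names(decomposition@coef) || !kB %in% names(decomposition@coef))
    stop("both channels must be present in the decomposition")
  WA <- decomposition@coef[[kA]]
  WB <- decomposition@coef[[kB]]
  if (!is.null(trials)) {
    WA <- WA[trials, , , drop = FALSE]
    WB <- WB[trials, , , drop = FALSE]
  }
  if (any(Mod(WA) == 0) || any(Mod(WB) == 0))
    stop("phase undefined: zero wavelet coefficient encountered")
  U <- WA * Conj(WB)
  U / Mod(U)
}

.areaPairLabel <- function(channels, chanA, chanB) {
  a <- channels$area[match(c(chanA, chanB), channels$id)]
  if (any(is.na(a))) return(NA_character_)
  paste(sort(a), collapse = "-")
}

## PPC maps from an [N x B] (or [N x F x T]) unit-phasor array.
.ppcOfPhasors <- function(U) {
  n <- dim(U)[1]
  S <- colSums(U, dims = 1)
  R <- Mod(S) / n
  .ppcFromResultant(R, n)
}

#' Pairwise phase consistency map of a channel pair
#'
#' Per (frequency, time) bin the per-trial phase difference is
#' `dphi_i = Arg(W_a,i * Conj(W_b,i))`; PPC is the mean cosine of the angular
#' distance over all unordered trial pairs, evaluated through the resultant
#' identity `(N R^2 - 1)/(N - 1)`. The bias-corrected map subtracts the mean
#' PPC of surrogate datasets in which one channel's trial order is permuted
#' independently of the other (without replacement).
#'
#' @param decomposition a [SpectralDecomposition-class] containing both
#'   channels.
#' @param chanA,chanB channel ids.
#' @param trials trial subset (default all); at least 2.
#' @param nSurrogates trial-shuffle surrogates for the bias correction
#'   (default 200; 0 skips correction).
#' @param seed RNG seed for the surrogate shuffles.
#' @return a [PPCMap-class].
#' @export
ppcMap <- function(decomposition, chanA, chanB, trials = NULL,
                   nSurrogates = 200, seed = 1) {
  U <- .pairPhasors(decomposition, chanA, chanB, trials)
  n <- dim(U)[1]
  if (n < 2) stop("PPC requires at least 2 trials")
  nf <- dim(U)[2]; nt <- dim(U)[3]
  raw <- .ppcOfPhasors(U)

  corrected <- raw
  if (nSurrogates > 0) {
    kA <- as.character(chanA); kB <- as.character(chanB)
    WA <- decomposition@coef[[kA]]
    WB <- decomposition@coef[[kB]]
    if (!is.null(trials)) {
      WA <- WA[trials, , , drop = FALSE]; WB <- WB[trials, , , drop = FALSE]
    }
    A <- matrix(WA / Mod(WA), n)      # N x (F*T)
    Bc <- Conj(matrix(WB / Mod(WB), n))
    set.seed(seed)
    acc <- matrix(0, nf, nt)
    for (s in seq_len(nSurrogates)) {
      perm <- sample.int(n)
      S <- colSums(A[perm, , drop = FALSE] * Bc)
      R <- Mod(S) / n
      acc <- acc + matrix(.ppcFromResultant(R, n), nf, nt)
    }
    corrected <- raw - acc / nSurrogates
  }
  methods::new("PPCMap", chanA = as.integer(chanA), chanB = as.integer(chanB),
               areaPair = .areaPairLabel(decomposition@channels, chanA, chanB),
               ppcRaw = raw, ppcCorrected = corrected,
               freq = decomposition@freq, time = decomposition@time,
               nTrials = as.integer(n), nSurrogates = as.integer(nSurrogates))
}

#' Permutation z-map of category-selective synchrony
#'
#' The statistic is `D = |PPC_catA - PPC_catB|` per (frequency, time) bin,
#' computed on trials of the two categories of the chosen dimension
#' (balanced to equal n by random subsampling of the larger group). Labels
#' are permuted `nPerm` times preserving group sizes; per bin,
#' `z = (D - mean(D_perm)) / sd(D_perm)` and the one-sided rank p-value is
#' `(1 + #{D_perm >= D}) / (nPerm + 1)`. Bins with zero permutation spread
#' are flagged and carry `z = NA`.
#'
#' @param decomposition a [SpectralDecomposition-class].
#' @param chanA,chanB channel ids.
#' @param labels character/factor of per-trial category labels (two levels),
#'   aligned with the decomposition's trials.
#' @param dimension label stored on the result ("AboveBelow"/"RightLeft").
#' @param nPerm number of label permutations (default 200).
#' @param trials optional trial subset (e.g. correct trials only).
#' @param balance subsample the larger group to equal n (default TRUE).
#' @param seed RNG seed for balancing and permutations.
#' @return a [SelectivityZMap-class] (cluster mask empty until
#'   [significantClusters()] is applied).
#' @export
categorySelectivityZ <- function(decomposition, chanA, chanB, labels,
                                 dimension = "AboveBelow", nPerm = 200,
                                 trials = NULL, balance = TRUE, seed = 1) {
  if (!is.null(trials)) labels <- labels[trials]
  U <- .pairPhasors(decomposition, chanA, chanB, trials)
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2) stop("labels must have exactly two levels")
  idxA <- which(labels == lev[1]); idxB <- which(labels == lev[2])
  if (length(idxA) < 2 || length(idxB) < 2)
    stop("both categories need at least 2 trials")
  set.seed(seed)
  if (balance) {
    m <- min(length(idxA), length(idxB))
    if (length(idxA) > m) idxA <- sort(sample(idxA, m))
    if (length(idxB) > m) idxB <- sort(sample(idxB, m))
  }
  ## canonical (sorted) trial order so results are invariant to an A/B label
  ## swap when group sizes are equal
  keep <- sort(c(idxA, idxB))
  selTrue <- keep %in% idxA
  U <- U[keep, , , drop = FALSE]
  nA <- length(idxA); nB <- length(idxB); n <- nA + nB
  nf <- dim(U)[2]; nt <- dim(U)[3]
  Um <- matrix(U, n)                      # n x B complex
  UmRe <- Re(Um); UmIm <- Im(Um)

  groupD <- function(selA) {
    SA <- colSums(Um[selA, , drop = FALSE])
    SB <- colSums(Um[!selA, , drop = FALSE])
    pA <- .ppcFromResultant(Mod(SA) / nA, nA)
    pB <- .ppcFromResultant(Mod(SB) / nB, nB)
    abs(pA - pB)
  }
  D <- matrix(groupD(selTrue), nf, nt)

  ## permutations via indicator-matrix multiplication
  P <- matrix(0, nPerm, n)
  for (s in seq_len(nPerm)) P[s, sample.int(n, nA)] <- 1
  SAre <- P %*% UmRe; SAim <- P %*% UmIm
  StRe <- colSums(UmRe); StIm <- colSums(UmIm)
  SBre <- sweep(-SAre, 2, StRe, "+"); SBim <- sweep(-SAim, 2, StIm, "+")
  pAperm <- .ppcFromResultant(sqrt(SAre^2 + SAim^2) / nA, nA)
  pBperm <- .ppcFromResultant(sqrt(SBre^2 + SBim^2) / nB, nB)
  Dperm <- abs(pAperm - pBperm)           # nPerm x B

  mu <- colMeans(Dperm)
  sdv <- .colSds(Dperm)
  zFlat <- (as.vector(D) - mu) / sdv
  flagged <- sdv == 0
  zFlat[flagged] <- NA
  pFlat <- (1 + colSums(Dperm >= rep(as.vector(D), each = nPerm))) / (nPerm + 1)

  methods::new("SelectivityZMap",
               D = D, z = matrix(zFlat, nf, nt), p = matrix(pFlat, nf, nt),
               nPerm = as.integer(nPerm), dimension = dimension,
               clusterMask = matrix(FALSE, nf, nt),
               flagged = matrix(flagged, nf, nt),
               freq = decomposition@freq, time = decomposition@time,
               chanA = as.integer(chanA), chanB = as.integer(chanB),
               areaPair = .areaPairLabel(decomposition@channels, chanA, chanB))
}

#' Cluster-significance mask of a selectivity map
#'
#' A bin survives iff it belongs to a rectangular region over which p < alpha
#' holds contiguously for at least `minDurationMs` at each of at least
#' `minFreqBins` consecutive frequency bins.
#'
#' @param zmap a [SelectivityZMap-class], or a p-value matrix
#'   (frequency x time) with `sRate` supplied.
#' @param alpha per-bin significance level.
#' @param minDurationMs minimum contiguous duration (ms).
#' @param minFreqBins minimum number of consecutive frequency bins.
#' @param sRate sampling rate of the time grid (Hz); taken from the map's
#'   time grid when a [SelectivityZMap-class] is given.
#' @return for matrix input, the logical mask; for a
#'   [SelectivityZMap-class], the map with its `clusterMask` slot filled.
#' @export
significantClusters <- function(zmap, alpha = 0.05, minDurationMs = 60,
                                minFreqBins = 3, sRate = NULL) {
  isMap <- is(zmap, "SelectivityZMap")
  p <- if (isMap) zmap@p else zmap
  if (isMap) sRate <- 1 / stats::median(diff(zmap@time))
  if (is.null(sRate)) stop("sRate required for matrix input")
  minSamp <- round(minDurationMs / 1000 * sRate)
  if (minSamp < 2) stop("minDurationMs must span at least 2 time steps")
  sig <- p < alpha
  sig[is.na(sig)] <- FALSE
  nf <- nrow(sig); nt <- ncol(sig)
  mask <- matrix(FALSE, nf, nt)
  if (nf >= minFreqBins) {
    for (f0 in seq_len(nf - minFreqBins + 1L)) {
      rows <- f0:(f0 + minFreqBins - 1L)
      allRows <- colSums(sig[rows, , drop = FALSE]) == minFreqBins
      r <- rle(allRows)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      ok <- which(r$values & r$lengths >= minSamp)
      for (k in ok) mask[rows, starts[k]:ends[k]] <- TRUE
    }
  }
  if (isMap) {
    zmap@clusterMask <- mask
    zmap
  } else mask
}

#' Population-combined selectivity map
#'
#' Combines the z-maps of several pairs by Stouffer's method
#' (`z_comb = sum(z) / sqrt(n)`) per bin and derives one-sided p-values from
#' the normal tail of the combined score. Single-pair chance fluctuations
#' average out, so the cluster rule applied to the combined map reflects
#' population-level selectivity, analogous to contouring a population-average
#' selectivity map.
#'
#' @param zmaps list of [SelectivityZMap-class] on identical grids.
#' @return a [SelectivityZMap-class] holding the combined map (nPerm is taken
#'   from the inputs; the cluster mask is empty until
#'   [significantClusters()] is applied).
#' @export
populationSelectivityMap <- function(zmaps) {
  stopifnot(length(zmaps) >= 2)
  f <- zmaps[[1]]@freq; tt <- zmaps[[1]]@time
  for (zm in zmaps)
    if (!identical(zm@freq, f) || !identical(zm@time, tt))
      stop("z-maps must share grids")
  zs <- lapply(zmaps, function(zm) { z <- zm@z; z[is.na(z)] <- 0; z })
  n <- length(zs)
  zc <- Reduce(`+`, zs) / sqrt(n)
  Dm <- Reduce(`+`, lapply(zmaps, methods::slot, "D")) / n
  pc <- stats::pnorm(zc, lower.tail = FALSE)
  methods::new("SelectivityZMap", D = Dm, z = zc, p = pc,
               nPerm = zmaps[[1]]@nPerm, dimension = zmaps[[1]]@dimension,
               clusterMask = matrix(FALSE, nrow(zc), ncol(zc)),
               flagged = Reduce(`|`, lapply(zmaps, methods::slot, "flagged")),
               freq = f, time = tt, chanA = NA_integer_, chanB = NA_integer_,
               areaPair = zmaps[[1]]@areaPair)
}

#' Band- and epoch-collapsed selectivity summary
#'
#' Collapses each z-map over the two frequency bands (beta 16-32 Hz, delta
#' 2-4 Hz) and the two trial epochs (Category 0-1.3 s, Shift 1.3-2.3 s), then
#' summarises across pairs per (area pair, dimension, epoch, band): mean z,
#' SEM, number of pairs, the percentage of pairs with at least one
#' significant cluster anywhere in the cell, and Bonferroni-corrected
#' confidence intervals for the mean.
#'
#' @param zmaps list of [SelectivityZMap-class] (cluster masks filled if the
#'   percent-selective column is wanted).
#' @param timeline event times for epoch windows.
#' @param ciLevel base confidence level before Bonferroni correction.
#' @return data.frame; groups with a single pair carry `NA` SEM (flagged),
#'   empty groups are omitted with a warning.
#' @export
selectivitySummary <- function(zmaps, timeline = defaultTimeline(),
                               ciLevel = 0.95) {
  stopifnot(length(zmaps) >= 1)
  cells <- expand.grid(band = c("beta", "delta"), epoch = c("category", "shift"),
                       stringsAsFactors = FALSE)
  rows <- list()
  for (zm in zmaps) {
    for (i in seq_len(nrow(cells))) {
      bl <- bandLimits(cells$band[i])
      win <- epochWindowFor(cells$epoch[i], timeline)
      fSel <- zm@freq >= bl[1] & zm@freq <= bl[2]
      tSel <- zm@time >= win[1] & zm@time <= win[2]
      rows[[length(rows) + 1L]] <- data.frame(
        areaPair = zm@areaPair, dimension = zm@dimension,
        epoch = cells$epoch[i], band = cells$band[i],
        meanZ = mean(zm@z[fSel, tSel], na.rm = TRUE),
        hasCluster = any(zm@clusterMask[fSel, tSel]),
        stringsAsFactors = FALSE)
    }
  }
  long <- do.call(rbind, rows)
  groups <- unique(long[c("areaPair", "dimension", "epoch", "band")])
  nGroups <- nrow(groups)
  out <- lapply(seq_len(nGroups), function(g) {
    sel <- long$areaPair == groups$areaPair[g] &
      long$dimension == groups$dimension[g] &
      long$epoch == groups$epoch[g] & long$band == groups$band[g]
    v <- long$meanZ[sel]
    nP <- length(v)
    if (!nP) return(NULL)
    sem <- if (nP > 1) stats::sd(v) / sqrt(nP) else NA_real_
    alphaAdj <- (1 - ciLevel) / nGroups      # Bonferroni across cells
    halfW <- if (nP > 1) stats::qt(1 - alphaAdj / 2, nP - 1) * sem else NA_real_
    data.frame(groups[g, ], nPairs = nP, meanZ = mean(v), sem = sem,
               ciLow = mean(v) - halfW, ciHigh = mean(v) + halfW,
               pctWithCluster = 100 * mean(long$hasCluster[sel]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Epoch vs pre-trial-baseline synchrony by category preference
#'
#' For each pair, computes the band/epoch-averaged PPC separately for the two
#' categories and for the fixation baseline (the last 750 ms of the fixation
#' window); the pair's preferred category is the sign of the
#' Above-minus-Below epoch difference. Across pairs, paired two-tailed
#' t-tests compare epoch synchrony with baseline synchrony separately for
#' preferred and non-preferred categories.
#'
#' @param decomposition a [SpectralDecomposition-class].
#' @param pairs 2-column matrix of channel id pairs.
#' @param labels per-trial category labels (two levels; first sorted level is
#'   treated as "Above" for the preference sign).
#' @param band,epoch band and epoch of interest.
#' @param timeline event times.
#' @param baselineDurS duration of the fixation baseline (s).
#' @return list with `pairTable` (per-pair averages) and `tests` (paired
#'   t-test results for preferred and non-preferred categories).
#' @export
baselineSynchronyComparison <- function(decomposition, pairs, labels,
                                        band = "beta", epoch = "category",
                                        timeline = defaultTimeline(),
                                        baselineDurS = 0.75) {
  bl <- bandLimits(band)
  win <- epochWindowFor(epoch, timeline)
  base <- c(timeline[["gapOn"]] - baselineDurS, timeline[["gapOn"]])
  fSel <- decomposition@freq >= bl[1] & decomposition@freq <= bl[2]
  tEpoch <- decomposition@time >= win[1] & decomposition@time <= win[2]
  tBase <- decomposition@time >= base[1] & decomposition@time <= base[2]
  if (!any(tBase)) stop("decomposition lacks the fixation baseline window")
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  stopifnot(length(lev) == 2)

  avgPpc <- function(U, tSel) {
    sub <- U[, fSel, tSel, drop = FALSE]
    mean(.ppcOfPhasors(sub))
  }
  tab <- lapply(seq_len(nrow(pairs)), function(i) {
    U <- .pairPhasors(decomposition, pairs[i, 1], pairs[i, 2])
    iA <- which(labels == lev[1]); iB <- which(labels == lev[2])
    eA <- avgPpc(U[iA, , , drop = FALSE], tEpoch)
    eB <- avgPpc(U[iB, , , drop = FALSE], tEpoch)
    bA <- avgPpc(U[iA, , , drop = FALSE], tBase)
    bB <- avgPpc(U[iB, , , drop = FALSE], tBase)
    pref <- if (eA >= eB) lev[1] else lev[2]
    data.frame(chanA = pairs[i, 1], chanB = pairs[i, 2], preferred = pref,
               epochPref = max(eA, eB), epochNonPref = min(eA, eB),
               basePref = if (pref == lev[1]) bA else bB,
               baseNonPref = if (pref == lev[1]) bB else bA)
  })
  tab <- do.call(rbind, tab)
  tests <- data.frame(
    category = c("preferred", "nonpreferred"),
    meanEpoch = c(mean(tab$epochPref), mean(tab$epochNonPref)),
    meanBaseline = c(mean(tab$basePref), mean(tab$baseNonPref)))
  if (nrow(tab) > 1) {
    tp <- stats::t.test(tab$epochPref, tab$basePref, paired = TRUE)
    tn <- stats::t.test(tab$epochNonPref, tab$baseNonPref, paired = TRUE)
    tests$t <- c(tp$statistic, tn$statistic)
    tests$p <- c(tp$p.value, tn$p.value)
  }
  list(pairTable = tab, tests = tests)
}
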