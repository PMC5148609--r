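## Spiking selectivity: binned and smoothed firing rates, baseline z-scoring,
## bias-corrected omega-squared percent explained variance, and population
## significance summaries.

#' Binned, smoothed, baseline z-scored firing rates
#'
#' Spike counts on contiguous 20 ms bins are converted to spikes/s, convolved
#' with a Gaussian window (200 ms full width at half maximum by default;
#' switchable to the standard-deviation convention), and z-transformed per
#' unit using the mean and variance of the smoothed rate over the 3 s
#' pre-trial baseline, pooled across trials.
#'
#' @param session a [SessionRecording-class].
#' @param electrode electrode id.
#' @param unit unit id, or `NULL` for all spikes on the electrode (pooled
#'   multi-unit; see [pooledMultiunitRates()]).
#' @param binMs bin width (ms).
#' @param smoothMs Gaussian width (ms).
#' @param widthIs "fwhm" (default) or "sd" convention for `smoothMs`.
#' @param baselineWindow `c(t0, t1)` of the pre-trial baseline (s).
#' @param window analysis window `c(t0, t1)` (s); defaults to the whole
#'   recording.
#' @return a [RateSeries-class]; errors if the baseline variance is zero
#'   (silent unit).
#' @export
smoothedRates <- function(session, electrode, unit = NULL, binMs = 20,
                          smoothMs = 200, widthIs = c("fwhm", "sd"),
                          baselineWindow = NULL, window = NULL) {
  widthIs <- match.arg(widthIs)
  tl <- session@groundTruth@timeline
  if (is.null(baselineWindow))
    baselineWindow <- c(tl[["baselineStart"]], tl[["fixOn"]])
  if (is.null(window)) window <- range(session@time)
  sp <- session@spikes
  sp <- sp[sp$electrode == electrode, ]
  if (!is.null(unit)) sp <- sp[sp$unit == unit, ]
  nTrial <- nrow(session@trials)
  edges <- seq(window[1], window[2], by = binMs / 1000)
  centers <- edges[-length(edges)] + binMs / 2000
  nb <- length(centers)
  counts <- matrix(0, nTrial, nb)
  if (nrow(sp)) {
    inWin <- sp$time >= window[1] & sp$time < edges[length(edges)]
    sp <- sp[inWin, ]
    b <- findInterval(sp$time, edges, rightmost.closed = FALSE)
    tab <- table(factor(sp$trial, levels = seq_len(nTrial)),
                 factor(b, levels = seq_len(nb)))
    counts <- matrix(as.numeric(tab), nTrial, nb)
  }
  rate <- counts / (binMs / 1000)
  k <- gaussianKernel(smoothMs, binMs, widthIs)
  sm <- t(apply(rate, 1, function(r)
    stats::filter(c(rep(r[1], length(k)), r, rep(r[nb], length(k))),
                  k, sides = 2)[(length(k) + 1):(length(k) + nb)]))
  base <- centers >= baselineWindow[1] & centers <= baselineWindow[2]
  if (!any(base)) stop("analysis window does not cover the baseline")
  mu <- mean(sm[, base]); sdv <- stats::sd(as.vector(sm[, base]))
  if (sdv == 0) {
    warning("zero baseline variance (silent unit); z-rates undefined, ",
            "exclude this unit from selectivity analyses")
    z <- matrix(NA_real_, nrow(sm), ncol(sm))
  } else z <- (sm - mu) / sdv
  methods::new("RateSeries",
               id = paste0("e", electrode, if (!is.null(unit)) paste0("u", unit) else "-mu"),
               rate = sm, zRate = z,
               binCenters = centers, binMs = binMs,
               kernel = sprintf("gaussian %s=%g ms", widthIs, smoothMs))
}

#' Pooled multi-unit rates of an electrode
#'
#' Pools the spikes of all isolated units recorded on one electrode and
#' computes [smoothedRates()] on the union train.
#'
#' @inheritParams smoothedRates
#' @param ... passed to [smoothedRates()].
#' @return a [RateSeries-class].
#' @export
pooledMultiunitRates <- function(session, electrode, ...) {
  sp <- session@spikes
  if (!any(sp$electrode == electrode)) stop("electrode has no units")
  smoothedRates(session, electrode, unit = NULL, ...)
}

#' Bias-corrected omega-squared percent explained variance
#'
#' Per time bin (column), the omega-squared effect size of the grouping:
#' `w2 = (SS_between - df_between * MSE) / (SS_total + MSE) * 100` with
#' `df_between = k - 1`. Unlike eta-squared, the estimator is unbiased under
#' the null, so it may be slightly negative and is deliberately not clipped
#' at zero. Bins with zero total variance are defined as 0.
#'
#' @param x numeric matrix (trial x bin), e.g. the `zRate` of a
#'   [RateSeries-class], or a numeric vector (one bin).
#' @param labels per-trial group labels (>= 2 groups, each with >= 2 trials).
#' @return numeric vector of percent explained variance per bin.
#' @export
omegaPev <- function(x, labels) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  lev <- unique(labels)
  k <- length(lev)
  if (k < 2) stop("need at least 2 groups")
  ns <- vapply(lev, function(l) sum(labels == l), numeric(1))
  if (any(ns < 2)) stop("each group needs at least 2 trials")
  n <- nrow(x)
  grand <- colMeans(x)
  ssTot <- colSums(sweep(x, 2, grand)^2)
  ssB <- numeric(ncol(x))
  for (l in lev) {
    sel <- labels == l
    gm <- colMeans(x[sel, , drop = FALSE])
    ssB <- ssB + sum(sel) * (gm - grand)^2
  }
  ssW <- ssTot - ssB
  mse <- ssW / (n - k)
  w2 <- (ssB - (k - 1) * mse) / (ssTot + mse) * 100
  w2[ssTot + mse == 0] <- 0
  w2
}

#' Population significance of spiking selectivity
#'
#' Two complementary summaries of a population of per-unit PEV time courses:
#' (a) the population trace (mean +/- SEM) with per-bin one-sided one-sample
#' t-tests of PEV > 0 across units, significant bars requiring
#' `p < alphaPop` sustained for at least `minRunMs`; and (b) the percentage
#' of units individually significant per bin at `p < alphaUnit`, assessed by
#' per-unit label-permutation tests on the omega-PEV statistic.
#'
#' @param zRates list of trial x bin matrices (one per unit/electrode),
#'   sharing the bin grid.
#' @param labels per-trial category labels.
#' @param binMs bin width (ms).
#' @param alphaPop,minRunMs population-trace criteria.
#' @param alphaUnit per-unit criterion.
#' @param nPerm label permutations per unit.
#' @param seed RNG seed.
#' @return list with `pev` (unit x bin matrix), `populationMean`, `sem`,
#'   `pPop`, `sigMask` (logical per bin), `pctSignificant` (percent of units
#'   with p < alphaUnit per bin).
#' @export
selectivitySignificance <- function(zRates, labels, binMs = 20,
                                    alphaPop = 0.05, minRunMs = 100,
                                    alphaUnit = 0.01, nPerm = 200, seed = 1) {
  nUnit <- length(zRates)
  if (nUnit < 2) stop("population requires at least 2 units")
  minRun <- round(minRunMs / binMs)
  if (minRun < 2) stop("minRunMs must span at least 2 bins")
  pev <- t(vapply(zRates, omegaPev, numeric(ncol(zRates[[1]])), labels = labels))
  popMean <- colMeans(pev)
  sem <- .colSds(pev) / sqrt(nUnit)
  tStat <- popMean / sem
  pPop <- stats::pt(tStat, df = nUnit - 1, lower.tail = FALSE)
  sig <- pPop < alphaPop
  sig[is.na(sig)] <- FALSE
  r <- rle(sig)
  drop <- r$values & r$lengths < minRun
  r$values[drop] <- FALSE
  sigMask <- inverse.rle(r)

  set.seed(seed)
  n <- length(labels)
  pctSig <- matrix(0, nUnit, ncol(pev))
  for (u in seq_len(nUnit)) {
    exceed <- matrix(0, 1, ncol(pev))
    for (s in seq_len(nPerm)) {
      permPev <- omegaPev(zRates[[u]], labels[sample.int(n)])
      exceed <- exceed + (permPev >= pev[u, ])
    }
    pUnit <- (1 + exceed) / (nPerm + 1)
    pctSig[u, ] <- pUnit < alphaUnit
  }
  list(pev = pev, populationMean = popMean, sem = sem, pPop = pPop,
       sigMask = sigMask, pctSignificant = 100 * colMeans(pctSig))
}
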