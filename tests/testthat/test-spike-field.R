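# A small session whose spike phases are fully controlled: one LFP channel
# whose wavelet phases come from band-noise, spikes placed at chosen times.
makePlvSession <- function(nTrial = 10, spikeTimes, sRate = 1000) {
  tl <- defaultTimeline()
  tg <- seq(tl[["baselineStart"]], tl[["end"]], by = 1 / sRate)
  lfpArr <- array(rnorm(nTrial * length(tg), sd = 0.05), c(1, nTrial, length(tg)))
  spk <- do.call(rbind, lapply(seq_len(nTrial), function(tr)
    data.frame(electrode = 1L, unit = 1L, trial = tr, time = spikeTimes[[tr]])))
  methods::new("SessionRecording", lfp = lfpArr, time = tg, sRate = sRate,
               spikes = spk, channels = data.frame(id = 1L, area = "AIP"),
               trials = data.frame(trial = seq_len(nTrial)),
               groundTruth = smallConfig(nTrials = as.integer(nTrial)))
}

test_that("raw PLV hits its exact landmark values", {
  expect_equal(plvOfPhases(c(0, pi / 2, pi, 3 * pi / 2)), 0, tolerance = 1e-12)
  expect_equal(plvOfPhases(rep(1.234, 7)), 1)
})

test_that("PLV machinery returns 1 for spikes at a constant LFP phase", {
  ## deterministic 20 Hz LFP; spikes at the same phase every cycle
  sRate <- 1000
  tl <- defaultTimeline()
  tg <- seq(tl[["baselineStart"]], tl[["end"]], by = 1 / sRate)
  nTrial <- 6
  lfpArr <- array(0, c(1, nTrial, length(tg)))
  spikeTimes <- vector("list", nTrial)
  for (tr in seq_len(nTrial)) {
    lfpArr[1, tr, ] <- sin(2 * pi * 20 * tg)
    spikeTimes[[tr]] <- seq(0.025, 1.275, by = 1 / 20)   # one per cycle
  }
  s <- makePlvSession(nTrial, spikeTimes)
  s@lfp <- lfpArr
  cl <- preprocessLfp(s, evokedRemoval = FALSE)
  dec <- morletTransform(cl, freq = c(20), timeRange = c(-0.2, 1.4))
  res <- plvZ(s, 1, dec, 1, epoch = "category", nPerm = 20)
  expect_gt(res@plv[1], 0.98)
})

test_that("modulation-depth recovery: PLV approximates m/2", {
  sRate <- 1000
  tl <- defaultTimeline()
  tg <- seq(tl[["baselineStart"]], tl[["end"]], by = 1 / sRate)
  fosc <- 2 * 2^(0.1 * 36)     # a grid frequency in the beta band
  m <- 0.6
  nTrial <- 40
  set.seed(30)
  spikeTimes <- vector("list", nTrial)
  lfpArr <- array(0, c(1, nTrial, length(tg)))
  for (tr in seq_len(nTrial)) {
    ph0 <- runif(1, -pi, pi)
    phase <- 2 * pi * fosc * tg + ph0
    lfpArr[1, tr, ] <- sin(phase) + rnorm(length(tg), sd = 0.05)
    spikeTimes[[tr]] <- synthSpikeTrain(tg, rep(45, length(tg)),
                                        modDepth = m, phase = phase - pi / 2)
  }
  s <- makePlvSession(nTrial, spikeTimes)
  s@lfp <- lfpArr
  cl <- preprocessLfp(s, evokedRemoval = FALSE)
  dec <- morletTransform(cl, freq = morletFrequencyGrid()[35:39],
                         timeRange = c(-4.1, 2.2))
  res <- plvZ(s, 1, dec, 1, epoch = "category", nPerm = 10)
  expect_gt(sum(res@nSpikes), 2000)
  k <- which.min(abs(res@freq - fosc))
  expect_lt(abs(res@plv[k] - m / 2), 0.03)
})

test_that("permutation z discounts spurious locking at low spike counts", {
  ## few spikes inflate raw PLV; the LFP-permutation z stays centred on 0
  cfg <- generatorConfig(
    nChannels = c(AIP = 1L, cPFC = 1L), nTrials = 30L,
    couplingSpec = data.frame(chanA = 1L, chanB = 2L, band = "beta",
                              epoch = "category", kappaAbove = 0,
                              kappaBelow = 0, amplitude = 0.08),
    spikeSpec = data.frame(electrode = 1:2, nUnits = 1L, rate = 7.7,
                           gainAbove = 1, gainBelow = 1, modDepth = 0,
                           prefPhase = 0, targetChannel = 1:2,
                           targetBand = "beta"),
    seed = 61L)
  s <- generateSession(cfg)
  cl <- preprocessLfp(s)
  dec <- morletTransform(cl, freq = morletFrequencyGrid()[27:37],
                         channels = 1, timeRange = c(-0.1, 1.4))
  ## ~10 spikes per trial in the 1.3 s epoch
  res <- plvZ(s, 2, dec, 1, epoch = "category", nPerm = 200, seed = 62)
  expect_gt(mean(res@nSpikes), 5)
  expect_gt(mean(res@plv), 0.05)               # raw PLV inflated at low counts
  zs <- res@z[is.finite(res@z)]
  expect_lt(abs(mean(zs)), 3 / sqrt(length(zs)) * 1.5 + 0.5)
  expect_error(plvZ(s, 2, dec, 1, epoch = "baseline"), "no spikes|fewer")
})

test_that("directionality contrast is antisymmetric and null for identical input", {
  cfg <- smallConfig(nTrials = 20L, seed = 63L)
  s <- generateSession(cfg)
  cl <- preprocessLfp(s)
  dec <- morletTransform(cl, freq = morletFrequencyGrid()[seq(1, 61, 6)],
                         timeRange = c(-0.1, 1.4))
  p12 <- lapply(1:3, function(i) plvZ(s, 1, dec, 2, nPerm = 50, seed = i))
  p21 <- lapply(1:3, function(i) plvZ(s, 2, dec, 1, nPerm = 50, seed = i + 10))
  same <- directionalityContrast(p12, p12)
  expect_true(all(!same$perFrequency$sig))
  ab <- directionalityContrast(p12, p21)
  ba <- directionalityContrast(p21, p12)
  expect_equal(ab$perFrequency$meanDiff, -ba$perFrequency$meanDiff,
               tolerance = 1e-12)
  expect_error(directionalityContrast(p12, p21[1:2]), "matched")
})

test_that("one-way locking produces a one-way, band-confined contrast", {
  nP <- 8
  coup <- data.frame(chanA = 1:nP, chanB = nP + (1:nP), band = "beta",
                     epoch = "category", kappaAbove = 0, kappaBelow = 0,
                     amplitude = 0.08)
  ss <- rbind(
    data.frame(electrode = 1:nP, nUnits = 1L, rate = 15, gainAbove = 1,
               gainBelow = 1, modDepth = 0, prefPhase = 0,
               targetChannel = 1:nP, targetBand = "beta"),
    data.frame(electrode = nP + (1:nP), nUnits = 1L, rate = 15, gainAbove = 1,
               gainBelow = 1, modDepth = 0.4, prefPhase = 0,
               targetChannel = 1:nP, targetBand = "beta"))
  cfg <- generatorConfig(nChannels = c(AIP = as.integer(nP), cPFC = as.integer(nP)),
                         nTrials = 36L, couplingSpec = coup, spikeSpec = ss,
                         seed = 64L)
  s <- generateSession(cfg)
  cl <- preprocessLfp(s)
  dec <- morletTransform(cl, timeRange = c(-0.1, 1.4))
  locked <- lapply(1:nP, function(i)
    plvZ(s, nP + i, dec, i, epoch = "category", nPerm = 100, seed = i))
  unlocked <- lapply(1:nP, function(i)
    plvZ(s, i, dec, nP + i, epoch = "category", nPerm = 100, seed = 40 + i))
  dc <- directionalityContrast(locked, unlocked, band = c(22, 32))
  expect_gt(dc$bandTest$meanAB, dc$bandTest$meanBA)
  expect_lt(dc$bandTest$p, 0.05)
  pf <- dc$perFrequency
  outOfBand <- pf$freq < 14 | pf$freq > 36
  expect_lt(mean(pf$sig[outOfBand] & pf$meanDiff[outOfBand] > 0), 0.12)
})

test_that("decile selection is deterministic with documented tie handling", {
  sc <- setNames(c(10:1), letters[1:10])
  expect_equal(topDecileSelection(sc)$ids, "a")
  expect_equal(topDecileSelection(sc, side = "bottom")$ids, "j")
  sc20 <- setNames(rnorm(20), paste0("e", 1:20))
  expect_length(topDecileSelection(sc20)$ids, 2)
  tie <- setNames(rep(1, 20), paste0("e", 1:20))
  selTie <- topDecileSelection(tie)
  expect_equal(selTie$ids, c("e1", "e2"))
  expect_true(selTie$tieFlag)
  expect_warning(topDecileSelection(sc[1:5]), "fewer than 10")
})

test_that("group PLV comparison separates selective from non-selective spikes", {
  set.seed(65)
  freq <- morletFrequencyGrid()[seq(21, 41, 2)]
  inBand <- freq >= 16 & freq <= 32
  zA <- matrix(rnorm(8 * length(freq)), 8)
  zA[, inBand] <- zA[, inBand] + 2
  zB <- matrix(rnorm(8 * length(freq)), 8)
  res <- selectiveSpikePlvAnalysis(zA, zB, freq)
  expect_gt(mean(res$sig[inBand]), 0.5)
  expect_lt(mean(res$sig[!inBand]), 0.3)
  swapped <- selectiveSpikePlvAnalysis(zB, zA, freq)
  expect_equal(swapped$diff, -res$diff, tolerance = 1e-12)
  expect_error(selectiveSpikePlvAnalysis(zA[0, , drop = FALSE], zB, freq),
               "empty")
})

test_that("selectivity-synchrony correlation behaves at its landmarks", {
  x <- 1:10
  res <- pevPlvCorrelation(x, 2 * x + 3)
  expect_equal(res$estimate[res$method == "pearson"], 1)
  expect_error(pevPlvCorrelation(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(pevPlvCorrelation(1:2, 1:2), "at least 3")
  set.seed(66)
  r <- replicate(50, {
    pevPlvCorrelation(rnorm(30), rnorm(30))$estimate[1]
  })
  expect_lt(mean(abs(r) > 2 / sqrt(30)), 0.2)
})
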