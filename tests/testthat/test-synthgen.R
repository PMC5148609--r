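test_that("generation is deterministic given the seed", {
  cfg <- smallConfig(nTrials = 8L, seed = 42L)
  a <- generateSession(cfg)
  b <- generateSession(cfg)
  expect_identical(a@lfp, b@lfp)
  expect_identical(a@spikes, b@spikes)
  expect_identical(a@trials, b@trials)
})

test_that("config validity catches inconsistent specifications", {
  expect_error(smallConfig(lapseRate = 1.2), "lapseRate")
  bad <- data.frame(chanA = 1L, chanB = 9L, band = "beta", epoch = "category",
                    kappaAbove = 1, kappaBelow = 1, amplitude = 0.05)
  expect_error(generatorConfig(couplingSpec = bad,
                               nChannels = c(AIP = 1L, cPFC = 1L)),
               "unknown channel")
  badSpk <- data.frame(electrode = 1L, nUnits = 1L, rate = 5, gainAbove = 1,
                       gainBelow = 1, modDepth = 1.2, prefPhase = 0,
                       targetChannel = 1L, targetBand = "beta")
  expect_error(generatorConfig(spikeSpec = badSpk), "modulation depth")
})

test_that("spike trains realise the intended Poisson statistics", {
  tg <- seq(0, 50, by = 1e-3)
  set.seed(9)
  n <- length(synthSpikeTrain(tg, rep(12, length(tg))))
  expect_lt(abs(n - 12 * 50), 3 * sqrt(12 * 50))
  expect_error(synthSpikeTrain(tg, rep(-1, length(tg))), "negative rate")
  expect_error(synthSpikeTrain(tg, rep(1, length(tg)), modDepth = 1),
               "modDepth")
  expect_length(synthSpikeTrain(tg, rep(0, length(tg))), 0)

  ## gain scales the expected count
  set.seed(10)
  n2 <- length(synthSpikeTrain(tg, rep(12, length(tg)), gain = 2))
  expect_lt(abs(n2 - 24 * 50), 3 * sqrt(24 * 50))
})

test_that("LFP background carries the configured 1/f decay and 60 Hz line", {
  cfg <- smallConfig(nTrials = 6L, seed = 7L)
  s <- generateSession(cfg)
  x <- s@lfp[2, 1, ]   # channel without coupled oscillator injections
  sp <- stats::spec.pgram(x, taper = 0, plot = FALSE, detrend = TRUE)
  f <- sp$freq * s@sRate
  sel <- f >= 3 & f <= 45                   # away from line and evoked content
  fit <- stats::lm(log(sp$spec[sel]) ~ log(f[sel]))
  expect_lt(abs(-coef(fit)[2] - cfg@pinkExponent), 0.2)
  lineBin <- which.min(abs(f - 60))
  neighborhood <- sp$spec[abs(f - 60) < 4 & abs(f - 60) > 1.5]
  expect_gt(sp$spec[lineBin], 5 * median(neighborhood))
})

test_that("evoked transient is identical across trials and recoverable", {
  cfg <- smallConfig(nTrials = 40L, seed = 8L)
  s <- generateSession(cfg)
  mu <- colMeans(s@lfp[2, , ])
  tpl <- catsync:::.evokedTemplate(s@time, 0, cfg@evokedAmplitude) +
    catsync:::.evokedTemplate(s@time, 1.3, cfg@evokedAmplitude)
  resid <- mu - tpl
  ## residual is background noise averaged over trials: sd ~ rms/sqrt(n)
  expect_lt(stats::sd(resid[s@time < -0.5]),
            3 * cfg@noiseRms / sqrt(cfg@nTrials))
  peakRegion <- s@time > 0 & s@time < 0.3
  expect_gt(max(abs(mu[peakRegion])), cfg@evokedAmplitude / 2)
})

test_that("injected phase coupling matches the von Mises pair formula", {
  ## high-SNR configuration so wavelet phase tracks the oscillator phase
  kappa <- 4
  cfg <- generatorConfig(
    nChannels = c(AIP = 1L, cPFC = 1L), nTrials = 60L,
    noiseRms = 0.01, lineNoiseAmplitude = 0, evokedAmplitude = 0,
    couplingSpec = data.frame(chanA = 1L, chanB = 2L, band = "beta",
                              epoch = "category", kappaAbove = kappa,
                              kappaBelow = kappa, amplitude = 0.1),
    spikeSpec = data.frame(electrode = 1:2, nUnits = 1L, rate = 5,
                           gainAbove = 1, gainBelow = 1, modDepth = 0,
                           prefPhase = 0, targetChannel = 1:2,
                           targetBand = "beta"),
    seed = 21L)
  s <- generateSession(cfg)
  cl <- preprocessLfp(s)
  dec <- morletTransform(cl, freq = morletFrequencyGrid()[29:35],
                         timeRange = c(0.3, 1.0))
  pm <- ppcMap(dec, 1, 2, nSurrogates = 0)
  measured <- mean(pm@ppcRaw)
  expected <- catsync:::vonMisesPairPPC(kappa)
  ## Monte-Carlo oracle: direct simulation of von Mises phase differences
  set.seed(1)
  mc <- replicate(200, ppc(rVonMises(60, 0, kappa) - rVonMises(60, 0, kappa)))
  expect_lt(abs(mean(mc) - expected), 0.02)   # oracle agrees with formula
  expect_lt(abs(measured - expected), 3 * stats::sd(mc))
})

test_that("sessions round-trip losslessly through the text container", {
  cfg <- smallConfig(nTrials = 5L, seed = 31L)
  s <- generateSession(cfg)
  d <- withr::local_tempdir()
  writeSession(s, file.path(d, "ses"))
  r <- readSession(file.path(d, "ses"))
  expect_identical(r@lfp, s@lfp)
  expect_equal(r@time, s@time)
  expect_identical(r@spikes$time, s@spikes$time)
  expect_identical(as.data.frame(r@trials), as.data.frame(s@trials))
  expect_identical(r@channels$area, s@channels$area)
  expect_equal(r@groundTruth@couplingSpec, s@groundTruth@couplingSpec)

  ## truncation is an error, not a partial session
  lf <- file.path(d, "ses", "lfp_001.csv")
  ln <- readLines(lf)
  writeLines(ln[1:3], lf)
  expect_error(readSession(file.path(d, "ses")), "truncated|inconsistent")

  ## schema mismatch is a named error
  writeSession(s, file.path(d, "ses2"))
  meta <- jsonlite::read_json(file.path(d, "ses2", "meta.json"))
  meta$schema <- "other-schema"
  jsonlite::write_json(meta, file.path(d, "ses2", "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  expect_error(readSession(file.path(d, "ses2")), "catsync-session-1")
})

test_that("a zero-spike electrode round-trips with a flag", {
  cfg <- smallConfig(nTrials = 4L, seed = 32L)
  s <- generateSession(cfg)
  s@spikes <- s@spikes[s@spikes$electrode != 2, ]
  d <- withr::local_tempdir()
  writeSession(s, file.path(d, "z"))
  expect_warning(readSession(file.path(d, "z")), "without spikes")
})
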