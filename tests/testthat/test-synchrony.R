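test_that("pairwise PPC equals the resultant identity to machine precision", {
  set.seed(2)
  worst <- 0
  for (i in 1:1000) {
    n <- sample(2:40, 1)
    phi <- runif(n, -pi, pi)
    worst <- max(worst, abs(ppc(phi) - ppcPairwiseSum(phi)))
  }
  expect_lt(worst, 1e-12)
})

test_that("PPC attains its documented landmark values", {
  expect_equal(ppc(rep(0.3, 10)), 1)
  expect_equal(ppc(c(0, pi)), -1)
  set.seed(3)
  v <- ppc(rVonMises(1000, 1, 2))
  expect_lt(abs(v - (besselI(2, 1) / besselI(2, 0))^2), 0.03)  # ~0.487
  expect_error(ppc(0.2), "at least 2")
})

test_that("PPC maps are symmetric in the pair and invariant to joint reordering", {
  set.seed(4)
  ph <- list(`1` = randomPhasors(12, 4, 30), `2` = randomPhasors(12, 4, 30))
  dec <- makeDecomposition(ph)
  ab <- ppcMap(dec, 1, 2, nSurrogates = 0)
  ba <- ppcMap(dec, 2, 1, nSurrogates = 0)
  expect_equal(ab@ppcRaw, ba@ppcRaw, tolerance = 1e-12)

  ord <- sample(12)
  dec2 <- makeDecomposition(lapply(ph, function(a) a[ord, , , drop = FALSE]))
  expect_equal(ppcMap(dec2, 1, 2, nSurrogates = 0)@ppcRaw, ab@ppcRaw,
               tolerance = 1e-12)
  expect_error(ppcMap(makeDecomposition(lapply(ph, function(a)
    a[1, , , drop = FALSE])), 1, 2), "at least 2")
})

test_that("surrogate bias correction centres null PPC on zero at small N", {
  set.seed(5)
  vals <- vapply(1:100, function(i) {
    dec <- makeDecomposition(list(`1` = randomPhasors(20, 3, 25),
                                  `2` = randomPhasors(20, 3, 25)))
    mean(ppcMap(dec, 1, 2, nSurrogates = 200, seed = i)@ppcCorrected)
  }, numeric(1))
  se <- stats::sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 3 * se)
})

test_that("selectivity permutation null is calibrated", {
  set.seed(6)
  dec <- makeDecomposition(list(`1` = randomPhasors(40, 20, 100),
                                `2` = randomPhasors(40, 20, 100)))
  labels <- rep(c("Above", "Below"), each = 20)
  zm <- categorySelectivityZ(dec, 1, 2, labels, nPerm = 200, seed = 7)
  fpr <- mean(zm@p < 0.05)
  expect_gt(fpr, 0.03); expect_lt(fpr, 0.07)           # 5% +/- 2% over 2000 bins
  expect_lt(abs(mean(zm@z, na.rm = TRUE)), 0.1)
  expect_lt(abs(stats::sd(as.vector(zm@z), na.rm = TRUE) - 1), 0.1)
  ## no cluster survives on independent null bins
  expect_equal(sum(significantClusters(zm)@clusterMask), 0)
})

test_that("selectivity is symmetric in the category labels", {
  set.seed(8)
  dec <- makeDecomposition(list(`1` = randomPhasors(16, 3, 40),
                                `2` = randomPhasors(16, 3, 40)))
  labels <- rep(c("Above", "Below"), each = 8)
  z1 <- categorySelectivityZ(dec, 1, 2, labels, nPerm = 100, seed = 9)
  swapped <- ifelse(labels == "Above", "Below", "Above")
  z2 <- categorySelectivityZ(dec, 1, 2, swapped, nPerm = 100, seed = 9)
  expect_equal(z1@D, z2@D, tolerance = 1e-12)
  expect_equal(z1@z, z2@z, tolerance = 1e-12)
})

test_that("an injected concentration difference produces strong z in its bins", {
  set.seed(10)
  nTrial <- 60
  cp <- coupledPhasors(nTrial / 2, 4, 60, kappa = 6)   # Above: tight coupling
  nullA <- randomPhasors(nTrial / 2, 4, 60)            # Below: none
  nullB <- randomPhasors(nTrial / 2, 4, 60)
  join <- function(a, b) {
    out <- array(0i, dim = c(nTrial, 4, 60)); out[1:30, , ] <- a
    out[31:60, , ] <- b; out
  }
  dec <- makeDecomposition(list(`1` = join(cp$A, nullA),
                                `2` = join(cp$B, nullB)))
  labels <- rep(c("Above", "Below"), each = 30)
  zm <- categorySelectivityZ(dec, 1, 2, labels, nPerm = 200, seed = 11)
  expect_gt(mean(zm@z, na.rm = TRUE), 3)
})

test_that("the cluster rule keeps only rectangles wide and long enough", {
  sRate <- 1000 / 3
  base <- matrix(0.5, 10, 200)
  ms <- function(k) round(k / 1000 * sRate)
  b1 <- base; b1[4:6, 50 + seq_len(ms(100))] <- 0.01      # 100 ms x 3 bins
  b2 <- base; b2[3:7, 50 + seq_len(ms(50))] <- 0.01       # 50 ms x 5 bins
  b3 <- base; b3[4:5, 50 + seq_len(ms(100))] <- 0.01      # 100 ms x 2 bins
  m1 <- significantClusters(b1, sRate = sRate)
  expect_equal(sum(m1), 3 * ms(100))
  expect_true(all(which(rowSums(m1) > 0) == 4:6))
  expect_equal(sum(significantClusters(b2, sRate = sRate)), 0)
  expect_equal(sum(significantClusters(b3, sRate = sRate)), 0)
  expect_error(significantClusters(b1, minDurationMs = 2, sRate = sRate),
               "2 time steps")
})

test_that("population combination sharpens consistent selectivity", {
  set.seed(12)
  mkNull <- function() {
    dec <- makeDecomposition(list(`1` = randomPhasors(20, 5, 50),
                                  `2` = randomPhasors(20, 5, 50)))
    categorySelectivityZ(dec, 1, 2, rep(c("A", "B"), each = 10),
                         nPerm = 100, seed = sample.int(1e6, 1))
  }
  maps <- replicate(4, mkNull(), simplify = FALSE)
  popd <- populationSelectivityMap(maps)
  expect_lt(abs(mean(popd@z)), 0.15)
  expect_lt(abs(stats::sd(as.vector(popd@z)) - 1), 0.2)
})

test_that("band/epoch summary reports group means, SEM and cluster rates", {
  set.seed(13)
  tGrid <- seq(-0.2, 2.3, by = 3 / 1000)
  nt <- length(tGrid)
  mk <- function() {
    dec <- makeDecomposition(list(`1` = randomPhasors(16, 8, nt),
                                  `2` = randomPhasors(16, 8, nt)),
                             freq = c(2, 2.6, 3.4, 4, 16, 20, 26, 32),
                             time = tGrid)
    significantClusters(categorySelectivityZ(
      dec, 1, 2, rep(c("A", "B"), each = 8), nPerm = 50,
      seed = sample.int(1e6, 1)))
  }
  tab <- selectivitySummary(list(mk(), mk(), mk()))
  expect_equal(nrow(tab), 4)   # 2 bands x 2 epochs, one area pair/dimension
  expect_true(all(is.finite(tab$sem)))
  expect_true(all(tab$nPairs == 3))
  one <- selectivitySummary(list(mk()))
  expect_true(all(is.na(one$sem)))
})

test_that("baseline comparison isolates epoch-confined coupling", {
  kap <- 4
  mkSess <- function(kAbove, kBelow, seed) {
    generatorConfig(
      nChannels = c(AIP = 1L, cPFC = 1L), nTrials = 40L,
      noiseRms = 0.02, lineNoiseAmplitude = 0, evokedAmplitude = 0,
      couplingSpec = data.frame(chanA = 1L, chanB = 2L, band = "beta",
                                epoch = "category", kappaAbove = kAbove,
                                kappaBelow = kBelow, amplitude = 0.1),
      spikeSpec = data.frame(electrode = 1:2, nUnits = 1L, rate = 4,
                             gainAbove = 1, gainBelow = 1, modDepth = 0,
                             prefPhase = 0, targetChannel = 1:2,
                             targetBand = "beta"),
      seed = seed)
  }
  s <- generateSession(mkSess(kap, 0, 22L))
  cl <- preprocessLfp(s)
  dec <- morletTransform(cl, freq = morletFrequencyGrid()[29:35])
  res <- baselineSynchronyComparison(dec, cbind(1, 2), s@trials$categoryAB)
  expect_equal(res$pairTable$preferred, "Above")
  expect_gt(res$pairTable$epochPref, res$pairTable$basePref + 0.1)
  expect_lt(abs(res$pairTable$basePref), 0.1)

  ## swapping the injected kappas flips the preferred category
  s2 <- generateSession(mkSess(0, kap, 22L))
  dec2 <- morletTransform(preprocessLfp(s2), freq = morletFrequencyGrid()[29:35])
  res2 <- baselineSynchronyComparison(dec2, cbind(1, 2), s2@trials$categoryAB)
  expect_equal(res2$pairTable$preferred, "Below")
})
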