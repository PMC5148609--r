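# Fixture builders shared across test files. All fixtures are generated in
# code; sizes are kept small so the whole suite runs quickly.

# Synthetic spectral decomposition with externally supplied unit phasors.
# phasors: named list of complex arrays [trial x freq x time].
makeDecomposition <- function(phasors, freq = NULL, time = NULL,
                              sRate = 1000 / 3, areas = NULL) {
  d <- dim(phasors[[1]])
  if (is.null(freq)) freq <- seq(10, 10 + d[2] - 1)
  if (is.null(time)) time <- seq(0, by = 1 / sRate, length.out = d[3])
  if (is.null(areas)) areas <- rep("AIP", length(phasors))
  methods::new("SpectralDecomposition",
               coef = phasors, freq = as.numeric(freq), time = time,
               sRate = sRate, omega0 = 6,
               coi = matrix(FALSE, d[2], d[3]),
               channels = data.frame(id = as.integer(names(phasors)),
                                     area = areas),
               trials = data.frame(trial = seq_len(d[1])))
}

# iid uniform-phase phasor array (null synchrony).
randomPhasors <- function(nTrial, nFreq, nTime) {
  array(complex(modulus = 1,
                argument = stats::runif(nTrial * nFreq * nTime, -pi, pi)),
        dim = c(nTrial, nFreq, nTime))
}

# Phasor pair with a common von Mises-jittered phase at every bin: channel
# phases are latent + von Mises(0, kappa) jitter, drawn per trial (constant
# across bins), as in the generator's coupling model.
coupledPhasors <- function(nTrial, nFreq, nTime, kappa) {
  latent <- matrix(stats::runif(nTrial, -pi, pi), nTrial, nFreq * nTime)
  jA <- rVonMises(nTrial, 0, kappa)
  jB <- rVonMises(nTrial, 0, kappa)
  mk <- function(j) array(complex(modulus = 1, argument = latent + j),
                          dim = c(nTrial, nFreq, nTime))
  list(A = mk(jA), B = mk(jB))
}

# Minimal fast generator config for end-to-end tests.
smallConfig <- function(nTrials = 24L, seed = 1L, ...) {
  generatorConfig(nChannels = c(AIP = 1L, cPFC = 1L), nTrials = nTrials,
                  couplingSpec = data.frame(
                    chanA = 1L, chanB = 2L, band = "beta", epoch = "category",
                    kappaAbove = 2, kappaBelow = 0.3, amplitude = 0.06),
                  spikeSpec = data.frame(
                    electrode = 1:2, nUnits = 1L, rate = 8,
                    gainAbove = c(1, 2), gainBelow = 1, modDepth = 0,
                    prefPhase = 0, targetChannel = 1:2, targetBand = "beta"),
                  seed = seed, ...)
}
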