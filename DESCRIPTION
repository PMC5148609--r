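Package: catsync
Title: Frontoparietal Category-Selective Synchrony Analysis
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-electrode frontoparietal recordings from a
    delayed match-to-spatial-category task. Implements the task geometry and behavioral
    metrics, a seeded synthetic-session generator with known injected structure (1/f
    local field potential background, line noise, evoked transients, category-conditional
    von Mises phase coupling between channel pairs, and phase-modulated inhomogeneous
    Poisson spiking), Morlet wavelet time-frequency decomposition on a log-spaced 2-128 Hz
    grid, pairwise phase consistency (PPC) with surrogate bias correction, permutation
    z-scores of category-selective synchrony with a cluster-significance rule,
    bias-corrected omega-squared percent explained variance (wPEV) of spiking
    selectivity, and spike-field phase-locking values (PLV) with LFP-permutation
    z-scores, directionality contrasts, and selectivity-synchrony correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
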