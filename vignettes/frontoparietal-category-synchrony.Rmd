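---
title: "Category-selective frontoparietal synchrony: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Category-selective frontoparietal synchrony: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette explains the models and numerical choices behind `catsync`:
the task model, the synthetic-session generator that provides ground truth
for every estimator, and the four analysis stages (spectral decomposition,
LFP–LFP synchrony, spiking selectivity, spike–field locking). It states no
empirical result that the package's tests and `scripts/acceptance.R` do not
themselves compute.

## The task model

A trial presents a sample dot at one of 16 base positions (four per visual
quadrant; default x ∈ {±3, ±6}, y ∈ {±2, ±5} degrees of visual angle) plus a
discrete per-axis jitter of −0.5/0/+0.5°. The jitter is discrete with three
levels because only then does the sample space contain exactly
16 × 3² = 144 distinct locations, the count the task design fixes;
continuous jitter would make that count meaningless. The published design
does not print the base x coordinates; they are configurable defaults here,
while the y = ±2 rows are the attested boundary-proximal rows. The test grid
is likewise not derivable from any printed rule, so it ships as an explicit
coordinate list — by default a 24 × 26 rectangular lattice (624 locations)
whose points avoid the vertical meridian and the shifted boundary ordinates
(±4°), so that every location has a well-defined category in every frame.
Its cardinality is validated at load.

Category judgments use strict inequalities and the side-appropriate
hemi-boundary (left boundary for x < 0, right for x > 0); locations exactly
on a meridian or boundary are never displayed by the task and raise errors.
The match rule is boundary-referenced: the sample is categorized against the
*unshifted* boundaries, the test against the *shifted* ones (CW: left +4°,
right −4°; CCW reversed), and a match requires agreement. The boundary shift
therefore never changes the sample's own category — a property the test
suite asserts over all 144 locations and both shifts.

The behavioral agent responds by the true match rule except for independent
lapses. The default lapse rate of 0.0723 makes the simulated overall
accuracy match the published overall performance of 92.77% correct; it is a
study condition of the emulation, not a tuning knob. Per-location
P_ABOVE maps are reconstructed from first-test responses by inverting the
match logic: a Go response asserts that the sample's category equals the
test's shifted-frame category. The same inversion along the task-irrelevant
axis yields P_LEFT, which sits at 0.5 for any category-following agent.

## The synthetic-session generator

The generator emulates the *statistical structure* the analyses are designed
to detect, not the biophysics of cortex. Each channel's LFP (mV, 1 kHz) is a
sum of:

- **1/f^α background** (α = 1 by default, RMS 0.1 mV), realized by spectral
  shaping of white noise;
- **60 Hz line noise** (amplitude 0.02 mV, random phase per channel and
  trial);
- **evoked transients** at sample onset and boundary shift: a deterministic
  damped 8 Hz wavelet (amplitude 0.05 mV), identical across trials so that
  cross-trial-mean subtraction removes it exactly;
- **coupled band-limited oscillators**. Each coupling row designates a
  channel pair, a band (beta 16–32 Hz or delta 2–4 Hz), and an epoch. The
  latent oscillator is narrowband-filtered Gaussian noise — chosen over a
  deterministic sinusoid because its analytic phase is stochastic across
  trials, which is what makes trial-permutation null distributions
  informative. Each channel receives the latent signal rotated by an
  independent von Mises phase offset drawn per trial, with concentration
  κ_above or κ_below selected by the trial's category. The population
  phase-difference resultant is then (I₁(κ)/I₀(κ))², so the expected PPC is
  (I₁(κ)/I₀(κ))⁴ — an analytic ground truth the tests verify at high SNR.
  Epoch confinement uses 50 ms raised-cosine ramps to avoid spectral edge
  artifacts.

Default coupling injects beta coupling in the Category epoch (0–1.3 s) and
delta coupling in the Shift epoch (1.3–2.3 s) between an AIP and a cPFC
channel, with κ_above = 2 versus κ_below = 0.3. Oscillator amplitudes are
0.06 mV (beta) and 0.12 mV (delta) RMS: low-frequency LFP rhythms carry more
amplitude, consistent with the 1/f character of the background, and at equal
amplitude the delta estimator has intrinsically less power because a 1 s
epoch holds only two to four delta cycles and the wavelet support at 2–4 Hz
extends well beyond the epoch.

Spikes are inhomogeneous Poisson by thinning:
λ(t) = λ₀ · g_category · (1 + m · cos(φ_target(t) − φ_pref)), with the
category gain applied from sample onset onward and φ_target the realized
phase (latent + jitter) of the designated channel's oscillation where it is
active. The modulation depth satisfies m < 1 so the rate stays nonnegative;
for sinusoidal modulation the expected PLV relative to the true phase is
m/2, the second analytic ground truth.

Every (channel, trial) and (electrode-unit, trial) pair owns an RNG stream
derived from the master seed, so sessions are bit-reproducible and
insensitive to evaluation order. Sessions serialise to a plain-text
directory (JSON metadata + CSV tables + per-channel CSV matrices with
`%.17g` formatting), which round-trips every double exactly; a schema tag is
validated on read and truncation is an error, never a partial session.

What the generator does **not** emulate: volume conduction, electrode drift,
non-Poisson spike-train structure (bursting, refractoriness), cross-frequency
coupling, and nonstationary background statistics. Passing tests therefore
show that the estimators recover the injected structure under realistic
noise levels — not that real cortical data satisfy these models.

## Preprocessing and spectral decomposition

The raw LFP is band-stop filtered at 59–61 Hz with a 10th-order Butterworth
applied forward and backward (zero phase), low-pass filtered (8th-order
Butterworth at 80% of the target Nyquist) and decimated by 3 to 333.33 Hz,
then centred on the per-channel cross-trial mean at each sample, which
removes the stimulus-evoked component and leaves induced activity. The
explicit anti-alias filter is required because content between 167 and
500 Hz would otherwise fold into the analysis band. The notch precedes
decimation (the line frequency must be attenuated while it is still below
Nyquist with margin); the order of operations is recorded in the config.

The wavelet decomposition uses an analytic Morlet wavelet with ω₀ = 6 — the
convention of the standard wavelet-analysis toolbox, which balances time and
frequency resolution and makes scale ≈ 1/frequency — on the grid
f_k = 2·2^(0.1k), k = 0…60 (six octaves, 2–128 Hz, 0.1-octave steps).
Coefficients are computed by FFT convolution with Torrence–Compo
normalisation; 128 Hz sits below the decimated Nyquist of 166.7 Hz, and
requesting frequencies above Nyquist is an error. Bins inside the cone of
influence (within the e-folding time √2·s(f) of a record edge) are flagged
but retained; epoch/band power averages exclude flagged bins below 4 Hz,
where the cone is widest. "1/f normalisation" of power is implemented as
multiplication by f (reference 1 Hz): it is the operation that flattens a
power-law spectrum, which the tests verify in both directions (white noise
flat without it, pink noise flattened by it).

## LFP–LFP synchrony

PPC is computed per (frequency, time) bin from per-trial phase differences
Δφᵢ = Arg(W_a,ᵢ · conj(W_b,ᵢ)). The O(N²) pairwise mean cosine is evaluated
through the algebraic identity (N·R² − 1)/(N − 1), with the naive sum kept
as an independent test oracle; the two agree to machine precision. The bias
correction subtracts the mean PPC over 200 surrogates in which one channel's
trial order is permuted without replacement; for independent channels the
corrected PPC is centred on zero even at N = 20, where raw-estimator noise
is largest.

Category selectivity is D = |PPC_A − PPC_B| per bin, with a z-score and a
rank-based one-sided p-value from 200 label permutations preserving group
sizes. Groups are balanced to equal n by random subsampling of the larger
group; trials are kept in canonical order so an A/B label swap leaves D and
z bit-identical. p-values come from the permutation ranks, not a Gaussian
tail: because D is a folded (absolute-value) statistic, its permutation
z-score is inherently non-Gaussian, and only the rank p is exactly
calibrated (the suite verifies a 5% ± 2% false-positive rate at α = 0.05).
Where the permutation spread is zero the bin is flagged and z is undefined.

The cluster rule — p < 0.05 sustained for ≥ 60 ms (20 samples at 333 Hz) at
each of ≥ 3 consecutive frequency bins — is read as a rectangular criterion:
a bin survives if it belongs to a full rectangle of significant bins meeting
both extents. The per-frequency-run alternative reading admits ragged
regions; the rectangular reading is the stricter and simpler of the two and
any region ≥ 3 rows contains a 3-row rectangle, so only 3-row windows need
scanning. At 2–8 Hz the wavelet correlation time reaches seconds, so a
single chance fluctuation can satisfy the rule on one pair; population-level
inference therefore combines pairs by Stouffer's method
(z_comb = Σz/√n) before clustering, the analogue of contouring a
population-average map. Neural analyses default to correct trials only
(switchable), since the task-defined categories are only unambiguous when
the trial was performed correctly.

The baseline comparison averages band × epoch PPC per category against the
last 750 ms of the fixation window, assigns each pair's preferred category
by the sign of the Above-minus-Below epoch difference, and compares epoch to
baseline with paired two-tailed t-tests separately for preferred and
non-preferred categories.

## Spiking selectivity

Firing rates are spike counts on contiguous 20 ms bins converted to
spikes/s and convolved with a 200 ms Gaussian. The 200 ms figure is
interpreted as the full width at half maximum (σ ≈ 85 ms, truncated at
±3σ); the σ-convention is available as a switch since the width convention
is genuinely ambiguous in common usage. Rates are z-transformed per unit
using the mean and variance over the 3 s pre-trial baseline pooled across
trials; silent units (zero baseline variance) are flagged with undefined
z-rates and excluded from selectivity analyses. Multi-unit pooling takes the
union of unit spike trains per electrode before binning.

ωPEV per bin is (SS_between − df_between·MSE) / (SS_total + MSE) × 100 with
df_between = 1 for two categories. It is deliberately not clipped at zero:
slight negativity under the null is what makes the estimator unbiased, and
clipping would bias population averages upward. Zero total variance defines
the bin's value as 0. Population significance uses per-bin one-sided
one-sample t-tests of PEV > 0 across units with runs gated at ≥ 100 ms
(5 bins); per-unit significance uses 200 label permutations of the per-bin
ωPEV at p < 0.01, since no parametric per-unit test is canonical for a
bias-corrected effect size.

## Spike–field locking

For each frequency, spike phases are the wavelet phases of the target LFP
channel at spike times within the epoch (Category 0–1.3 s or Shift
1.3–2.3 s; spikes outside never contribute). The "single-trial" PLV is the
per-trial resultant length combined across trials by a spike-count-weighted
average — this keeps trials exchangeable under the permutation scheme — with
pooling of all spikes across trials available as a config switch. The
z-score comes from 200 permutations that reassign whole LFP trial traces
across trials while keeping each trial's spike series, which discounts the
locking that spike count and temporal pattern alone produce (raw PLV is
strongly inflated at ~10 spikes/trial; the permutation z stays centred — the
suite verifies both). Time shifts are not used as surrogates because they
break the trial-locked nonstationarity of the epoch structure.

Directionality contrasts are two-tailed paired t-tests across pairs of
z-PLV, per frequency and for the 22–32 Hz band average (the band of the
published directional effect; 16–32 Hz is used for general band summaries —
both are named constants). Decile conditioning selects ⌈0.10·n⌉ electrodes
or pairs by epoch-averaged score with deterministic id-order tie-breaking
(ties flagged, n < 10 warned). The selectivity–synchrony relation is
summarised by both Pearson and Spearman coefficients, as the linear and rank
versions genuinely differ when a minority of electrodes carries most of the
locking.

## Problem sizes and numerical choices

Test-suite and acceptance-script simulations use sessions of 2–16 channels
and 24–120 trials, 50–200 permutations/surrogates, and restricted frequency
subsets or time windows where a full map is not the point; these sizes give
each stochastic check a comfortable margin at its stated tolerance. Key
tolerances: the PPC identity is asserted at 1e-12; von Mises PPC recovery at
±0.03 (N = 1000); null false-positive rates at ±2 percentage points; PLV
depth recovery at ±0.03 with ≥ 2000 spikes; preprocessing attenuation
measured in the filter's steady state (a long record with the evaluation
window away from the edges, since a 2 Hz-wide 10th-order notch has an
impulse response of seconds).

Known limitations: the generator's phase offsets are constant within an
epoch rather than drifting; coupling is pairwise, not network-structured;
spike sorting is assumed done (units arrive labelled); and the group-level
ANOVAs of a full experimental report are out of scope — the package reports
group means ± SEM and implements the permutation and t-test machinery the
headline analyses need.
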