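---
title: "Quantifying neural synchronization to music: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neural synchronization to music: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beatsync)
```

## The scientific problem

When people listen to music, low-frequency cortical activity synchronizes
with the temporal structure of the sound. This package implements a complete
analysis chain for quantifying that synchronization from multichannel EEG:
which *musical feature* best drives the neural response (the amplitude
envelope, its rectified derivative, discrete beat onsets, or spectral flux),
how synchronization depends on the *beat rate* (tempi of 1–4 Hz, the range
of musical beats), and how it can be detected against the strongly
autocorrelated (1/f) background of EEG.

Two complementary pipelines are provided and cross-checked:

1. **Reliable components analysis (RCA)** reduces the electrode array to a
   small number of spatial components that are maximally correlated across
   participants, followed by time-domain stimulus–response correlation
   (SRCorr) and frequency-domain coherence (SRCoh).
2. **Temporal response functions (TRFs)** fit a lag-resolved linear forward
   model from stimulus features to each electrode by cross-validated ridge
   regression.

Both metrics are normalized against circular-shift surrogate distributions,
and differences across tempo conditions are tested with cluster-based
permutation statistics.

## Musical features

All features end up z-scored on a uniform 128 Hz analysis grid; features of
one trial are trimmed to a common length and re-standardized after
trimming.

* **Amplitude envelope** — mean across 128 gammatone bands with center
  frequencies linearly spaced between 60 and 6000 Hz (4th-order gammatone
  magnitude response applied in the frequency domain; the band's analytic
  signal magnitude is the band envelope). Linear spacing is the literal
  reading of the filterbank description this package follows; ERB-rate
  spacing is available via `spacing = "erb"`. The full-band Hilbert
  envelope (`hilbert_envelope()`) is the cheaper alternative used by the
  simulation pipeline. The smoothing applied before resampling (zero-phase
  4th-order Butterworth low-pass at 50 Hz) is this package's documented
  default: it is an anti-aliasing choice for the 128 Hz grid, not a
  published setting.
* **Derivative** — half-wave rectified first difference of the envelope,
  zero-padded at the head to preserve length. Emphasizes onsets.
* **Beats** — binary vectors with a 1 at each annotated onset sample.
* **Spectral flux** — short-time spectra with a hop of 344 samples at
  44.1 kHz (≈128 frames/s) and a window of twice the hop; magnitudes are
  compressed as `log(1 + 100·|X|)` and the per-frame sum of half-wave
  rectified increases over frequency is the flux. Whether the original
  analysis summed raw or normalized spectral differences is not stated;
  raw rectified differences of the log spectrogram are used here, with the
  compression constant exposed. Flux responds to pitch and timbre changes
  even at constant amplitude, which is what dissociates it from the
  envelope — `gen_audio(..., pitch_only = TRUE)` builds an equal-RMS
  pitch-alternation stimulus exercising exactly this dissociation.

Mutual information between feature pairs uses the plug-in estimator on
4 quantile (equal-count) bins. Equal-count bins make `MI(X, X)` exactly
`log2(4) = 2` bits, which the tests use as an anchor; time-reversal
surrogates provide the reference for shared-information comparisons. No
bias-corrected or continuous estimators are provided on purpose.

## EEG preprocessing

The cleaning chain is: zero-phase band-pass (0.5–30 Hz, 4th-order
Butterworth, applied forward–backward so TRF latencies are not shifted) →
average reference → downsample → epoch (dropping the first second after
stimulus onset to remove onset-evoked responses) → pooled bad-electrode
detection (squared amplitude above mean + 4 SD on ≥ 10 % of samples;
whether the criterion pools statistics across channels is ambiguous, so
pooled is the default with `scope = "per_channel"` available) → iterative
transient rejection (2 SD of the single-trial, single-electrode mean
squared amplitude, re-estimated four times). Rejected samples become NaN
for the RCA path and are rebuilt by shape-preserving piecewise cubic
(PCHIP) interpolation for the TRF path. Flagged bad channels are dropped
with a log message rather than rebuilt from neighbours, since neighbour
interpolation requires montage geometry that plain matrices do not carry.

## Reliable components analysis

With `Rxy` the symmetrized sum of between-participant cross-covariances
and `Rw` the pooled within-participant covariance, the spatial filters
solve the generalized eigenproblem `Rxy w = λ Rw w`. Covariances are
computed pairwise-complete so NaN-marked samples are tolerated (with at
least 50 % joint validity required per pair). `Rw` is shrunk toward its
diagonal by a configurable fraction (default 1e-6) because
average-referenced data are rank-deficient by one. The symmetric-pair-sum
covariance convention is this package's definition; the original
implementation's pooling weights are not restated anywhere we could follow.
Forward-model projections (`Rw W (WᵀRw W)⁻¹`) visualize component
topographies, and the sign convention (largest-magnitude forward
coefficient positive) makes outputs reproducible.

## SRCorr, SRCoh and surrogate normalization

SRCorr passes the feature through a least-squares temporal filter (lagged
Toeplitz design, shifts of 0–1 s *including* the instantaneous lag-0
term — the superset of both readings of "shifted by one sample up to 1 s" —
plus an intercept) and correlates the filtered feature with the neural
component; it equals the square root of the lagged regression's R².

SRCoh is Welch magnitude-squared coherence with 5 s Hamming windows and
50 % overlap. Five-second windows natively give 0.2 Hz bins; transforms
are zero-padded to 1024 samples at 128 Hz to produce the 0.125 Hz grid,
which is how the two stated numbers (5 s windows, 0.125 Hz resolution)
are reconciled. Values at the stimulation tempo and its first harmonic
are extracted from the exact grid bins.

Raw metrics are z-scored against circular-shift surrogates: the neural
time course is rotated by a random offset (50 iterations by default),
preserving each signal's marginal distribution and autocorrelation while
destroying alignment, which controls for the higher low-frequency power
of EEG. Shifts are drawn uniformly outside a guard band of one second
around zero; whether small shifts were excluded originally is unstated,
so the guard band is this package's choice. z-scoring of SRCoh is applied
per extracted value (tempo bin), not per spectrum bin.

## Temporal response functions

The TRF design concatenates per-feature lag blocks over 0–400 ms
(`round(0.4 · 128) = 51`, hence 52 lag columns per feature — documented
because 0.4·128 is not an integer) plus one unpenalized intercept. Ridge
weights solve `(SᵀS + λ m I) w = Sᵀr` with `m` the mean penalized
diagonal, so λ is unit-consistent across designs. λ is selected by
leave-one-trial-out cross-validation over 13 powers of ten from 1e-6 to
1e6 (per-decade is the convention of the standard toolboxes; the source
material states only the range), maximizing the mean validation
correlation across trials and electrodes — the selection statistic is
unstated there, and mean-r is common practice. Selection is per
participant × condition by default and configurable. TRF correlations are
averaged over the `k` electrodes with the highest validation r (7–8 in a
32-channel montage; ties break toward lower indices). "Fisher-z-scored"
TRF weights are read as standardization across the lag axis (Fisher's z
transforms correlations, which weights are not); `normalize_weights()`
implements exactly that, flagging zero-variance profiles instead of
dividing by zero.

The residualized model fits the nuisance features first, subtracts their
predictions, and fits the target feature on the residual EEG. A caveat
the tests make explicit: with strictly periodic stimuli every feature
predicts every other through the lag filter, so the residual-model null
is only clean for aperiodic (or orthogonalized) drivers.

The TRF surrogate z rotates each trial's response by an *independent*
offset before re-evaluating at the chosen λ. With a common offset, a
single lag filter can realign quasi-periodic stimuli whose period fits
inside the lag window, which inflates the null at fast tempi and makes
z-scores incomparable across tempo conditions; independent per-trial
offsets are the trial-structured analogue of rotating the concatenated
recording.

## Cluster-based permutation testing

A one-way ANOVA across tempo conditions (participants as observations) is
computed at each lag; runs of consecutive lags with p < 0.01 form
clusters scored by summed F. The null shuffles each participant's tempo
labels (preserving participant exchangeability), and by default retains
the *maximum* cluster statistic per permutation — the standard
family-wise-control convention; the description this package follows is
ambiguous between max-cluster and all-clusters nulls, so the all-clusters
variant stays available via `null = "all"`. Cluster p-values use the
`(1 + #exceedances)/(1 + n_perm)` estimator. The ANOVA at this stage is
one-way, as stated, not repeated-measures.

## Supporting statistics

Repeated-measures one-way ANOVA is computed from the classical
sum-of-squares decomposition with Greenhouse–Geisser epsilon from the
double-centered condition covariance; the correction is applied when
Mauchly's test rejects sphericity at 0.05 (the trigger threshold is this
package's choice). Partial η² is the reported effect size, and
`r_equivalent = sqrt(t²/(t² + df))` accompanies paired t-tests. FDR
correction delegates to `stats::p.adjust(method = "BH")`; per-participant
tempo slopes are OLS fits feeding a one-way ANOVA across features;
latency profiles get independent OLS fits per tempo segment with the
breakpoint between 2.5 and 2.75 Hz. Rating-based splits take the 15
highest- and lowest-rated trials per participant, with order-based tie
breaking.

## The synthetic-data generator

The generator exists so every stage can be validated against known ground
truth without any recorded data.

* **Audio**: exponentially decaying harmonic tones (4 harmonics, 1/n
  rolloff, 60 ms decay — percussive enough for clean envelope onsets,
  harmonic enough for flux to react to pitch), one onset per beat on an
  isochronous grid at the requested tempo, fundamentals cycling through a
  pitch set, per-beat amplitude jitter of 10 % so ridge designs are not
  perfectly periodic and ill-conditioned at harmonic lags.
* **EEG**: the generative model *is* the forward model — a
  difference-of-gamma kernel with a positive peak near 80 ms and a trough
  near 180 ms (a P1–N1–P2-like shape, so recovery tests target a
  realistic asymmetric waveform) convolved with the features, projected
  through a fixed topography, shared across participants, plus
  independent white + 1/f noise at a controlled SNR. `noise_var` fixes
  the noise floor absolutely, which is how condition-dependent kernel
  scaling (e.g. amplitude ∝ 1/tempo) translates into genuinely lower SNR
  rather than being cancelled by per-condition noise rescaling.

What the generator does *not* emulate: eye blinks and other artifacts with
non-Gaussian statistics, volume conduction with realistic head geometry,
non-isochronous beats, and the spectral richness of natural music. Passing
tests therefore demonstrate the correctness and calibration of the
estimators, not performance on recorded EEG.

## Numerical choices and degenerate inputs

Z-scoring of a constant vector returns zeros plus a degenerate flag rather
than dividing by zero, and this propagates (envelope of silence, empty
beat lists, constant TRF weight profiles). Colliding beat onsets merge
with a warning. Coherence bins without power report 0. The RCA
eigenproblem is solved by whitening with the regularized pooled
covariance, guaranteeing a real spectrum after symmetrization.

## Problem sizes used in the validation suite

The test-suite simulations use 10–20 trials of 10–30 s at 128 Hz, up to
32 channels and 10 participants, 50 surrogate iterations, and 200–1000
permutations (500 datasets for the family-wise calibration); the pipeline
demonstration runs 6 participants × 3 tempi × 6 trials of 15 s. These
sizes were chosen to give stable Monte-Carlo estimates at desk scale and
are stated here so results can be reproduced exactly with
`scripts/acceptance.R`.
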