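# beatsync

Cortical activity synchronizes with the temporal structure of music.
`beatsync` is an R package for quantifying that synchronization from
multichannel EEG: it extracts four time-varying **musical features** from
audio — the amplitude envelope (gammatone filterbank or full-band Hilbert),
its half-wave rectified first derivative, binary beat onsets, and spectral
flux — and relates them to neural recordings through two complementary
pipelines:

* **Reliable components analysis (RCA)** — spatial filters `w` solving the
  generalized eigenproblem `R_xy w = λ R_w w` (between-participant
  cross-covariance against pooled within-participant covariance), which
  maximize the correlation of component time courses across listeners.
  The first reliable component is then related to each musical feature by
  **stimulus–response correlation** (SRCorr: Pearson correlation between
  the component and the feature passed through a least-squares lagged
  temporal filter, equal to √R² of the lagged regression) and
  **stimulus–response coherence** (SRCoh: Welch magnitude-squared
  coherence, `|S_xy|² / (S_xx S_yy)`, 5 s Hamming windows, 50 % overlap,
  0.125 Hz bins), read out at the stimulation tempo and its first
  harmonic.
* **Temporal response functions (TRFs)** — forward encoding models
  `r(t) = Σ_f Σ_τ w_f(τ) s_f(t − τ) + ε(t)` over lags 0–400 ms, fit by
  ridge regression with leave-one-trial-out cross-validation over
  λ ∈ {10⁻⁶ … 10⁶}, scored by the per-electrode correlation between
  predicted and held-out EEG; univariate, multivariate and residualized
  (variance-partitioning) variants.

Both metrics are z-scored against **circular-shift surrogate**
distributions (rotating the neural signal preserves its spectrum and
autocorrelation while destroying stimulus alignment, controlling for 1/f
confounds), feature pairs are compared by binned **mutual information**
with time-reversal surrogates, and tempo effects on TRF weights are
assessed with **cluster-based permutation tests** (pointwise one-way
ANOVA, clusters of consecutive supra-threshold lags, max-cluster summed-F
null). Supporting statistics include repeated-measures ANOVA with
Greenhouse–Geisser correction, Benjamini–Hochberg FDR, per-participant
tempo slopes, piecewise latency regression, and rating-based trial splits
with the `r_equivalent` effect size.

A first-class **synthetic-data module** generates seeded percussive audio
with controlled beat tempo (1–4 Hz) and simulated multichannel EEG as a
known P1–N1–P2-like kernel convolved with the musical features, shared
across simulated participants, plus 1/f and white noise at controlled
SNR — so every stage of the pipeline is validated against known ground
truth. See `vignettes/methods.Rmd` for the models, assumptions and design
choices.

## Worked example

Simulate five listeners hearing a 2 Hz stimulus, recover the shared
component, and quantify synchronization both ways:

```r
library(beatsync)

spec     <- stimulus_spec(tempo_hz = 2, duration_s = 15, fs_audio = 8000, seed = 1)
audio    <- gen_audio(spec)
envelope <- hilbert_envelope(audio, fs_audio = 8000)
flux     <- spectral_flux(audio, 8000, frame_len = round(8000 / 128))
feats    <- trim_features(list(envelope = envelope, flux = flux))

n   <- length(feats$envelope$values)
sim <- eeg_sim_spec(n_participants = 5, n_trials = 6,
                    trial_duration_s = n / 128, n_channels = 16,
                    snr_db = 10, seed = 2)
fm      <- cbind(feats$envelope$values, feats$flux$values)
dataset <- gen_eeg_dataset(fm, sim)

concat <- lapply(dataset$participants, function(tr) do.call(rbind, tr))
rca    <- fit_rca(concat)
rca
#> <rca_model> 16 channels, 3 components; reliabilities: 3.97, 0.166, 0.144

rc1     <- rca_project(concat[[1]], rca, component = 1)
env_cat <- rep(feats$envelope$values, 6)
srcorr(env_cat, rc1, fs = 128)
#> [1] 0.992...
zscore_vs_surrogate(srcorr_metric(env_cat, 128), rc1, env_cat,
                    n_iter = 50, seed = 3)
#> <surrogate_summary> raw 0.9924, null 0.9812 +/- 0.0034 over 50 shifts => z = 3.29

trials <- lapply(1:6, function(tr)
  list(features = fm, response = dataset$participants[[1]][[tr]]))
crossval_trf(trials, fs = 128)
#> <trf_cv> lambda = 1, mean validation r = 0.6353 (best electrode 0.9843)
```

The reliabilities show one dominant shared component (3.97 versus ~0.15
for the rest), recovered from 16 channels at 10 dB SNR. The raw SRCorr of
0.99 is inflated by the stimulus periodicity — the surrogate null is
itself 0.98 — which is why the z-score against circular shifts (3.3),
not the raw correlation, is the meaningful readout. The cross-validated
TRF at its selected ridge parameter predicts held-out EEG at r ≈ 0.98 on
the best electrode.

The full orchestration (`run_pipeline(default_config())`) simulates a
multi-tempo study end-to-end and emits tidy tables of z-SRCorr, z-SRCoh,
z-TRF correlations, TRF cluster statistics and mutual information; a thin
command-line wrapper lives in `inst/scripts/run_pipeline.R`.

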