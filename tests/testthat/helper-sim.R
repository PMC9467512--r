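# Shared fixture builders. Everything is generated in code under fixed
# seeds; no stored data.

# Musical features of one short synthetic stimulus on the 128 Hz grid.
make_audio_features <- function(tempo_hz = 2, duration_s = 10,
                                fs_audio = 8000, seed = 1L,
                                fs_out = 128) {
  spec <- stimulus_spec(tempo_hz, duration_s, fs_audio = fs_audio, seed = seed)
  audio <- gen_audio(spec)
  env <- hilbert_envelope(audio, fs_audio, fs_out = fs_out)
  feats <- trim_features(list(
    envelope = env,
    derivative = first_derivative(env),
    beats = beats_to_vector(attr(audio, "beat_onsets_s"), fs_out, duration_s),
    flux = spectral_flux(audio, fs_audio,
                         frame_len = round(fs_audio / fs_out), fs_out = fs_out)
  ))
  list(audio = audio, features = feats,
       n = length(feats[[1L]]$values), fs = fs_out)
}

# Smooth aperiodic feature: low-passed white noise, z-scored.
smooth_noise_feature <- function(n, fs = 128, f_cut = 8) {
  x <- stats::rnorm(n)
  bf <- signal::butter(4, f_cut / (fs / 2), type = "low")
  as.numeric(zscore(as.numeric(signal::filtfilt(bf, x))))
}

# Trials whose response is a known kernel convolved with an aperiodic
# feature plus white noise at snr_db, for TRF recovery tests.
make_kernel_trials <- function(n_trials = 8, duration_s = 10, fs = 128,
                               snr_db = 10, n_channels = 4,
                               kernel = default_kernel(fs), seed = 1L,
                               topography = NULL) {
  set.seed(seed)
  n <- round(duration_s * fs)
  if (is.null(topography))
    topography <- seq(1, 0.2, length.out = n_channels)
  lapply(seq_len(n_trials), function(tr) {
    feat <- smooth_noise_feature(n, fs)
    src <- beatsync:::conv_causal(feat, as.numeric(kernel))
    sig <- outer(src, topography)
    noise_sd <- sqrt(mean(apply(sig, 2, stats::var)) / 10^(snr_db / 10))
    list(features = feat,
         response = sig + matrix(stats::rnorm(n * n_channels, sd = noise_sd),
                                 n, n_channels),
         source = src, topography = topography)
  })
}
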