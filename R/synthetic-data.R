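## Synthetic stimuli and simulated EEG with known ground truth.
##
## The generators emulate the statistical structure the analysis assumes:
## percussive audio with an isochronous beat at a controlled tempo,
## pitch changes that can be decoupled from amplitude changes, and
## multichannel EEG built as a known lag-resolved kernel convolved with
## the musical features, shared across simulated participants, plus
## 1/f-shaped and white background noise at a controlled SNR.

#' Specification of a synthetic music-like stimulus
#'
#' @param tempo_hz beat rate in beats per second (the study range is
#'   1-4 Hz in 0.25 Hz steps).
#' @param duration_s stimulus duration in seconds.
#' @param fs_audio audio sampling rate in Hz.
#' @param pitch_cycle ordered fundamental frequencies (Hz) applied to
#'   successive beats, recycled.
#' @param amplitude_jitter fractional SD of per-beat amplitude (default
#'   0.1 so the design is not perfectly periodic).
#' @param seed integer seed; identical specs regenerate bit-identical audio.
#' @return object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(tempo_hz, duration_s, fs_audio = 44100,
                          pitch_cycle = c(220, 277.18, 329.63, 440),
                          amplitude_jitter = 0.1, seed = 1L) {
  assert_scalar_pos(tempo_hz, "tempo_hz")
  assert_scalar_pos(duration_s, "duration_s")
  assert_scalar_pos(fs_audio, "fs_audio")
  if (any(pitch_cycle <= 0)) stop_invalid("pitch_cycle must be positive")
  structure(list(tempo_hz = tempo_hz, duration_s = duration_s,
                 fs_audio = fs_audio, pitch_cycle = pitch_cycle,
                 amplitude_jitter = amplitude_jitter, seed = as.integer(seed)),
            class = "stimulus_spec")
}

#' Binary beat train at a fixed tempo
#'
#' Ones exactly at samples `round(k * fs / tempo_hz)` for k = 0, 1, ...
#' while within the duration; zeros elsewhere.
#'
#' @param tempo_hz beats per second (> 0).
#' @param duration_s duration in seconds (> 0).
#' @param fs sampling rate in Hz; must satisfy `fs >= 2 * tempo_hz`.
#' @return numeric 0/1 vector of length `round(duration_s * fs)`.
#' @export
gen_beat_train <- function(tempo_hz, duration_s, fs) {
  assert_scalar_pos(tempo_hz, "tempo_hz")
  assert_scalar_pos(duration_s, "duration_s")
  assert_scalar_pos(fs, "fs")
  if (fs < 2 * tempo_hz) stop_invalid("fs must be at least twice tempo_hz")
  n <- round(duration_s * fs)
  k <- 0:floor(duration_s * tempo_hz + 1)
  idx <- round(k * fs / tempo_hz)
  idx <- idx[idx < n]
  out <- numeric(n)
  out[idx + 1L] <- 1
  out
}

## Single percussive tone: harmonics with 1/n rolloff, exponential decay.
## decay_s is the amplitude e-folding time.
synth_tone <- function(f0, fs, length_n, n_harmonics = 4L, decay_s = 0.06) {
  t <- (seq_len(length_n) - 1L) / fs
  env <- exp(-t / decay_s)
  y <- numeric(length_n)
  for (h in seq_len(n_harmonics)) {
    fh <- f0 * h
    if (fh < fs / 2) y <- y + sin(2 * pi * fh * t) / h
  }
  y * env
}

#' Generate a synthetic percussive stimulus
#'
#' Sums exponentially decaying harmonic tones (4 harmonics, 1/n amplitude
#' rolloff, 60 ms decay), one onset per beat, with the fundamental cycling
#' through `pitch_cycle` and per-beat amplitude jitter. With
#' `pitch_only = TRUE`, consecutive tones are sustained and cross-faded at
#' equal RMS so the amplitude stays flat while the spectrum changes —
#' a stimulus that dissociates spectral flux from the amplitude envelope.
#'
#' @param spec a [stimulus_spec()].
#' @param pitch_only logical; build the flat-amplitude pitch-alternation
#'   variant instead of the percussive one.
#' @return numeric waveform, peak-normalized to `max(abs(x)) = 1`, with
#'   attributes `fs` and `beat_onsets_s`.
#' @export
gen_audio <- function(spec, pitch_only = FALSE) {
  stopifnot(inherits(spec, "stimulus_spec"))
  if (max(spec$pitch_cycle) * 4 >= spec$fs_audio / 2 && !pitch_only)
    stop_invalid("pitch (incl. harmonics) above Nyquist")
  if (max(spec$pitch_cycle) >= spec$fs_audio / 2)
    stop_invalid("pitch above Nyquist")
  fs <- spec$fs_audio
  n <- round(spec$duration_s * fs)
  beat_idx <- which(gen_beat_train(spec$tempo_hz, spec$duration_s, fs) == 1) - 1L
  onsets_s <- beat_idx / fs
  n_beats <- length(beat_idx)
  pitches <- rep_len(spec$pitch_cycle, n_beats)
  rng <- local({ set.seed(spec$seed); stats::rnorm(n_beats, 1, spec$amplitude_jitter) })
  rng <- pmax(rng, 0.1)
  y <- numeric(n)
  if (pitch_only) {
    ## Sustained equal-RMS tones with raised-cosine cross-fades at beats.
    period_n <- round(fs / spec$tempo_hz)
    fade_n <- max(2L, round(0.02 * fs))
    t <- (seq_len(n) - 1L) / fs
    for (b in seq_len(n_beats)) {
      i0 <- beat_idx[b] + 1L
      i1 <- if (b < n_beats) beat_idx[b + 1L] + fade_n else n
      i1 <- min(i1, n)
      seg <- i0:i1
      tone <- sin(2 * pi * pitches[b] * t[seg])
      w <- rep(1, length(seg))
      nf <- min(fade_n, length(seg))
      if (b > 1L) w[seq_len(nf)] <- (1 - cos(pi * seq(0, 1, length.out = nf))) / 2
      if (b < n_beats) {
        w[(length(seg) - nf + 1L):length(seg)] <-
          (1 + cos(pi * seq(0, 1, length.out = nf))) / 2
      }
      y[seg] <- y[seg] + tone * w
    }
  } else {
    tone_n <- min(n, round(0.6 * fs / spec$tempo_hz + 0.12 * fs))
    for (b in seq_len(n_beats)) {
      i0 <- beat_idx[b] + 1L
      len <- min(tone_n, n - i0 + 1L)
      if (len < 2L) next
      y[i0:(i0 + len - 1L)] <- y[i0:(i0 + len - 1L)] +
        rng[b] * synth_tone(pitches[b], fs, len)
    }
  }
  peak <- max(abs(y))
  if (peak > 0) y <- y / peak
  attr(y, "fs") <- fs
  attr(y, "beat_onsets_s") <- onsets_s
  y
}

#' Default simulated cortical response kernel
#'
#' Difference of two gamma-shaped waveforms with a positive peak near
#' 80 ms and a negative trough near 180 ms, emulating a P1-N1-P2-like
#' response over lags 0-400 ms. Used as the ground-truth forward kernel
#' in simulations so recovery tests target a realistic, asymmetric shape.
#'
#' @param fs sampling rate of the kernel lag axis (Hz).
#' @param lag_hi_ms upper lag bound in ms.
#' @return numeric kernel with attribute `lag_ms`.
#' @export
default_kernel <- function(fs = 128, lag_hi_ms = 400) {
  lags_ms <- seq(0, lag_hi_ms, by = 1000 / fs)
  t <- lags_ms / 1000
  gamma_bump <- function(t, peak_s, shape = 4) {
    scale <- peak_s / (shape - 1)
    g <- (t / scale)^(shape - 1) * exp(-(t / scale))
    g / max(g)
  }
  k <- gamma_bump(t, 0.08) - 0.8 * gamma_bump(t, 0.18)
  k <- k / max(abs(k))
  attr(k, "lag_ms") <- lags_ms
  k
}

## 1/f^alpha noise by spectral shaping of white Gaussian noise.
pink_noise <- function(n, alpha = 1) {
  nfft <- stats::nextn(n, 2)
  w <- stats::rnorm(nfft)
  W <- stats::fft(w)
  f <- c(1, seq_len(nfft - 1))            # avoid dividing DC by zero
  f <- pmin(f, nfft - f + 1)              # symmetric frequency index
  W <- W / f^(alpha / 2)
  x <- Re(stats::fft(W, inverse = TRUE)) / nfft
  x <- x[seq_len(n)]
  x / stats::sd(x)
}

#' Specification of a simulated multi-participant EEG dataset
#'
#' The generative model is the forward convolution model itself: a known
#' lag-resolved kernel per feature, a fixed channel topography, a source
#' time course common to all participants, and per-participant noise.
#'
#' @param n_participants number of simulated participants.
#' @param n_trials trials per tempo condition.
#' @param trial_duration_s trial length in seconds.
#' @param fs_eeg EEG sampling rate (Hz).
#' @param n_channels electrode count.
#' @param kernel numeric kernel (lags at `fs_eeg`, 0-400 ms) or a list of
#'   kernels, one per feature.
#' @param topography per-channel gain of the simulated source; defaults to
#'   a smooth unimodal gain profile.
#' @param snr_db ratio of source variance to noise variance in dB;
#'   `Inf` means noise-free.
#' @param noise_var absolute per-channel noise variance; when given it
#'   overrides `snr_db`, so conditions with weaker kernels genuinely
#'   have lower effective SNR instead of noise rescaled per condition.
#' @param noise_exponent spectral slope alpha of the 1/f^alpha background.
#' @param seed integer seed.
#' @return object of class `eeg_sim_spec`.
#' @export
eeg_sim_spec <- function(n_participants = 10, n_trials = 10,
                         trial_duration_s = 20, fs_eeg = 128,
                         n_channels = 32, kernel = default_kernel(fs_eeg),
                         topography = NULL, snr_db = 10, noise_var = NULL,
                         noise_exponent = 1, seed = 1L) {
  if (is.null(topography)) {
    topography <- exp(-((seq_len(n_channels) - n_channels / 3)^2) /
                        (2 * (n_channels / 6)^2))
  }
  if (length(topography) != n_channels)
    stop_invalid("topography must have one entry per channel")
  kl <- if (is.list(kernel)) kernel else list(kernel)
  for (k in kl) {
    lag_ms <- attr(k, "lag_ms") %||% ((seq_along(k) - 1L) * 1000 / fs_eeg)
    if (max(lag_ms) > 400 + 1e-9) stop_invalid("kernel lag axis must lie within [0, 400] ms")
  }
  structure(list(n_participants = as.integer(n_participants),
                 n_trials = as.integer(n_trials),
                 trial_duration_s = trial_duration_s, fs_eeg = fs_eeg,
                 n_channels = as.integer(n_channels), kernel = kl,
                 topography = as.numeric(topography), snr_db = snr_db,
                 noise_var = noise_var,
                 noise_exponent = noise_exponent, seed = as.integer(seed)),
            class = "eeg_sim_spec")
}

#' Simulate a multi-participant EEG dataset from musical features
#'
#' Each channel c of each trial reads
#' `topography[c] * sum_f (kernel_f * feature_f)(t) + noise`, where `*`
#' is causal linear convolution, the convolved source is identical
#' across participants (so reliable components analysis can recover it)
#' and the noise (white + 1/f^alpha, equal variance split) is drawn
#' independently per participant and channel, scaled so that
#' var(signal)/var(noise) matches `snr_db`.
#'
#' @param features a numeric matrix (time x features) or list of feature
#'   vectors sampled at `sim$fs_eeg`; one per trial is recycled across
#'   trials, or a list of per-trial matrices may be given.
#' @param sim an [eeg_sim_spec()].
#' @return list of class `eeg_sim_dataset`: `participants` (list; each a
#'   list of time x channel trial matrices), `source` (list of per-trial
#'   source vectors), `spec`, and `fs`.
#' @export
gen_eeg_dataset <- function(features, sim) {
  stopifnot(inherits(sim, "eeg_sim_spec"))
  n_t <- round(sim$trial_duration_s * sim$fs_eeg)
  trial_feats <- normalize_feature_arg(features, sim$n_trials, n_t)
  n_feat <- ncol(trial_feats[[1L]])
  kernels <- if (length(sim$kernel) == 1L) rep(sim$kernel, n_feat) else sim$kernel
  if (length(kernels) != n_feat)
    stop_invalid("need one kernel per feature (or a single shared kernel)")
  ## Common source per trial.
  sources <- lapply(trial_feats, function(fm) {
    s <- numeric(nrow(fm))
    for (f in seq_len(n_feat)) s <- s + conv_causal(fm[, f], as.numeric(kernels[[f]]))
    s
  })
  set.seed(sim$seed)
  topo <- sim$topography
  participants <- vector("list", sim$n_participants)
  for (p in seq_len(sim$n_participants)) {
    trials <- vector("list", sim$n_trials)
    for (tr in seq_len(sim$n_trials)) {
      s <- sources[[tr]]
      sig <- outer(s, topo)                       # time x channel
      sig_var <- mean(apply(sig, 2, stats::var))
      if (is.infinite(sim$snr_db) && is.null(sim$noise_var)) {
        trials[[tr]] <- sig
      } else {
        target_noise_var <- sim$noise_var %||% (sig_var / 10^(sim$snr_db / 10))
        if (all(topo == 0) && is.null(sim$noise_var)) target_noise_var <- 1
        noise <- sapply(seq_len(sim$n_channels), function(ch) {
          w <- stats::rnorm(length(s))
          pk <- pink_noise(length(s), sim$noise_exponent)
          nz <- (w / stats::sd(w) + pk) / sqrt(2)
          nz * sqrt(target_noise_var)
        })
        trials[[tr]] <- sig + noise
      }
    }
    participants[[p]] <- trials
  }
  structure(list(participants = participants, source = sources,
                 spec = sim, fs = sim$fs_eeg,
                 channel_labels = paste0("ch", seq_len(sim$n_channels))),
            class = "eeg_sim_dataset")
}

## Accepts a vector, a time x feature matrix, or a list of per-trial
## matrices; returns a list of n_trials time x feature matrices of n_t rows.
normalize_feature_arg <- function(features, n_trials, n_t) {
  as_mat <- function(f) {
    m <- if (is.matrix(f)) f else matrix(as.numeric(f), ncol = 1L)
    if (nrow(m) != n_t)
      stop_invalid("feature length (", nrow(m), ") does not match trial samples (", n_t, ")")
    m
  }
  if (is.list(features) && !is.data.frame(features)) {
    if (length(features) == n_trials && (is.matrix(features[[1L]]) || length(features[[1L]]) == n_t))
      return(lapply(features, as_mat))
    ## list of feature vectors shared across trials
    m <- do.call(cbind, lapply(features, as.numeric))
    return(rep(list(as_mat(m)), n_trials))
  }
  rep(list(as_mat(features)), n_trials)
}

#' @export
print.eeg_sim_dataset <- function(x, ...) {
  cat(sprintf("<eeg_sim_dataset> %d participants x %d trials, %d channels @ %g Hz\n",
              length(x$participants), length(x$participants[[1L]]),
              x$spec$n_channels, x$fs))
  invisible(x)
}
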