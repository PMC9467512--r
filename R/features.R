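## Musical feature extraction.
##
## Four time-varying features describe a musical stimulus on the 128 Hz
## analysis grid: (1) the amplitude envelope, from a 128-channel
## gammatone filterbank spanning 60-6000 Hz (or the full-band Hilbert
## envelope), (2) its half-wave rectified first derivative, (3) binary
## beat onsets, and (4) spectral flux, the frame-to-frame summed positive
## change of the log-magnitude spectrogram. All features are z-scored;
## features of one trial are trimmed to a common length downstream.

FEATURE_NAMES <- c("envelope", "derivative", "beats", "flux")

#' Construct a feature time series
#'
#' Lightweight container pairing a standardized feature vector with its
#' sampling rate and condition labels.
#'
#' @param values numeric vector (z-scored units).
#' @param fs sampling rate in Hz.
#' @param feature_name one of `"envelope"`, `"derivative"`, `"beats"`,
#'   `"flux"` (or a custom label).
#' @param tempo_hz tempo condition label (optional).
#' @param trial_id trial identifier (optional).
#' @param degenerate logical, `TRUE` if standardization hit a constant
#'   input and returned zeros.
#' @return object of class `feature_ts`.
#' @export
feature_ts <- function(values, fs, feature_name = "feature", tempo_hz = NA_real_,
                       trial_id = NA_character_, degenerate = FALSE) {
  structure(list(values = as.numeric(values), fs = fs,
                 feature_name = feature_name, tempo_hz = tempo_hz,
                 trial_id = trial_id, degenerate = isTRUE(degenerate)),
            class = "feature_ts")
}

#' @export
print.feature_ts <- function(x, ...) {
  cat(sprintf("<feature_ts '%s'> %d samples @ %g Hz%s\n", x$feature_name,
              length(x$values), x$fs,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

## Standardize raw values into a feature_ts, propagating the degenerate flag.
standardize_feature <- function(values, fs, feature_name, tempo_hz = NA_real_,
                                trial_id = NA_character_) {
  z <- zscore(values)
  feature_ts(z, fs, feature_name, tempo_hz, trial_id,
             degenerate = isTRUE(attr(z, "degenerate")))
}

## Gammatone filterbank applied in the frequency domain. For each center
## frequency the 4th-order gammatone magnitude response is imposed on the
## one-sided spectrum, whose inverse transform is directly the band's
## analytic signal; its modulus is the band envelope.
gammatone_band_envelopes <- function(x, fs, cf, order = 4) {
  n <- length(x)
  nfft <- stats::nextn(n, 2)
  X <- stats::fft(c(x, numeric(nfft - n)))
  f <- (0:(nfft - 1)) * fs / nfft
  onesided <- numeric(nfft)
  onesided[1L] <- 1
  onesided[2:(nfft / 2)] <- 2
  onesided[nfft / 2 + 1L] <- 1
  Xa <- X * onesided
  env <- matrix(0, n, length(cf))
  for (i in seq_along(cf)) {
    erb <- 24.7 * (4.37 * cf[i] / 1000 + 1)     # equivalent rectangular bandwidth
    b <- 1.019 * erb
    H <- (1 + ((f - cf[i]) / b)^2)^(-order / 2)
    band <- stats::fft(Xa * H, inverse = TRUE) / nfft
    env[, i] <- Mod(band[seq_len(n)])
  }
  env
}

#' Gammatone-filterbank amplitude envelope
#'
#' Decomposes the waveform with a gammatone filterbank (default 128
#' channels with center frequencies linearly spaced between 60 and
#' 6000 Hz), takes the magnitude of each band's analytic signal, averages
#' across bands, low-pass smooths (4th-order Butterworth at 50 Hz),
#' resamples to the analysis rate and z-scores.
#'
#' @param waveform numeric audio vector.
#' @param fs_audio audio sampling rate (Hz); must exceed `2 * f_hi`.
#' @param n_channels number of gammatone bands.
#' @param f_lo,f_hi band center-frequency range in Hz.
#' @param fs_out analysis sampling rate (Hz).
#' @param spacing `"linear"` (literal linear spacing) or `"erb"`.
#' @return a [feature_ts()] named `"envelope"`.
#' @export
gammatone_envelope <- function(waveform, fs_audio, n_channels = 128,
                               f_lo = 60, f_hi = 6000, fs_out = 128,
                               spacing = c("linear", "erb")) {
  spacing <- match.arg(spacing)
  if (f_hi >= fs_audio / 2) stop_invalid("f_hi must be below Nyquist")
  if (length(waveform) < 2L) stop_invalid("waveform too short")
  cf <- if (spacing == "linear") {
    seq(f_lo, f_hi, length.out = n_channels)
  } else {
    ## ERB-rate spacing between the same endpoints
    erb_rate <- function(f) 21.4 * log10(4.37 * f / 1000 + 1)
    erb_inv <- function(e) (10^(e / 21.4) - 1) * 1000 / 4.37
    erb_inv(seq(erb_rate(f_lo), erb_rate(f_hi), length.out = n_channels))
  }
  env <- rowMeans(gammatone_band_envelopes(as.numeric(waveform), fs_audio, cf))
  env <- lowpass_zero_phase(env, fs_audio, 50)
  env <- resample_linear(env, fs_audio, fs_out)
  standardize_feature(env, fs_out, "envelope")
}

#' Full-band Hilbert amplitude envelope
#'
#' Magnitude of the analytic signal of the raw waveform, smoothed
#' (50 Hz low-pass), resampled to the analysis rate and z-scored.
#'
#' @inheritParams gammatone_envelope
#' @param smooth logical; apply the 50 Hz low-pass before resampling.
#' @return a [feature_ts()] named `"envelope"`.
#' @export
hilbert_envelope <- function(waveform, fs_audio, fs_out = 128, smooth = TRUE) {
  if (length(waveform) < 2L) stop_invalid("empty or scalar waveform")
  if (any(!is.finite(waveform))) stop_invalid("waveform must be finite")
  env <- Mod(analytic_signal(as.numeric(waveform)))
  if (smooth) env <- lowpass_zero_phase(env, fs_audio, 50)
  env <- resample_linear(env, fs_audio, fs_out)
  standardize_feature(env, fs_out, "envelope")
}

#' Half-wave rectified first derivative of an envelope
#'
#' First difference with negative values set to zero, padded with a
#' leading zero to preserve length, then z-scored. Emphasizes energy
#' increases (onsets).
#'
#' @param envelope a [feature_ts()] (typically the amplitude envelope).
#' @return a [feature_ts()] named `"derivative"`.
#' @export
first_derivative <- function(envelope) {
  v <- if (inherits(envelope, "feature_ts")) envelope$values else as.numeric(envelope)
  fs <- if (inherits(envelope, "feature_ts")) envelope$fs else NA_real_
  if (length(v) < 2L) stop_invalid("envelope must have at least 2 samples")
  d <- c(0, pmax(diff(v), 0))
  standardize_feature(d, fs, "derivative",
                      tempo_hz = if (inherits(envelope, "feature_ts")) envelope$tempo_hz else NA_real_,
                      trial_id = if (inherits(envelope, "feature_ts")) envelope$trial_id else NA_character_)
}

#' Spectral flux (spectral novelty)
#'
#' Short-time spectra are computed with a hop of `frame_len` samples
#' (~128 frames/s at 44.1 kHz) and a Hamming window of `2 * frame_len`;
#' magnitudes are log-compressed as `log(1 + compression * |X|)`; the flux
#' is the per-frame sum over frequency of half-wave rectified increases
#' relative to the previous frame, resampled to exactly `fs_out` and
#' z-scored. Sensitive to pitch and timbre changes even when the
#' amplitude envelope is flat.
#'
#' @param waveform numeric audio vector.
#' @param fs_audio audio sampling rate (Hz).
#' @param frame_len frame advance (hop) in samples.
#' @param fs_out analysis sampling rate (Hz).
#' @param compression constant in the log compression.
#' @return a [feature_ts()] named `"flux"`.
#' @export
spectral_flux <- function(waveform, fs_audio, frame_len = 344, fs_out = 128,
                          compression = 100) {
  if (frame_len <= 0) stop_invalid("frame_len must be positive")
  x <- as.numeric(waveform)
  win_len <- 2L * as.integer(frame_len)
  if (length(x) < 2L * win_len) stop_invalid("waveform shorter than 2 frames")
  hop <- as.integer(frame_len)
  n_frames <- 1L + (length(x) - win_len) %/% hop
  w <- signal::hamming(win_len)
  starts <- (seq_len(n_frames) - 1L) * hop
  frames <- matrix(x[outer(seq_len(win_len), starts, `+`)], nrow = win_len)
  frames <- frames * w
  S <- Mod(stats::mvfft(frames))[seq_len(win_len %/% 2L + 1L), , drop = FALSE]
  S <- log1p(compression * S)
  dS <- S[, -1L, drop = FALSE] - S[, -ncol(S), drop = FALSE]
  flux <- c(0, colSums(pmax(dS, 0)))
  fs_frames <- fs_audio / hop
  flux <- resample_linear(flux, fs_frames, fs_out)
  standardize_feature(flux, fs_out, "flux")
}

#' Binary beat-onset vector from annotated onset times
#'
#' Places a 1 at sample `round(onset * fs)` for each onset, 0 elsewhere;
#' standardized like the other features. Two onsets rounding to the same
#' sample collapse to a single 1 with a warning.
#'
#' @param onsets_s onset times in seconds, within `[0, duration_s)`.
#' @param fs analysis sampling rate (Hz).
#' @param duration_s total duration in seconds.
#' @param standardize z-score the vector (default) or return raw 0/1.
#' @return a [feature_ts()] named `"beats"`.
#' @export
beats_to_vector <- function(onsets_s, fs, duration_s, standardize = TRUE) {
  assert_scalar_pos(fs, "fs")
  assert_scalar_pos(duration_s, "duration_s")
  n <- round(duration_s * fs)
  if (length(onsets_s) && (any(onsets_s < 0) || any(onsets_s >= duration_s)))
    stop_invalid("onsets must lie within [0, duration_s)")
  idx <- round(onsets_s * fs) + 1L
  idx[idx > n] <- n
  if (anyDuplicated(idx)) {
    warning("beat onsets collide on the sampling grid; merged")
    idx <- unique(idx)
  }
  v <- numeric(n)
  v[idx] <- 1
  if (!standardize) return(feature_ts(v, fs, "beats"))
  standardize_feature(v, fs, "beats")
}

#' Trim a set of features to matching length
#'
#' Features of one trial can differ by a few samples after independent
#' resampling; they are cut to the shortest common length and
#' re-standardized so the z-scoring contract holds on the trimmed grid.
#'
#' @param features list of [feature_ts()] objects.
#' @return list of features, all of equal length.
#' @export
trim_features <- function(features) {
  stopifnot(length(features) >= 1L)
  n <- min(vapply(features, function(f) length(f$values), integer(1)))
  lapply(features, function(f) {
    f$values <- f$values[seq_len(n)]
    if (!f$degenerate) {
      z <- zscore(f$values)
      f$values <- as.numeric(z)
      f$degenerate <- isTRUE(attr(z, "degenerate"))
    }
    f
  })
}

#' Amplitude spectrum of a feature on a fine frequency grid
#'
#' Hamming-windowed DFT magnitude, zero-padded so the bin width reaches
#' the requested resolution; supports averaging and z-scoring spectra
#' across segments of one tempo condition.
#'
#' @param feature a [feature_ts()] or numeric vector.
#' @param fs sampling rate (needed if `feature` is a bare vector).
#' @param target_resolution_hz requested frequency bin width in Hz.
#' @return list with `frequency` (Hz) and `amplitude`.
#' @export
feature_spectrum <- function(feature, fs = NULL, target_resolution_hz = 0.0025) {
  if (target_resolution_hz <= 0) stop_invalid("resolution must be positive")
  v <- if (inherits(feature, "feature_ts")) feature$values else as.numeric(feature)
  if (is.null(fs)) fs <- if (inherits(feature, "feature_ts")) feature$fs else
    stop_invalid("fs required for bare vectors")
  if (length(v) < 2L) stop_invalid("feature too short")
  w <- signal::hamming(length(v))
  vw <- (v - mean(v)) * w
  nfft <- max(length(v), ceiling(fs / target_resolution_hz))
  A <- Mod(stats::fft(c(vw, numeric(nfft - length(v)))))
  half <- seq_len(nfft %/% 2L + 1L)
  list(frequency = (half - 1L) * fs / nfft, amplitude = A[half])
}

#' Average and z-score amplitude spectra across segments
#'
#' @param spectra list of outputs of [feature_spectrum()] on a shared grid.
#' @return list with `frequency` and z-scored mean `amplitude`.
#' @export
average_spectra <- function(spectra) {
  stopifnot(length(spectra) >= 1L)
  A <- rowMeans(sapply(spectra, `[[`, "amplitude"))
  list(frequency = spectra[[1L]]$frequency, amplitude = as.numeric(zscore(A)))
}
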