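## EEG preprocessing chain: zero-phase band-pass filtering, average
## re-referencing, downsampling, epoching, pooled bad-electrode
## detection, and iterative transient rejection with a NaN policy (for
## the reliable-components path) or shape-preserving cubic interpolation
## (for the encoding-model path).

#' Construct an EEG trial set
#'
#' @param trials list of time x channel numeric matrices.
#' @param fs sampling rate (Hz).
#' @param channel_labels channel names; defaults to `ch1..chN`.
#' @param participant_id identifier.
#' @param tempo_hz per-trial tempo labels (recycled if scalar).
#' @param quality_mask optional list of logical matrices matching
#'   `trials`; `FALSE` marks invalidated samples.
#' @return object of class `eeg_trial_set`.
#' @export
eeg_trial_set <- function(trials, fs, channel_labels = NULL,
                          participant_id = NA_character_, tempo_hz = NA_real_,
                          quality_mask = NULL) {
  stopifnot(is.list(trials), length(trials) >= 1L)
  ncs <- vapply(trials, ncol, integer(1))
  if (length(unique(ncs)) != 1L) stop_invalid("all trials must share channel count")
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(ncs[1L]))
  if (is.null(quality_mask))
    quality_mask <- lapply(trials, function(m) matrix(TRUE, nrow(m), ncol(m)))
  stopifnot(all(mapply(function(t, q) all(dim(t) == dim(q)), trials, quality_mask)))
  structure(list(trials = trials, fs = fs, channel_labels = channel_labels,
                 participant_id = participant_id,
                 tempo_hz = rep_len(tempo_hz, length(trials)),
                 quality_mask = quality_mask),
            class = "eeg_trial_set")
}

#' @export
print.eeg_trial_set <- function(x, ...) {
  cat(sprintf("<eeg_trial_set> %d trials, %d channels @ %g Hz\n",
              length(x$trials), ncol(x$trials[[1L]]), x$fs))
  invisible(x)
}

#' Band-pass filter, average re-reference and downsample
#'
#' Applies a zero-phase (forward-backward) 4th-order Butterworth
#' band-pass (default 0.5-30 Hz) per channel, subtracts the mean across
#' channels at every sample (average reference), and resamples to the
#' working rate. Zero-phase filtering is used so response latencies are
#' not shifted.
#'
#' @param raw time x channel matrix, or an [eeg_trial_set()].
#' @param fs_in input sampling rate (Hz), > 60.
#' @param band band edges in Hz.
#' @param fs_out output sampling rate (Hz).
#' @param reref apply the average reference.
#' @return filtered matrix (or trial set) at `fs_out`.
#' @export
filter_reref <- function(raw, fs_in, band = c(0.5, 30), fs_out = 128,
                         reref = TRUE) {
  if (inherits(raw, "eeg_trial_set")) {
    out <- lapply(raw$trials, filter_reref, fs_in = fs_in, band = band,
                  fs_out = fs_out, reref = reref)
    return(eeg_trial_set(out, fs_out, raw$channel_labels, raw$participant_id,
                         raw$tempo_hz))
  }
  if (fs_in <= 60) stop_invalid("fs_in must exceed 60 Hz")
  if (band[2L] >= fs_in / 2 || band[1L] <= 0)
    stop_invalid("band edges incompatible with sampling rate")
  x <- as.matrix(raw)
  bf <- signal::butter(4, band / (fs_in / 2), type = "pass")
  x <- apply(x, 2L, function(ch) as.numeric(signal::filtfilt(bf, ch)))
  if (reref) x <- x - rowMeans(x)
  if (fs_out != fs_in) x <- apply(x, 2L, resample_linear, fs_in = fs_in, fs_out = fs_out)
  x
}

#' Epoch a continuous recording, dropping the onset second
#'
#' Cuts `[onset_s + skip_s, offset_s)` out of a continuous time x channel
#' matrix; the first second after stimulus onset is discarded to remove
#' onset-evoked responses.
#'
#' @param x continuous time x channel matrix.
#' @param fs sampling rate (Hz).
#' @param onsets_s,offsets_s trial boundaries in seconds.
#' @param skip_s seconds discarded after each onset (default 1).
#' @return list of trial matrices.
#' @export
epoch_trials <- function(x, fs, onsets_s, offsets_s, skip_s = 1) {
  stopifnot(length(onsets_s) == length(offsets_s))
  lapply(seq_along(onsets_s), function(i) {
    i0 <- round((onsets_s[i] + skip_s) * fs) + 1L
    i1 <- round(offsets_s[i] * fs)
    if (i1 <= i0) stop_invalid("trial ", i, " empty after onset skip")
    x[i0:i1, , drop = FALSE]
  })
}

#' Detect bad electrodes by pooled squared-amplitude statistics
#'
#' A channel is flagged when its squared amplitude exceeds
#' `mean + 4 SD` of the squared data on at least 10% of samples. The
#' mean and SD are pooled over all channels and time by default
#' (`scope = "pooled"`); `scope = "per_channel"` evaluates each channel
#' against its own statistics.
#'
#' @param trial_set an [eeg_trial_set()] or time x channel matrix.
#' @param n_sd SD multiplier.
#' @param min_fraction minimum fraction of supra-threshold samples.
#' @param scope `"pooled"` or `"per_channel"`.
#' @return integer vector of flagged channel indices (possibly empty).
#' @export
detect_bad_electrodes <- function(trial_set, n_sd = 4, min_fraction = 0.1,
                                  scope = c("pooled", "per_channel")) {
  scope <- match.arg(scope)
  x <- if (inherits(trial_set, "eeg_trial_set"))
    do.call(rbind, trial_set$trials) else as.matrix(trial_set)
  if (length(x) == 0L || ncol(x) < 2L) stop_invalid("need at least 2 channels of data")
  sq <- x^2
  if (scope == "pooled") {
    thr <- mean(sq) + n_sd * stats::sd(sq)
    frac <- colMeans(sq > thr)
  } else {
    frac <- vapply(seq_len(ncol(sq)), function(ch) {
      thr <- mean(sq[, ch]) + n_sd * stats::sd(sq[, ch])
      mean(sq[, ch] > thr)
    }, numeric(1))
  }
  which(frac >= min_fraction)
}

#' Drop channels from a trial set
#' @param trial_set an [eeg_trial_set()].
#' @param channels integer indices to remove.
#' @return trial set without those channels.
#' @export
drop_channels <- function(trial_set, channels) {
  if (length(channels) == 0L) return(trial_set)
  keep <- setdiff(seq_len(ncol(trial_set$trials[[1L]])), channels)
  eeg_trial_set(lapply(trial_set$trials, function(m) m[, keep, drop = FALSE]),
                trial_set$fs, trial_set$channel_labels[keep],
                trial_set$participant_id, trial_set$tempo_hz,
                lapply(trial_set$quality_mask, function(m) m[, keep, drop = FALSE]))
}

#' Reject noisy transients per trial and electrode
#'
#' Samples whose squared amplitude exceeds two SD of the single-trial,
#' single-electrode mean squared amplitude are invalidated; the
#' threshold is re-estimated on the surviving samples and re-applied,
#' four passes in total. `mode = "nan"` records the rejections in the
#' quality mask (reliable-components path); `mode = "interpolate"`
#' replaces them by shape-preserving piecewise cubic (PCHIP)
#' interpolation over valid neighbors (encoding-model path).
#'
#' @param trial_set an [eeg_trial_set()].
#' @param mode `"nan"` or `"interpolate"`.
#' @param n_sd SD multiplier (default 2).
#' @param n_passes threshold re-estimation passes (default 4).
#' @return an [eeg_trial_set()] with updated trials and quality mask.
#' @export
reject_transients <- function(trial_set, mode = c("nan", "interpolate"),
                              n_sd = 2, n_passes = 4L) {
  mode <- match.arg(mode)
  stopifnot(inherits(trial_set, "eeg_trial_set"))
  trials <- trial_set$trials
  masks <- trial_set$quality_mask
  for (tr in seq_along(trials)) {
    m <- trials[[tr]]
    valid <- masks[[tr]]
    for (ch in seq_len(ncol(m))) {
      v <- valid[, ch]
      for (pass in seq_len(n_passes)) {
        sq <- m[, ch]^2
        ok <- v
        if (sum(ok) < 4L) break
        thr <- mean(sq[ok]) + n_sd * stats::sd(sq[ok])
        bad <- ok & sq > thr
        if (!any(bad)) break
        v[bad] <- FALSE
      }
      valid[, ch] <- v
      if (mode == "interpolate" && any(!v)) {
        good <- which(v)
        if (length(good) >= 2L) {
          m[!v, ch] <- pracma::pchip(good, m[good, ch], which(!v))
        }
      }
    }
    masks[[tr]] <- valid
    if (mode == "nan") {
      m[!valid] <- NA_real_
    }
    trials[[tr]] <- m
  }
  eeg_trial_set(trials, trial_set$fs, trial_set$channel_labels,
                trial_set$participant_id, trial_set$tempo_hz, masks)
}

#' Standard preprocessing chain
#'
#' filter -> average reference -> downsample -> epoch -> bad-electrode
#' detection -> transient rejection, in that order.
#'
#' @param x continuous time x channel matrix.
#' @param fs_in input rate (Hz).
#' @param onsets_s,offsets_s trial boundaries (seconds).
#' @param mode transient-rejection mode, see [reject_transients()].
#' @param fs_out analysis rate (Hz).
#' @return list: `trial_set` (cleaned), `bad_channels` (dropped indices).
#' @export
preprocess_eeg <- function(x, fs_in, onsets_s, offsets_s,
                           mode = c("nan", "interpolate"), fs_out = 128) {
  mode <- match.arg(mode)
  filt <- filter_reref(x, fs_in, fs_out = fs_out)
  trials <- epoch_trials(filt, fs_out, onsets_s, offsets_s)
  ts <- eeg_trial_set(trials, fs_out)
  bad <- detect_bad_electrodes(ts)
  if (length(bad)) {
    message("dropping bad electrode(s): ",
            paste(ts$channel_labels[bad], collapse = ", "))
    ts <- drop_channels(ts, bad)
  }
  list(trial_set = reject_transients(ts, mode), bad_channels = bad)
}
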