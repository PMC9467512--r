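## Stimulus-response correlation (time domain) and coherence
## (frequency domain) between a musical feature and a neural component.

#' Lagged (Toeplitz) design matrix of a stimulus feature
#'
#' Column j holds the feature delayed by j-1 samples (head zero-padded),
#' for lags 0 .. round(max_lag_s * fs), plus a final intercept column of
#' ones. At 128 Hz with a 1 s maximum shift this is 129 lag columns plus
#' the intercept. Lag 0 (the instantaneous term) is included.
#'
#' @param feature numeric vector or [feature_ts()].
#' @param fs sampling rate (Hz); taken from the feature if available.
#' @param max_lag_s maximum shift in seconds.
#' @return matrix with attributes `max_lag_samples` and `has_intercept`.
#' @export
build_lag_matrix <- function(feature, fs = NULL, max_lag_s = 1.0) {
  if (max_lag_s <= 0) stop_invalid("max_lag_s must be positive")
  v <- if (inherits(feature, "feature_ts")) feature$values else as.numeric(feature)
  if (is.null(fs)) fs <- if (inherits(feature, "feature_ts")) feature$fs else
    stop_invalid("fs required")
  max_lag <- round(max_lag_s * fs)
  n <- length(v)
  if (n <= max_lag) stop_invalid("feature shorter than the lag span")
  out <- matrix(0, n, max_lag + 2L)
  for (j in 0:max_lag) out[(j + 1L):n, j + 1L] <- v[seq_len(n - j)]
  out[, max_lag + 2L] <- 1
  attr(out, "max_lag_samples") <- max_lag
  attr(out, "has_intercept") <- TRUE
  out
}

#' Stimulus-response correlation (SRCorr)
#'
#' Fits a lagged temporal filter by least squares (Moore-Penrose
#' pseudoinverse of the Toeplitz design) mapping the feature onto the
#' neural component, then correlates the filtered feature with the
#' component. Equal to the square root of the R-squared of the lagged
#' multiple regression, so SRCorr lies in [0, 1].
#'
#' @param feature numeric vector or [feature_ts()].
#' @param component neural component time course, same length.
#' @param fs sampling rate (Hz).
#' @param max_lag_s maximum temporal shift (seconds).
#' @return scalar correlation with attribute `filter` (the temporal filter).
#' @export
srcorr <- function(feature, component, fs = NULL, max_lag_s = 1.0) {
  v <- if (inherits(feature, "feature_ts")) feature$values else as.numeric(feature)
  if (is.null(fs) && inherits(feature, "feature_ts")) fs <- feature$fs
  comp <- as.numeric(component)
  n <- min(length(v), length(comp))
  v <- v[seq_len(n)]; comp <- comp[seq_len(n)]
  if (stats::sd(comp) == 0) stop_invalid("constant component: correlation undefined")
  L <- build_lag_matrix(v, fs, max_lag_s)
  ok <- is.finite(comp)
  w <- qr.coef(qr(L[ok, , drop = FALSE]), comp[ok])
  w[is.na(w)] <- 0
  pred <- as.numeric(L %*% w)
  r <- stats::cor(pred[ok], comp[ok])
  attr(r, "filter") <- w
  r
}

#' Precomputed SRCorr metric for repeated evaluation
#'
#' Factors the lagged design once and returns a closure
#' `(neural, ...) -> SRCorr`, so surrogate z-scoring (dozens of
#' evaluations against the same feature) costs one triangular solve per
#' call instead of one QR factorization.
#'
#' @inheritParams srcorr
#' @return function of the neural component returning the SRCorr.
#' @export
srcorr_metric <- function(feature, fs = NULL, max_lag_s = 1.0) {
  v <- if (inherits(feature, "feature_ts")) feature$values else as.numeric(feature)
  if (is.null(fs) && inherits(feature, "feature_ts")) fs <- feature$fs
  L <- build_lag_matrix(v, fs, max_lag_s)
  qrL <- qr(L)
  n <- nrow(L)
  function(neural, ...) {
    comp <- as.numeric(neural)[seq_len(n)]
    if (stats::sd(comp) == 0) stop_invalid("constant component: correlation undefined")
    w <- qr.coef(qrL, comp)
    w[is.na(w)] <- 0
    stats::cor(as.numeric(L %*% w), comp)
  }
}

#' Stimulus-response coherence spectrum (SRCoh)
#'
#' Welch magnitude-squared coherence with a 5 s Hamming window, 50%
#' overlap and transforms zero-padded to give 0.125 Hz bins at 128 Hz:
#' `msc = |Sxy|^2 / (Sxx Syy)`, bounded in [0, 1].
#'
#' @param feature,component numeric vectors of equal length.
#' @param fs sampling rate (Hz).
#' @param window_s Welch window length in seconds.
#' @param overlap fractional window overlap.
#' @param nfft transform length; defaults to `fs / 0.125` rounded up to
#'   at least the window length.
#' @return object of class `coherence_spectrum` with `frequencies` (Hz)
#'   and `msc`.
#' @export
srcoh <- function(feature, component, fs = 128, window_s = 5, overlap = 0.5,
                  nfft = NULL) {
  x <- if (inherits(feature, "feature_ts")) feature$values else as.numeric(feature)
  if (inherits(feature, "feature_ts")) fs <- feature$fs
  y <- as.numeric(component)
  n <- min(length(x), length(y))
  x <- x[seq_len(n)]; y <- y[seq_len(n)]
  win_len <- round(window_s * fs)
  if (n < 2L * win_len) stop_invalid("input shorter than two Welch windows")
  if (is.null(nfft)) nfft <- max(win_len, ceiling(fs / 0.125))
  hop <- round(win_len * (1 - overlap))
  starts <- seq(1L, n - win_len + 1L, by = hop)
  w <- signal::hamming(win_len)
  sxx <- syy <- numeric(nfft)
  sxy <- complex(real = numeric(nfft), imaginary = numeric(nfft))
  for (s in starts) {
    seg_x <- (x[s:(s + win_len - 1L)] - mean(x[s:(s + win_len - 1L)])) * w
    seg_y <- (y[s:(s + win_len - 1L)] - mean(y[s:(s + win_len - 1L)])) * w
    X <- stats::fft(c(seg_x, numeric(nfft - win_len)))
    Y <- stats::fft(c(seg_y, numeric(nfft - win_len)))
    sxx <- sxx + Mod(X)^2
    syy <- syy + Mod(Y)^2
    sxy <- sxy + X * Conj(Y)
  }
  half <- seq_len(nfft %/% 2L + 1L)
  msc <- Mod(sxy[half])^2 / (sxx[half] * syy[half])
  msc[!is.finite(msc)] <- 0
  structure(list(frequencies = (half - 1L) * fs / nfft, msc = pmin(1, msc),
                 window_s = window_s, overlap = overlap,
                 n_windows = length(starts)),
            class = "coherence_spectrum")
}

#' @export
print.coherence_spectrum <- function(x, ...) {
  cat(sprintf("<coherence_spectrum> %d bins, %g-%g Hz (%d windows of %g s)\n",
              length(x$frequencies), min(x$frequencies), max(x$frequencies),
              x$n_windows, x$window_s))
  invisible(x)
}

#' Coherence at the stimulation tempo and its first harmonic
#'
#' Reads the magnitude-squared coherence at the bins nearest `tempo_hz`
#' and `2 * tempo_hz`, plus their mean and difference (fundamental minus
#' harmonic; negative when the harmonic dominates).
#'
#' @param spec a `coherence_spectrum`.
#' @param tempo_hz stimulation tempo (Hz).
#' @return list: `msc_f0`, `msc_2f0`, `mean`, `difference`.
#' @export
coh_at_tempo <- function(spec, tempo_hz) {
  stopifnot(inherits(spec, "coherence_spectrum"))
  if (2 * tempo_hz > max(spec$frequencies))
    stop_invalid("first harmonic above the spectrum range")
  i0 <- which.min(abs(spec$frequencies - tempo_hz))
  i1 <- which.min(abs(spec$frequencies - 2 * tempo_hz))
  msc_f0 <- spec$msc[i0]; msc_2f0 <- spec$msc[i1]
  list(msc_f0 = msc_f0, msc_2f0 = msc_2f0,
       mean = (msc_f0 + msc_2f0) / 2, difference = msc_f0 - msc_2f0)
}

#' Tidy stimulus-brain synchronization table for one condition
#'
#' @param feature,component aligned vectors.
#' @param fs sampling rate.
#' @param tempo_hz stimulation tempo.
#' @param participant participant label.
#' @param feature_name feature label.
#' @return one-row data.frame with srcorr, msc_f0, msc_2f0.
#' @export
stim_brain_table <- function(feature, component, fs = 128, tempo_hz = NA_real_,
                             participant = NA_character_,
                             feature_name = NA_character_) {
  r <- srcorr(feature, component, fs)
  ct <- coh_at_tempo(srcoh(feature, component, fs), tempo_hz)
  data.frame(participant = participant, tempo = tempo_hz,
             feature = feature_name, srcorr = as.numeric(r),
             msc_f0 = ct$msc_f0, msc_2f0 = ct$msc_2f0,
             stringsAsFactors = FALSE)
}
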