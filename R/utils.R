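## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(structure(class = c("beatsync_invalid_argument", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_invalid(name, " must be a positive finite scalar")
  invisible(x)
}

#' Analytic signal via the one-sided spectrum
#'
#' Returns the complex analytic signal whose real part is `x` and whose
#' modulus is the instantaneous amplitude (Hilbert envelope).
#'
#' @param x real numeric vector.
#' @return complex vector, same length as `x`.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  if (n == 0L) stop_invalid("empty input")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Z-score a vector with a degenerate-input guard
#'
#' Standardizes to mean 0, SD 1. A (near-)constant input cannot be
#' standardized; it is returned as all zeros with attribute
#' `degenerate = TRUE` rather than dividing by zero.
#'
#' @param x numeric vector.
#' @return numeric vector with attribute `degenerate` (logical).
#' @export
zscore <- function(x) {
  if (!is.numeric(x) || length(x) < 1L) stop_invalid("x must be a non-empty numeric vector")
  s <- stats::sd(x)
  if (!is.finite(s) || s < .Machine$double.eps * 1e3) {
    out <- numeric(length(x))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- (x - mean(x)) / s
  attr(out, "degenerate") <- FALSE
  out
}

## Linear interpolation of a uniformly sampled series onto a new rate.
## Assumes the input is already band-limited below the target Nyquist.
resample_linear <- function(x, fs_in, fs_out) {
  n <- length(x)
  t_in <- (seq_len(n) - 1L) / fs_in
  dur <- n / fs_in
  t_out <- seq(0, dur - 1 / fs_out, by = 1 / fs_out)
  stats::approx(t_in, x, xout = t_out, rule = 2)$y
}

## Zero-phase 4th-order Butterworth low-pass, guarded for short inputs.
lowpass_zero_phase <- function(x, fs, f_cut, order = 4L) {
  if (f_cut >= fs / 2) return(x)
  bf <- signal::butter(order, f_cut / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

## FFT-based linear convolution, full length n + m - 1 truncated to n
## (causal kernel applied to a signal).
conv_causal <- function(x, kernel) {
  n <- length(x); m <- length(kernel)
  nfft <- stats::nextn(n + m - 1L, 2)
  y <- Re(stats::fft(stats::fft(c(x, numeric(nfft - n))) *
                       stats::fft(c(kernel, numeric(nfft - m))), inverse = TRUE)) / nfft
  y[seq_len(n)]
}
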