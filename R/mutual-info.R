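## Mutual information between musical features.
##
## Plug-in MI on quantile-binned (equal-count) states, compared against
## time-reversal surrogates. With equal-count bins MI(X, X) is exactly
## log2(n_bins), a clean anchor for testing.

#' Quantile (equal-count) binning
#'
#' Assigns labels `0 .. n_bins-1` so that bin counts are equal to within
#' one. Ties are broken by sample order, so any strictly monotone
#' transform of the input yields identical labels.
#'
#' @param x numeric vector, length at least `n_bins`.
#' @param n_bins number of states.
#' @return integer label vector.
#' @export
quantile_bin <- function(x, n_bins = 4L) {
  if (length(x) < n_bins) stop_invalid("need at least n_bins samples")
  if (stats::sd(x) == 0 || !is.finite(stats::sd(x)))
    stop_invalid("constant input has no quantiles")
  r <- rank(x, ties.method = "first")
  as.integer(floor((r - 1L) * n_bins / length(x)))
}

#' Plug-in mutual information in bits
#'
#' Quantile-bins both series and evaluates
#' `sum p(i,j) log2(p(i,j) / (p(i) p(j)))` on the joint histogram.
#'
#' @param x,y numeric vectors of equal length.
#' @param n_bins number of quantile bins per variable.
#' @return object of class `mi_result` with fields `mi_bits`,
#'   `feature_pair`, `n_bins`.
#' @export
mi_bits <- function(x, y, n_bins = 4L) {
  if (length(x) != length(y)) stop_invalid("x and y must have equal length")
  bx <- quantile_bin(x, n_bins)
  by <- quantile_bin(y, n_bins)
  joint <- table(factor(bx, levels = 0:(n_bins - 1L)),
                 factor(by, levels = 0:(n_bins - 1L)))
  p <- joint / sum(joint)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  mi <- sum(p[nz] * log2(p[nz] / outer(px, py)[nz]))
  structure(list(mi_bits = max(0, mi), feature_pair = c(deparse(substitute(x)),
                                                        deparse(substitute(y))),
                 surrogate_mi_bits = NA_real_, n_bins = as.integer(n_bins)),
            class = "mi_result")
}

#' Mutual information with a time-reversal surrogate
#'
#' Computes MI between `x` and `y` and between `x` and the time-reversed
#' `y`. Reversal preserves the marginal distribution of `y` but destroys
#' its temporal alignment with `x`, so the difference isolates genuinely
#' shared temporal structure.
#'
#' @inheritParams mi_bits
#' @return `mi_result` with `surrogate_mi_bits` filled in.
#' @export
mi_surrogate <- function(x, y, n_bins = 4L) {
  res <- mi_bits(x, y, n_bins)
  res$surrogate_mi_bits <- mi_bits(x, rev(y), n_bins)$mi_bits
  res
}

#' @export
print.mi_result <- function(x, ...) {
  cat(sprintf("<mi_result> %.4f bits (%d bins)%s\n", x$mi_bits, x$n_bins,
              if (!is.na(x$surrogate_mi_bits))
                sprintf(", surrogate %.4f bits", x$surrogate_mi_bits) else ""))
  invisible(x)
}

#' Mutual information table across feature pairs
#'
#' Concatenates trials per tempo condition (in fixed trial order), then
#' computes data and time-reversal surrogate MI for every unordered pair
#' of features, emitting the tidy table consumed by downstream ANOVA.
#'
#' @param feature_sets named list; each element is a list of per-trial
#'   [feature_ts()] objects (or numeric vectors) for one feature.
#' @param tempo_hz tempo condition label.
#' @param subgroup stimulation subgroup label.
#' @param n_bins quantile bins.
#' @return data.frame: feature_pair, tempo, subgroup, mi_bits,
#'   surrogate_mi_bits.
#' @export
mi_feature_table <- function(feature_sets, tempo_hz = NA_real_,
                             subgroup = NA_character_, n_bins = 4L) {
  cat_one <- function(fl) {
    unlist(lapply(fl, function(f) if (inherits(f, "feature_ts")) f$values else as.numeric(f)))
  }
  series <- lapply(feature_sets, cat_one)
  nm <- names(series)
  pairs <- utils::combn(nm, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    r <- mi_surrogate(series[[a]], series[[b]], n_bins)
    data.frame(feature_pair = paste(a, b, sep = "-"), tempo = tempo_hz,
               subgroup = subgroup, mi_bits = r$mi_bits,
               surrogate_mi_bits = r$surrogate_mi_bits,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
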