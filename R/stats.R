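## Supporting statistics: repeated-measures ANOVA with
## Greenhouse-Geisser correction, FDR, per-participant tempo slopes,
## piecewise latency regression, ratings handling and the paired
## comparison effect size r_equivalent.

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Classical within-subjects ANOVA on a complete participant x condition
#' table. Sphericity is assessed with Mauchly's test; when rejected (at
#' `mauchly_alpha`), the Greenhouse-Geisser epsilon computed from the
#' condition covariance scales the degrees of freedom of the reported
#' p-value. Partial eta-squared is reported as the effect size.
#'
#' @param values numeric participant x condition matrix (complete).
#' @param mauchly_alpha threshold of the Mauchly test that triggers the
#'   correction.
#' @return list: `f`, `df1`, `df2`, `p` (uncorrected),
#'   `gg_epsilon`, `df1_gg`, `df2_gg`, `p_gg`, `p_reported` (corrected
#'   when sphericity is rejected), `mauchly_p`, `partial_eta_sq`.
#' @export
rm_anova_1way <- function(values, mauchly_alpha = 0.05) {
  x <- as.matrix(values)
  if (anyNA(x)) stop_invalid("missing cells in the participant x condition table")
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L) stop_invalid("need >= 2 participants and >= 2 conditions")
  grand <- mean(x)
  cond_means <- colMeans(x)
  subj_means <- rowMeans(x)
  ss_cond <- n * sum((cond_means - grand)^2)
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1L
  df2 <- (n - 1L) * (k - 1L)
  ms_cond <- ss_cond / df1
  ms_err <- ss_err / df2
  f <- if (ms_err > 0) ms_cond / ms_err else 0
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)

  ## Greenhouse-Geisser epsilon from the double-centered covariance.
  S <- stats::cov(x)
  dc <- S - outer(rowMeans(S), rep(1, k)) - outer(rep(1, k), colMeans(S)) + mean(S)
  eps <- sum(diag(dc))^2 / ((k - 1) * sum(dc^2))
  eps <- min(1, max(1 / (k - 1), eps))

  mauchly_p <- mauchly_p_value(x)
  use_gg <- !is.na(mauchly_p) && mauchly_p < mauchly_alpha
  df1_gg <- eps * df1
  df2_gg <- eps * df2
  p_gg <- stats::pf(f, df1_gg, df2_gg, lower.tail = FALSE)
  list(f = f, df1 = df1, df2 = df2, p = p,
       gg_epsilon = eps, df1_gg = df1_gg, df2_gg = df2_gg, p_gg = p_gg,
       p_reported = if (use_gg) p_gg else p, sphericity_rejected = use_gg,
       mauchly_p = mauchly_p,
       partial_eta_sq = if (ss_cond + ss_err > 0) ss_cond / (ss_cond + ss_err) else 0)
}

## Mauchly's sphericity test on orthonormal contrasts of the condition
## covariance; chi-square approximation. NA when k = 2 (trivially spherical)
## or the contrast covariance is singular.
mauchly_p_value <- function(x) {
  n <- nrow(x); k <- ncol(x)
  if (k <= 2L) return(NA_real_)
  C <- stats::contr.helmert(k)
  C <- qr.Q(qr(C))                               # orthonormal contrasts
  S <- crossprod(scale(x %*% C, center = TRUE, scale = FALSE)) / (n - 1)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) return(NA_real_)
  p_dim <- k - 1L
  W <- prod(ev) / (mean(ev)^p_dim)
  df <- p_dim * (p_dim + 1L) / 2L - 1L
  rho <- 1 - (2 * p_dim^2 + p_dim + 2) / (6 * p_dim * (n - 1))
  chi <- -(n - 1) * rho * log(W)
  stats::pchisq(chi, df, lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone in rank.
#'
#' @param p_values numeric vector in [0, 1].
#' @return adjusted p-values, same order as the input.
#' @export
fdr_bh <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop_invalid("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-participant linear tempo slopes of a synchronization metric
#'
#' Fits one ordinary least-squares line per participant to metric values
#' as a function of tempo; the slopes quantify tempo specificity and are
#' compared across features downstream with a one-way ANOVA.
#'
#' @param metric participant x tempo numeric matrix.
#' @param tempos tempo values (Hz), one per column.
#' @return numeric vector of slopes, one per participant.
#' @export
tempo_slopes <- function(metric, tempos) {
  x <- as.matrix(metric)
  if (length(tempos) != ncol(x)) stop_invalid("one tempo per column required")
  if (ncol(x) < 3L) stop_invalid("need at least 3 tempi")
  tc <- tempos - mean(tempos)
  as.numeric(x %*% tc) / sum(tc^2)
}

#' Piecewise linear regression of TRF latencies over tempo
#'
#' Fits independent OLS lines to the slow (tempo <= break) and fast
#' (tempo > break) segments, as used for latency profiles whose slope
#' changes between the 2.5 and 2.75 Hz conditions.
#'
#' @param latencies latency values (e.g. ms), one per tempo.
#' @param tempos tempo values (Hz), same length.
#' @param break_between two tempos; the breakpoint lies between them.
#' @return data.frame with one row per segment: slope, t, p, r_squared,
#'   n.
#' @export
piecewise_latency_fit <- function(latencies, tempos,
                                  break_between = c(2.5, 2.75)) {
  stopifnot(length(latencies) == length(tempos))
  cut_at <- mean(break_between)
  seg <- list(slow = tempos < cut_at, fast = tempos >= cut_at)
  rows <- lapply(names(seg), function(nm) {
    idx <- seg[[nm]]
    if (sum(idx) < 3L) stop_invalid("segment '", nm, "' has fewer than 3 tempi")
    fit <- stats::lm(latencies[idx] ~ tempos[idx])
    sm <- summary(fit)
    data.frame(segment = nm, slope = sm$coefficients[2L, 1L],
               t = sm$coefficients[2L, 3L], p = sm$coefficients[2L, 4L],
               r_squared = sm$r.squared, n = sum(idx),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Normalize subjective ratings per participant
#'
#' Divides each rating by the participant's maximum absolute rating in
#' that category, mapping onto [-1, 1].
#'
#' @param ratings numeric vector of ratings on [-100, 100].
#' @return normalized ratings.
#' @export
normalize_ratings <- function(ratings) {
  m <- max(abs(ratings))
  if (m == 0) return(ratings)
  ratings / m
}

#' Split trials by subjective rating
#'
#' Returns the `n` lowest- and `n` highest-rated trial indices on one
#' rating dimension, ignoring tempo condition; ties are broken by trial
#' order (with a warning when all ratings tie).
#'
#' @param ratings data.frame with one row per trial and the rating
#'   columns, or a numeric vector.
#' @param dimension column name when `ratings` is a data.frame.
#' @param n trials per extreme (default 15).
#' @return list with `low` and `high` integer index vectors.
#' @export
split_by_rating <- function(ratings, dimension = NULL, n = 15L) {
  v <- if (is.data.frame(ratings)) {
    if (is.null(dimension) || !dimension %in% names(ratings))
      stop_invalid("dimension must name a rating column")
    ratings[[dimension]]
  } else as.numeric(ratings)
  if (length(v) < 2L * n) stop_invalid("need at least 2n rated trials")
  if (length(unique(v)) == 1L) warning("all ratings equal; order-based split")
  ord <- order(v, seq_along(v))
  list(low = sort(ord[seq_len(n)]),
       high = sort(ord[(length(v) - n + 1L):length(v)]))
}

#' Effect size r_equivalent for a paired t-test
#'
#' `r = sqrt(t^2 / (t^2 + df))`.
#'
#' @param t t statistic.
#' @param df degrees of freedom.
#' @return scalar effect size in [0, 1).
#' @export
r_equivalent <- function(t, df) {
  sqrt(t^2 / (t^2 + df))
}

#' Paired comparison with r_equivalent
#'
#' Paired t-test between two matched measurement vectors, reporting the
#' r_equivalent effect size in a tidy row.
#'
#' @param a,b paired numeric vectors.
#' @param label comparison label.
#' @return one-row data.frame: test, statistic, df, p, effect_size.
#' @export
paired_comparison <- function(a, b, label = "paired") {
  tt <- stats::t.test(a, b, paired = TRUE)
  data.frame(test = label, statistic = unname(tt$statistic),
             df = unname(tt$parameter), p = tt$p.value,
             effect_size = r_equivalent(unname(tt$statistic),
                                        unname(tt$parameter)),
             stringsAsFactors = FALSE)
}
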