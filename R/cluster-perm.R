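## Cluster-based permutation testing of TRF weight time courses across
## tempo conditions. A one-way ANOVA across tempi is run at each time
## lag; runs of consecutive lags with p below the cluster-forming alpha
## are clusters, scored by their summed F. Significance is assessed
## against a null built by shuffling each participant's tempo labels and
## retaining the maximum cluster statistic per permutation (family-wise
## control over lags).

## Vectorized one-way ANOVA across the tempo dimension of a
## participant x tempo x lag array; returns F and p per lag.
anova_f_lags <- function(w) {
  n_p <- dim(w)[1L]; n_t <- dim(w)[2L]; n_l <- dim(w)[3L]
  gm <- apply(w, c(2L, 3L), mean)                  # tempo x lag group means
  m <- colMeans(gm)                                # grand mean per lag
  ssb <- n_p * colSums((gm - rep(m, each = n_t))^2)
  ssw <- apply((w - aperm(array(gm, dim = c(n_t, n_l, n_p)), c(3L, 1L, 2L)))^2,
               3L, sum)
  df1 <- n_t - 1L
  df2 <- n_p * n_t - n_t
  f <- (ssb / df1) / (ssw / df2)
  f[!is.finite(f)] <- 0
  list(f = f, p = stats::pf(f, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2)
}

#' Pointwise one-way ANOVA of TRF weights across tempi
#'
#' At each time lag, tests whether weights differ across tempo
#' conditions, with participants as observations.
#'
#' @param weights participant x tempo x lag numeric array.
#' @return data.frame with `lag`, `f`, `p` (plus `df1`/`df2` attributes).
#' @export
pointwise_f <- function(weights) {
  stopifnot(length(dim(weights)) == 3L)
  if (dim(weights)[1L] < 2L) stop_invalid("need at least 2 participants")
  if (dim(weights)[2L] < 2L) stop_invalid("need at least 2 tempo conditions")
  res <- anova_f_lags(weights)
  out <- data.frame(lag = seq_along(res$f), f = res$f, p = res$p)
  attr(out, "df1") <- res$df1
  attr(out, "df2") <- res$df2
  out
}

#' Identify clusters of consecutive supra-threshold lags
#'
#' @param p_series pointwise p-values along the lag axis.
#' @param f_series aligned F statistics.
#' @param alpha cluster-forming threshold.
#' @return data.frame with `start`, `end` (lag indices, inclusive) and
#'   `summed_f`; zero rows when nothing crosses the threshold.
#' @export
find_clusters <- function(p_series, f_series, alpha = 0.01) {
  stopifnot(length(p_series) == length(f_series))
  below <- p_series < alpha
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(start = starts[keep], end = ends[keep],
             summed_f = vapply(keep, function(i)
               sum(f_series[starts[i]:ends[i]]), numeric(1)))
}

#' Cluster-based permutation test across tempo conditions
#'
#' Observed clusters are formed from the pointwise ANOVA at
#' `alpha_cluster`; the null distribution collects, for each of `n_perm`
#' within-participant shuffles of the tempo labels, the maximum cluster
#' summed-F (or, with `null = "all"`, every cluster's summed F). Each
#' observed cluster receives `p = (1 + #{null >= observed}) / (1 + n_perm)`.
#'
#' @param weights participant x tempo x lag array.
#' @param n_perm number of label permutations.
#' @param alpha_cluster cluster-forming threshold on pointwise p.
#' @param alpha_final significance level for clusters.
#' @param seed integer seed.
#' @param lag_axis_ms optional lag axis in ms for reporting.
#' @param null `"max"` (family-wise max-cluster null) or `"all"`.
#' @return object of class `cluster_result`: data.frame `clusters`
#'   (start/end lag and ms, summed_f, p_value, significant) plus the
#'   null distribution and parameters.
#' @export
cluster_permutation_test <- function(weights, n_perm = 1000L,
                                     alpha_cluster = 0.01, alpha_final = 0.05,
                                     seed = 1L, lag_axis_ms = NULL,
                                     null = c("max", "all")) {
  null <- match.arg(null)
  stopifnot(length(dim(weights)) == 3L)
  if (n_perm < 2L) stop_invalid("n_perm must be at least 2")
  if (n_perm < 100L) warning("fewer than 100 permutations: p-values are coarse")
  n_p <- dim(weights)[1L]; n_t <- dim(weights)[2L]; n_l <- dim(weights)[3L]
  obs <- anova_f_lags(weights)
  clusters <- find_clusters(obs$p, obs$f, alpha_cluster)

  set.seed(seed)
  null_stat <- numeric(0)
  for (b in seq_len(n_perm)) {
    wp <- weights
    for (p_i in seq_len(n_p)) {
      wp[p_i, , ] <- weights[p_i, sample.int(n_t), ]
    }
    res <- anova_f_lags(wp)
    cl <- find_clusters(res$p, res$f, alpha_cluster)
    stat <- if (nrow(cl) == 0L) 0 else
      if (null == "max") max(cl$summed_f) else cl$summed_f
    null_stat <- c(null_stat, stat)
  }
  if (nrow(clusters)) {
    clusters$p_value <- vapply(clusters$summed_f, function(s)
      (1 + sum(null_stat >= s)) / (1 + length(null_stat)), numeric(1))
    clusters$significant <- clusters$p_value < alpha_final
  } else {
    clusters$p_value <- numeric(0)
    clusters$significant <- logical(0)
  }
  if (!is.null(lag_axis_ms) && nrow(clusters)) {
    clusters$start_ms <- lag_axis_ms[clusters$start]
    clusters$end_ms <- lag_axis_ms[clusters$end]
  }
  structure(list(clusters = clusters, null_distribution = null_stat,
                 alpha_cluster = alpha_cluster, alpha_final = alpha_final,
                 n_permutations = as.integer(n_perm), seed = as.integer(seed)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s), %d permutations\n",
              nrow(x$clusters), x$n_permutations))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}
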