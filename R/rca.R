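## Reliable (correlated) components analysis.
##
## RCA finds spatial filters w maximizing the correlation of the
## filtered time courses across participants. With Rxy the symmetrized
## sum of between-participant cross-covariances and Rw the pooled
## within-participant covariance, the filters solve the generalized
## eigenproblem Rxy w = lambda Rw w; eigenvalues order components by
## reliability. Covariances are computed pairwise-complete so NaN-marked
## samples (from transient rejection) are tolerated.

#' Fit reliable components across participants
#'
#' @param datasets list of time x channel matrices, one per participant,
#'   equal dimensions; NaN marks invalid samples.
#' @param n_components number of components to retain.
#' @param ridge_frac diagonal shrinkage fraction applied to the pooled
#'   covariance so it is invertible (average-referenced data are rank
#'   deficient by one).
#' @param min_overlap minimum fraction of jointly valid samples required
#'   for every pairwise covariance entry.
#' @return object of class `rca_model` with `filters`, `forward`,
#'   `reliabilities` (descending) and `n_components`.
#' @export
fit_rca <- function(datasets, n_components = 3L, ridge_frac = 1e-6,
                    min_overlap = 0.5) {
  if (!is.list(datasets) || length(datasets) < 2L)
    stop_invalid("need at least 2 participants")
  dims <- vapply(datasets, dim, integer(2))
  if (length(unique(dims[2L, ])) != 1L) stop_invalid("unequal channel counts")
  if (length(unique(dims[1L, ])) != 1L) stop_invalid("unequal time lengths")
  d <- dims[2L, 1L]
  n_p <- length(datasets)

  valid_frac <- function(a, b) {
    va <- !is.na(a[, 1L]); vb <- !is.na(b[, 1L])
    mean(va & vb)
  }
  pc_cov <- function(a, b) stats::cov(a, b, use = "pairwise.complete.obs")

  rxy <- matrix(0, d, d)
  rw <- matrix(0, d, d)
  for (i in seq_len(n_p)) {
    rw_i <- pc_cov(datasets[[i]], datasets[[i]])
    if (anyNA(rw_i)) stop_invalid("within-participant covariance undefined for participant ", i)
    rw <- rw + rw_i
    for (j in seq_len(n_p)) {
      if (i == j) next
      if (valid_frac(datasets[[i]], datasets[[j]]) < min_overlap)
        stop_invalid("participants ", i, " and ", j,
                     " share fewer than ", round(100 * min_overlap),
                     "% valid samples")
      rxy <- rxy + pc_cov(datasets[[i]], datasets[[j]])
    }
  }
  rxy <- (rxy + t(rxy)) / 2                 # guarantee a real spectrum
  rw_reg <- rw + ridge_frac * mean(diag(rw)) * diag(d)

  ## Whiten by Rw, then symmetric eigendecomposition.
  ew <- eigen(rw_reg, symmetric = TRUE)
  if (min(ew$values) <= 0)
    stop_invalid("pooled covariance not positive definite (dimension ",
                 which.min(ew$values), "); increase ridge_frac")
  whiten <- ew$vectors %*% diag(1 / sqrt(ew$values)) %*% t(ew$vectors)
  m <- whiten %*% rxy %*% whiten
  m <- (m + t(m)) / 2
  es <- eigen(m, symmetric = TRUE)
  filters <- whiten %*% es$vectors[, seq_len(n_components), drop = FALSE]
  reliabilities <- es$values[seq_len(n_components)]

  forward <- rw %*% filters %*% solve(t(filters) %*% rw %*% filters)
  ## Sign convention: largest-magnitude forward coefficient positive.
  for (k in seq_len(n_components)) {
    s <- sign(forward[which.max(abs(forward[, k])), k])
    if (s < 0) { forward[, k] <- -forward[, k]; filters[, k] <- -filters[, k] }
  }
  structure(list(filters = filters, forward = forward,
                 reliabilities = reliabilities,
                 n_components = as.integer(n_components)),
            class = "rca_model")
}

#' @export
print.rca_model <- function(x, ...) {
  cat(sprintf("<rca_model> %d channels, %d components; reliabilities: %s\n",
              nrow(x$filters), x$n_components,
              paste(signif(x$reliabilities, 3), collapse = ", ")))
  invisible(x)
}

#' Project a dataset onto a reliable component
#'
#' @param dataset time x channel matrix (channel count matching the model).
#' @param model an `rca_model`.
#' @param component component index (1 = most reliable).
#' @return numeric component time course; NA samples propagate.
#' @export
rca_project <- function(dataset, model, component = 1L) {
  stopifnot(inherits(model, "rca_model"))
  if (component < 1L || component > model$n_components)
    stop_invalid("component index out of range")
  if (ncol(dataset) != nrow(model$filters))
    stop_invalid("channel count does not match model")
  as.numeric(as.matrix(dataset) %*% model$filters[, component])
}

#' Export component topographies as a tidy table
#' @param model an `rca_model`.
#' @param channel_labels channel names.
#' @return data.frame: channel, component, weight (forward projection).
#' @export
rca_topography_table <- function(model, channel_labels = NULL) {
  d <- nrow(model$forward)
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(d))
  data.frame(channel = rep(channel_labels, model$n_components),
             component = rep(seq_len(model$n_components), each = d),
             weight = as.numeric(model$forward), stringsAsFactors = FALSE)
}
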