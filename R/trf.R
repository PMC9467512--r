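## Forward (encoding) temporal response functions.
##
## A TRF is a lag-resolved linear filter mapping stimulus features onto
## the neural response, estimated by ridge regression over lags
## 0-400 ms. The ridge parameter is chosen by leave-one-trial-out
## cross-validation over a 13-point grid of powers of ten (1e-6..1e6),
## maximizing the mean Pearson correlation between predicted and actual
## EEG across held-out trials and electrodes.

#' Lagged multi-feature design matrix for TRF estimation
#'
#' Horizontal concatenation of one lagged block per feature (lags
#' `0 .. round(lag_hi_ms/1000 * fs)` samples; 52 columns per feature at
#' 128 Hz) plus a single trailing intercept column.
#'
#' @param features numeric vector, time x feature matrix, or list of
#'   feature vectors / [feature_ts()] objects (equal lengths).
#' @param fs sampling rate (Hz).
#' @param lag_lo_ms,lag_hi_ms lag window in milliseconds.
#' @return design matrix with attributes `n_features`, `n_lags`,
#'   `lag_axis_ms`.
#' @export
build_design <- function(features, fs = 128, lag_lo_ms = 0, lag_hi_ms = 400) {
  if (lag_hi_ms <= lag_lo_ms) stop_invalid("lag_hi_ms must exceed lag_lo_ms")
  fm <- features_as_matrix(features)
  n <- nrow(fm); n_feat <- ncol(fm)
  lag_lo <- round(lag_lo_ms / 1000 * fs)
  lag_hi <- round(lag_hi_ms / 1000 * fs)
  lags <- lag_lo:lag_hi
  if (n <= length(lags)) stop_invalid("lag window longer than the data")
  out <- matrix(0, n, n_feat * length(lags) + 1L)
  col <- 1L
  for (f in seq_len(n_feat)) {
    for (j in lags) {
      if (j >= 0) out[(j + 1L):n, col] <- fm[seq_len(n - j), f]
      else out[seq_len(n + j), col] <- fm[(1L - j):n, f]
      col <- col + 1L
    }
  }
  out[, col] <- 1
  attr(out, "n_features") <- n_feat
  attr(out, "n_lags") <- length(lags)
  attr(out, "lag_axis_ms") <- lags / fs * 1000
  out
}

features_as_matrix <- function(features) {
  if (is.list(features) && !is.data.frame(features)) {
    cols <- lapply(features, function(f)
      if (inherits(f, "feature_ts")) f$values else as.numeric(f))
    n <- min(lengths(cols))
    return(do.call(cbind, lapply(cols, function(v) v[seq_len(n)])))
  }
  if (inherits(features, "feature_ts")) return(matrix(features$values, ncol = 1L))
  if (is.matrix(features)) return(features)
  matrix(as.numeric(features), ncol = 1L)
}

#' Ridge regression fit of a TRF
#'
#' Solves `(S'S + lambda * m * I) w = S'r` per electrode, where `m` is
#' the mean diagonal of `S'S` over penalized columns (so lambda is
#' expressed in units of the design's own scale) and the intercept
#' column is left unpenalized.
#'
#' @param design matrix from [build_design()] (or any matrix whose last
#'   column is the intercept).
#' @param response numeric vector or time x electrode matrix.
#' @param lambda_ ridge parameter, >= 0.
#' @param fs sampling rate, carried into the model.
#' @return object of class `trf_model` with `weights`
#'   (feature x lag x electrode), `intercept`, `lambda_`, `fs`,
#'   `lag_axis_ms`.
#' @export
ridge_fit <- function(design, response, lambda_, fs = 128) {
  if (lambda_ < 0) stop_invalid("lambda_ must be nonnegative")
  r <- if (is.matrix(response)) response else matrix(as.numeric(response), ncol = 1L)
  if (nrow(design) != nrow(r)) stop_invalid("design and response row mismatch")
  xtx <- crossprod(design)
  xtr <- crossprod(design, r)
  fit <- ridge_solve(xtx, xtr, lambda_)
  trf_model_from_coef(fit, design, lambda_, fs)
}

## Solve the penalized normal equations from precomputed cross-products.
ridge_solve <- function(xtx, xtr, lambda_) {
  p <- ncol(xtx)
  pen <- diag(p)
  pen[p, p] <- 0                                   # intercept unpenalized
  scale <- mean(diag(xtx)[-p])
  a <- xtx + lambda_ * scale * pen
  w <- tryCatch(solve(a, xtr), error = function(e)
    stop_invalid("singular system; use lambda_ > 0 for collinear designs"))
  w
}

trf_model_from_coef <- function(w, design, lambda_, fs) {
  n_feat <- attr(design, "n_features") %||% 1L
  n_lags <- attr(design, "n_lags") %||% (nrow(w) - 1L)
  lag_axis <- attr(design, "lag_axis_ms") %||% ((seq_len(n_lags) - 1L) / fs * 1000)
  n_el <- ncol(w)
  weights <- array(w[seq_len(n_feat * n_lags), , drop = FALSE],
                   dim = c(n_lags, n_feat, n_el))
  weights <- aperm(weights, c(2L, 1L, 3L))         # feature x lag x electrode
  structure(list(weights = weights, intercept = w[nrow(w), ],
                 coef = w, lambda_ = lambda_, fs = fs,
                 lag_axis_ms = lag_axis),
            class = "trf_model")
}

#' @export
print.trf_model <- function(x, ...) {
  d <- dim(x$weights)
  cat(sprintf("<trf_model> %d feature(s) x %d lags x %d electrode(s), lambda = %g\n",
              d[1L], d[2L], d[3L], x$lambda_))
  invisible(x)
}

#' Predict EEG from a fitted TRF
#' @param object a `trf_model`.
#' @param design design matrix built with the same lag window.
#' @param ... unused.
#' @return time x electrode matrix of predictions.
#' @export
predict.trf_model <- function(object, design, ...) {
  design %*% object$coef
}

#' Leave-one-trial-out cross-validated TRF
#'
#' For each ridge parameter on the grid and each held-out trial, trains
#' on the remaining trials (summed cross-products, so the cost per fold
#' is one linear solve), predicts the held-out EEG, and scores the
#' per-electrode Pearson correlation between predicted and actual data
#' (the TRF correlation). The lambda maximizing the mean correlation
#' over trials and electrodes is selected and the final model is trained
#' on all trials at that lambda.
#'
#' @param trials list of trials; each a list with `features` (vector,
#'   matrix or list) and `response` (time x electrode matrix).
#' @param fs sampling rate (Hz).
#' @param lambda_grid candidate ridge parameters.
#' @param lag_lo_ms,lag_hi_ms lag window (ms).
#' @return list of class `trf_cv`: `model` (final `trf_model`),
#'   `evaluation` (`trf_evaluation`: per-trial x electrode r at the
#'   chosen lambda, mean r, lambda path).
#' @export
crossval_trf <- function(trials, fs = 128, lambda_grid = 10^(-6:6),
                         lag_lo_ms = 0, lag_hi_ms = 400) {
  if (length(trials) < 3L) stop_invalid("need at least 3 trials per condition")
  designs <- lapply(trials, function(tr)
    build_design(tr$features, fs, lag_lo_ms, lag_hi_ms))
  responses <- lapply(trials, function(tr)
    if (is.matrix(tr$response)) tr$response else matrix(tr$response, ncol = 1L))
  n_trials <- length(trials)
  n_el <- ncol(responses[[1L]])
  xtx_all <- mapply(function(d, r) crossprod(d), designs, responses, SIMPLIFY = FALSE)
  xtr_all <- mapply(function(d, r) crossprod(d, r), designs, responses, SIMPLIFY = FALSE)
  xtx_sum <- Reduce(`+`, xtx_all)
  xtr_sum <- Reduce(`+`, xtr_all)

  r_grid <- array(NA_real_, dim = c(length(lambda_grid), n_trials, n_el))
  for (li in seq_along(lambda_grid)) {
    for (k in seq_len(n_trials)) {
      w <- ridge_solve(xtx_sum - xtx_all[[k]], xtr_sum - xtr_all[[k]],
                       lambda_grid[li])
      pred <- designs[[k]] %*% w
      for (e in seq_len(n_el)) {
        y <- responses[[k]][, e]
        ok <- is.finite(y)
        r_grid[li, k, e] <- suppressWarnings(stats::cor(pred[ok, e], y[ok]))
      }
    }
  }
  r_grid[is.na(r_grid)] <- 0
  mean_r_by_lambda <- apply(r_grid, 1L, mean)
  best <- which.max(mean_r_by_lambda)
  lambda_best <- lambda_grid[best]
  w_final <- ridge_solve(xtx_sum, xtr_sum, lambda_best)
  model <- trf_model_from_coef(w_final, designs[[1L]], lambda_best, fs)
  per_trial_r <- r_grid[best, , , drop = TRUE]
  per_trial_r <- matrix(per_trial_r, nrow = n_trials, ncol = n_el)
  evaluation <- structure(list(
    per_trial_per_electrode_r = per_trial_r,
    electrode_mean_r = colMeans(per_trial_r),
    mean_r = mean(per_trial_r),
    lambda_path = data.frame(lambda = lambda_grid, mean_r = mean_r_by_lambda),
    lambda_ = lambda_best), class = "trf_evaluation")
  structure(list(model = model, evaluation = evaluation), class = "trf_cv")
}

#' @export
print.trf_cv <- function(x, ...) {
  cat(sprintf("<trf_cv> lambda = %g, mean validation r = %.4f (best electrode %.4f)\n",
              x$model$lambda_, x$evaluation$mean_r,
              max(x$evaluation$electrode_mean_r)))
  invisible(x)
}

#' Select the electrodes with the highest TRF correlations
#'
#' @param evaluation a `trf_evaluation` (or numeric vector of mean r per
#'   electrode).
#' @param k number of electrodes (the study averaged 7-8).
#' @return integer indices of the k largest mean correlations; ties are
#'   broken toward lower indices (with a warning when the r map is flat).
#' @export
select_top_electrodes <- function(evaluation, k = 8L) {
  r <- if (inherits(evaluation, "trf_evaluation"))
    evaluation$electrode_mean_r else as.numeric(evaluation)
  if (k <= 0) stop_invalid("k must be positive")
  if (k > length(r)) stop_invalid("k exceeds electrode count")
  if (length(unique(r)) == 1L) warning("all electrodes tie; taking the first k")
  order(-r, seq_along(r))[seq_len(k)]
}

## Leave-one-trial-out mean validation r at a fixed lambda from
## precomputed designs/responses; electrodes restricts the average.
loo_mean_r <- function(designs, responses, xtx_all, xtr_all, lambda_,
                       electrodes = NULL) {
  xtx_sum <- Reduce(`+`, xtx_all)
  xtr_sum <- Reduce(`+`, xtr_all)
  n_el <- ncol(responses[[1L]])
  electrodes <- electrodes %||% seq_len(n_el)
  r_all <- matrix(NA_real_, length(designs), n_el)
  for (k in seq_along(designs)) {
    w <- ridge_solve(xtx_sum - xtx_all[[k]], xtr_sum - xtr_all[[k]], lambda_)
    pred <- designs[[k]] %*% w
    for (e in electrodes)
      r_all[k, e] <- suppressWarnings(stats::cor(pred[, e], responses[[k]][, e]))
  }
  r_all[is.na(r_all)] <- 0
  mean(r_all[, electrodes])
}

#' Surrogate z-score of the cross-validated TRF correlation
#'
#' Rotates the neural response of each trial by an independent random
#' offset (guard band of one second around zero shift), re-runs the
#' leave-one-trial-out evaluation at the given lambda, and z-scores the
#' observed mean TRF correlation against the surrogate distribution.
#' Shifts are drawn per trial rather than once per iteration so that,
#' for quasi-periodic stimuli, a single lag filter cannot realign every
#' rotated trial simultaneously — the trial-structured analogue of
#' shifting the concatenated neural time course. The lagged designs and
#' their cross-products are reused across iterations, so each iteration
#' costs one solve per fold.
#'
#' @inheritParams crossval_trf
#' @param lambda_ ridge parameter (typically the cross-validated choice).
#' @param electrodes electrode indices the mean r is averaged over
#'   (default all).
#' @param n_iter surrogate iterations.
#' @param seed integer seed.
#' @return `surrogate_summary` for the mean TRF correlation.
#' @export
trf_surrogate_z <- function(trials, fs = 128, lambda_, electrodes = NULL,
                            n_iter = 50L, seed = 1L,
                            lag_lo_ms = 0, lag_hi_ms = 400) {
  designs <- lapply(trials, function(tr)
    build_design(tr$features, fs, lag_lo_ms, lag_hi_ms))
  responses <- lapply(trials, function(tr)
    if (is.matrix(tr$response)) tr$response else matrix(tr$response, ncol = 1L))
  xtx_all <- lapply(designs, crossprod)
  xtr_for <- function(resps) mapply(crossprod, designs, resps, SIMPLIFY = FALSE)
  raw <- loo_mean_r(designs, responses, xtx_all, xtr_for(responses), lambda_,
                    electrodes)
  n <- min(vapply(responses, nrow, integer(1)))
  guard <- as.integer(fs)
  if (n <= 2L * guard) stop_invalid("trials too short for the guard band")
  shifts <- local({
    set.seed(seed)
    matrix(sample.int(n - 2L * guard, n_iter * length(responses),
                      replace = TRUE) + guard,
           nrow = n_iter)
  })
  sur <- vapply(seq_len(n_iter), function(it) {
    shifted <- lapply(seq_along(responses), function(tr) {
      apply(responses[[tr]], 2L, circular_shift, k = shifts[it, tr])
    })
    loo_mean_r(designs, shifted, xtx_all, xtr_for(shifted), lambda_, electrodes)
  }, numeric(1))
  s <- stats::sd(sur)
  if (!is.finite(s) || s == 0) stop_invalid("degenerate surrogate distribution (sd = 0)")
  structure(list(z = (raw - mean(sur)) / s, raw = raw, mean = mean(sur),
                 sd = s, n_iterations = as.integer(n_iter),
                 shifts_used = shifts, seed = as.integer(seed)),
            class = "surrogate_summary")
}

#' Residualized TRF of a target feature
#'
#' Tests whether the target feature predicts the EEG over and above a
#' set of nuisance features: stage 1 fits a multivariate TRF on the
#' nuisance features and predicts the EEG; stage 2 fits a TRF of the
#' target feature on the residual (actual minus predicted) EEG.
#'
#' @param trials list of trials; each a list with named `features` (list
#'   including `target` and all `nuisance` names) and `response`.
#' @param target_feature name of the feature of interest.
#' @param nuisance_features names of the features partialed out.
#' @param fs sampling rate.
#' @param lambda_grid ridge grid for both stages.
#' @return list of class `trf_cv` for the stage-2 (residual) model, with
#'   the stage-1 cross-validation attached as `$stage1`.
#' @export
residualized_trf <- function(trials, target_feature = "flux",
                             nuisance_features = c("envelope", "derivative", "beats"),
                             fs = 128, lambda_grid = 10^(-6:6)) {
  for (tr in trials) {
    missing <- setdiff(c(target_feature, nuisance_features), names(tr$features))
    if (length(missing)) stop_invalid("missing feature(s): ",
                                      paste(missing, collapse = ", "))
  }
  nuis_trials <- lapply(trials, function(tr)
    list(features = tr$features[nuisance_features], response = tr$response))
  stage1 <- crossval_trf(nuis_trials, fs, lambda_grid)
  resid_trials <- lapply(trials, function(tr) {
    d <- build_design(tr$features[nuisance_features], fs)
    pred <- predict(stage1$model, d)
    resp <- if (is.matrix(tr$response)) tr$response else matrix(tr$response, ncol = 1L)
    list(features = tr$features[target_feature], response = resp - pred)
  })
  out <- crossval_trf(resid_trials, fs, lambda_grid)
  out$stage1 <- stage1
  out
}

#' Standardize TRF weights across the lag axis
#'
#' Per feature and electrode, the lag-resolved weight vector is z-scored
#' (mean 0, SD 1 across lags) so weight time courses are comparable
#' across conditions and participants. Constant weight vectors cannot be
#' standardized and are returned as zeros with a degenerate flag.
#'
#' @param model a `trf_model` (or a feature x lag x electrode array).
#' @return array of normalized weights with attribute `degenerate`
#'   (feature x electrode logical matrix).
#' @export
normalize_weights <- function(model) {
  w <- if (inherits(model, "trf_model")) model$weights else model
  stopifnot(length(dim(w)) == 3L)
  if (dim(w)[2L] < 2L) stop_invalid("need at least 2 lags")
  out <- w
  degen <- matrix(FALSE, dim(w)[1L], dim(w)[3L])
  for (f in seq_len(dim(w)[1L])) for (e in seq_len(dim(w)[3L])) {
    z <- zscore(w[f, , e])
    out[f, , e] <- z
    degen[f, e] <- isTRUE(attr(z, "degenerate"))
  }
  attr(out, "degenerate") <- degen
  out
}
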