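test_that("the TRF design has 52 lag columns per feature plus intercept", {
  set.seed(1)
  v <- rnorm(600)
  d1 <- build_design(v, fs = 128)
  expect_equal(ncol(d1), 53)                     # 0..51 lags + intercept
  d4 <- build_design(list(v, v, v, v), fs = 128)
  expect_equal(ncol(d4), 4 * 52 + 1)

  imp <- c(1, numeric(299))
  di <- build_design(imp, fs = 128)
  expect_equal(which(di[10, 1:52] == 1), 10)     # shifted identity pattern
  expect_error(build_design(rnorm(30), fs = 128),
               class = "beatsync_invalid_argument")
})

test_that("ridge limits: OLS at 0, shrinkage to zero at infinity", {
  set.seed(2)
  X <- cbind(matrix(rnorm(100 * 4), 100, 4), 1)
  attr(X, "n_features") <- 1L; attr(X, "n_lags") <- 4L
  attr(X, "lag_axis_ms") <- 0:3
  y <- rnorm(100)
  fit0 <- ridge_fit(X, y, 0)
  beta_ols <- solve(crossprod(X), crossprod(X, y))
  expect_lt(max(abs(fit0$coef - beta_ols)), 1e-8)

  fit_inf <- ridge_fit(X, y, 1e12)
  expect_lt(max(abs(fit_inf$weights)), 1e-6)
  expect_equal(unname(fit_inf$intercept), mean(y), tolerance = 1e-4)

  expect_error(ridge_fit(X, y, -1), class = "beatsync_invalid_argument")
  Xc <- cbind(X[, 1], X[, 1], 1)   # collinear at lambda 0
  expect_error(ridge_fit(Xc, y, 0), class = "beatsync_invalid_argument")
})

test_that("noiseless responses are identified exactly", {
  set.seed(3)
  feat <- smooth_noise_feature(800)
  X <- build_design(feat, fs = 128)
  w_true <- c(as.numeric(default_kernel(128)), 0)   # 52 lags + intercept
  y <- as.numeric(X %*% w_true)
  fit <- ridge_fit(X, y, 1e-6)
  expect_lt(max(abs(fit$coef - w_true)), 1e-3)
})

test_that("cross-validation recovers the generating kernel", {
  trials <- make_kernel_trials(n_trials = 8, duration_s = 10, snr_db = 10,
                               n_channels = 4, seed = 4)
  cv <- crossval_trf(trials, fs = 128)
  expect_gt(max(cv$evaluation$electrode_mean_r), 0.5)
  best <- which.max(cv$evaluation$electrode_mean_r)
  k_est <- cv$model$weights[1L, , best]
  expect_gte(cor(k_est, as.numeric(default_kernel(128))), 0.9)
  # lag axis in ms over [0, 400]
  expect_equal(range(cv$model$lag_axis_ms), c(0, 51 / 128 * 1000))
})

test_that("validation r is honestly near zero for pure noise", {
  rs <- vapply(1:20, function(seed) {
    set.seed(seed)
    trials <- lapply(1:4, function(i)
      list(features = smooth_noise_feature(640),
           response = matrix(rnorm(640), ncol = 1)))
    crossval_trf(trials, fs = 128)$evaluation$mean_r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("validation never beats training in median and lambda is stable", {
  set.seed(5)
  trials <- make_kernel_trials(n_trials = 6, duration_s = 8, snr_db = 0,
                               n_channels = 2, seed = 6)
  cv <- crossval_trf(trials, fs = 128)
  # training r at the chosen lambda
  d <- lapply(trials, function(tr) build_design(tr$features, 128))
  X <- do.call(rbind, d)
  y <- do.call(rbind, lapply(trials, `[[`, "response"))
  fit <- ridge_fit(X, y, cv$model$lambda_)
  train_r <- mean(sapply(seq_len(ncol(y)), function(e)
    cor(as.numeric(X %*% fit$coef[, e]), y[, e])))
  expect_gte(train_r, cv$evaluation$mean_r)

  # duplicating every trial: the held-out trial's duplicate now sits in
  # the training set, so the selection can only drift toward weaker
  # regularization, never stronger
  cv2 <- crossval_trf(c(trials, trials), fs = 128)
  expect_lte(cv2$model$lambda_, cv$model$lambda_)

  expect_error(crossval_trf(trials[1:2], fs = 128),
               class = "beatsync_invalid_argument")
})

test_that("kernel recovery degrades monotonically as SNR drops", {
  med_r <- vapply(c(10, 0, -10), function(snr) {
    median(vapply(1:3, function(seed) {
      trials <- make_kernel_trials(n_trials = 6, duration_s = 8,
                                   snr_db = snr, n_channels = 2,
                                   seed = 100 + seed)
      cv <- crossval_trf(trials, fs = 128)
      best <- which.max(cv$evaluation$electrode_mean_r)
      cor(cv$model$weights[1L, , best], as.numeric(default_kernel(128)))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med_r) < 0))
  expect_gte(med_r[1L], 0.9)
})

test_that("electrode selection takes the k best, with deterministic ties", {
  ev <- structure(list(electrode_mean_r = c(0.2, 0.9, 0.1, 0.5)),
                  class = "trf_evaluation")
  expect_equal(select_top_electrodes(ev, 1), 2L)
  expect_equal(sort(select_top_electrodes(ev, 2)), c(2L, 4L))
  expect_warning(flat <- select_top_electrodes(rep(0.3, 6), 3), "tie")
  expect_equal(flat, 1:3)
  expect_error(select_top_electrodes(ev, 0), class = "beatsync_invalid_argument")
  expect_error(select_top_electrodes(ev, 9), class = "beatsync_invalid_argument")

  # electrodes carrying the simulated source are the ones selected
  set.seed(7)
  topo <- numeric(8); topo[c(3, 7)] <- 1
  trials <- make_kernel_trials(n_trials = 5, duration_s = 8, snr_db = 10,
                               n_channels = 8, seed = 8, topography = topo)
  cv <- crossval_trf(trials, fs = 128)
  expect_setequal(select_top_electrodes(cv$evaluation, 2), c(3L, 7L))
})

test_that("multivariate models dominate univariate non-generating features", {
  wins <- vapply(1:5, function(seed) {
    f <- make_audio_features(2, 10, seed = 900 + seed)
    n <- f$n
    fm <- sapply(f$features, function(x) x$values[1:n])
    set.seed(seed)
    src <- beatsync:::conv_causal(fm[, "envelope"], as.numeric(default_kernel(128))) +
      beatsync:::conv_causal(fm[, "beats"], as.numeric(default_kernel(128)))
    resp <- src + sd(src) * rnorm(n)
    mk <- function(feats) lapply(1:4, function(i) {
      i0 <- ((i - 1) * (n %/% 4)) + 1; i1 <- i * (n %/% 4)
      list(features = if (is.matrix(feats)) feats[i0:i1, , drop = FALSE]
           else feats[i0:i1],
           response = matrix(resp[i0:i1], ncol = 1))
    })
    multi <- crossval_trf(mk(fm), fs = 128)$evaluation$mean_r
    flux_only <- crossval_trf(mk(fm[, "flux"]), fs = 128)$evaluation$mean_r
    multi >= flux_only
  }, logical(1))
  expect_gte(median(wins), 1)
})

test_that("residualizing removes nuisance-driven predictability", {
  # EEG generated from (aperiodic) nuisance features only: the residual
  # target model should have no predictive power left. Aperiodic drivers
  # matter here: strictly periodic features all predict one another
  # through the lag filter, so the null band is only meaningful when the
  # target shares no periodicity with the nuisances.
  rs <- vapply(1:6, function(seed) {
    set.seed(seed)
    n <- 4096
    fm <- list(envelope = smooth_noise_feature(n),
               derivative = smooth_noise_feature(n),
               beats = smooth_noise_feature(n),
               flux = smooth_noise_feature(n))
    src <- beatsync:::conv_causal(fm$envelope, as.numeric(default_kernel(128)))
    resp <- src + 0.5 * sd(src) * rnorm(n)
    q <- n %/% 4
    trials <- lapply(1:4, function(i) {
      idx <- ((i - 1) * q + 1):(i * q)
      list(features = lapply(fm, `[`, idx),
           response = matrix(resp[idx], ncol = 1))
    })
    residualized_trf(trials, "flux", c("envelope", "derivative", "beats"),
                     fs = 128)$evaluation$mean_r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.1)

  f <- make_audio_features(2, 8, seed = 1)
  trials_missing <- list(list(features = list(envelope = rnorm(500)),
                              response = matrix(rnorm(500), ncol = 1)))
  expect_error(residualized_trf(trials_missing),
               class = "beatsync_invalid_argument")
})

test_that("residual flux TRF matches the direct one for orthogonal drivers", {
  set.seed(9)
  n <- 5120
  # flux orthogonal to the nuisances by construction
  nuis <- replicate(3, smooth_noise_feature(n))
  flux <- smooth_noise_feature(n)
  flux <- as.numeric(zscore(residuals(lm(flux ~ nuis))))
  src <- beatsync:::conv_causal(flux, as.numeric(default_kernel(128)))
  resp <- src + 0.3 * sd(src) * rnorm(n)
  q <- n %/% 4
  trials <- lapply(1:4, function(i) {
    idx <- ((i - 1) * q + 1):(i * q)
    list(features = list(envelope = nuis[idx, 1], derivative = nuis[idx, 2],
                         beats = nuis[idx, 3], flux = flux[idx]),
         response = matrix(resp[idx], ncol = 1))
  })
  res <- residualized_trf(trials, "flux", c("envelope", "derivative", "beats"),
                          fs = 128)
  direct <- crossval_trf(lapply(trials, function(tr)
    list(features = tr$features$flux, response = tr$response)), fs = 128)
  expect_gte(cor(res$model$weights[1L, , 1L],
                 direct$model$weights[1L, , 1L]), 0.95)

  # zero EEG gives zero weights at positive lambda
  zt <- lapply(trials, function(tr)
    list(features = tr$features$flux, response = matrix(0, q, 1)))
  X <- build_design(zt[[1L]]$features, 128)
  z_fit <- ridge_fit(X, zt[[1L]]$response, 1)
  expect_true(all(abs(z_fit$weights) < 1e-12))
})

test_that("weight normalization standardizes each lag profile", {
  set.seed(10)
  w <- array(rnorm(2 * 52 * 3), dim = c(2, 52, 3))
  nw <- normalize_weights(w)
  for (f in 1:2) for (e in 1:3) {
    expect_lt(abs(mean(nw[f, , e])), 1e-12)
    expect_lt(abs(sd(nw[f, , e]) - 1), 1e-12)
  }
  # affine invariance
  nw2 <- normalize_weights(3 * w + 7)
  expect_equal(nw2[1, , 1], nw[1, , 1], tolerance = 1e-10)

  wc <- w; wc[1, , 1] <- 5
  nc <- normalize_weights(wc)
  expect_true(attr(nc, "degenerate")[1, 1])
  expect_true(all(nc[1, , 1] == 0))
  expect_error(normalize_weights(array(1, dim = c(1, 1, 1))),
               class = "beatsync_invalid_argument")
})

test_that("the TRF surrogate z separates signal from rotated nulls", {
  trials <- make_kernel_trials(n_trials = 5, duration_s = 10, snr_db = 10,
                               n_channels = 3, seed = 11)
  cv <- crossval_trf(trials, fs = 128)
  z <- trf_surrogate_z(trials, fs = 128, lambda_ = cv$model$lambda_,
                       n_iter = 20, seed = 12)
  expect_gte(z$z, 5)
  z2 <- trf_surrogate_z(trials, fs = 128, lambda_ = cv$model$lambda_,
                        n_iter = 20, seed = 12)
  expect_identical(z$z, z2$z)
})
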