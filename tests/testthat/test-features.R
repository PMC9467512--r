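test_that("hilbert envelope recovers known amplitude modulation", {
  fs <- 4000
  t <- seq(0, 3, by = 1 / fs)
  # constant-amplitude tone: interior envelope is flat at 1
  tone <- sin(2 * pi * 500 * t)
  env_raw <- Mod(beatsync:::analytic_signal(tone))
  interior <- env_raw[(fs %/% 2):(length(tone) - fs %/% 2)]
  expect_lt(max(abs(interior - 1)), 0.01)

  # AM tone: envelope tracks the modulator
  m <- 1 + 0.8 * sin(2 * pi * 4 * t)
  am <- m * sin(2 * pi * 500 * t)
  env <- hilbert_envelope(am, fs, fs_out = 128)
  m_ds <- beatsync:::resample_linear(m, fs, 128)
  n <- min(length(env$values), length(m_ds))
  core <- 30:(n - 30)
  expect_gt(cor(env$values[core], m_ds[core]), 0.99)

  # |.| symmetry
  env_flip <- hilbert_envelope(-am, fs, fs_out = 128)
  expect_equal(env$values, env_flip$values, tolerance = 1e-10)

  expect_error(hilbert_envelope(numeric(0), fs),
               class = "beatsync_invalid_argument")
})

test_that("gammatone envelope isolates the modulation rate", {
  fs <- 16000
  t <- seq(0, 4, by = 1 / fs)
  am <- (1 + 0.9 * sin(2 * pi * 10 * t)) * sin(2 * pi * 1000 * t)
  env <- gammatone_envelope(am, fs, n_channels = 32)
  sp <- feature_spectrum(env, target_resolution_hz = 0.05)
  keep <- sp$frequency > 2 & sp$frequency < 40
  expect_lt(abs(sp$frequency[keep][which.max(sp$amplitude[keep])] - 10), 0.3)

  # scale invariance after z-scoring
  env3 <- gammatone_envelope(3 * am, fs, n_channels = 32)
  expect_equal(env$values, env3$values, tolerance = 1e-9)

  # silence is degenerate
  sil <- gammatone_envelope(numeric(16000), fs, n_channels = 8)
  expect_true(sil$degenerate)
  expect_true(all(sil$values == 0))

  expect_error(gammatone_envelope(am, fs, f_hi = 9000),
               class = "beatsync_invalid_argument")
})

test_that("half-wave rectified derivative matches hand computation", {
  v <- c(0, 1, 0, 1)
  d <- first_derivative(feature_ts(v, fs = 4))
  manual <- as.numeric(zscore(c(0, 1, 0, 1)))
  expect_equal(d$values, manual, tolerance = 1e-12)

  dec <- first_derivative(feature_ts(seq(5, 1), fs = 4))
  expect_true(dec$degenerate)
  expect_true(all(dec$values == 0))

  # a positive ramp has constant slope everywhere past the leading pad
  ramp <- first_derivative(feature_ts(seq(0, 1, by = 0.1), fs = 4))
  expect_equal(diff(ramp$values[-1]), rep(0, 9), tolerance = 1e-12)

  expect_error(first_derivative(feature_ts(1, fs = 4)),
               class = "beatsync_invalid_argument")
})

test_that("spectral flux detects spectral change, not amplitude", {
  fs <- 8000
  # tone entering after 1 s of silence: flux spikes at the onset, then
  # settles near zero in the steady state
  t <- seq(0, 3, by = 1 / fs)
  tone <- c(numeric(fs), sin(2 * pi * 440 * t))
  fx <- spectral_flux(tone, fs, frame_len = round(fs / 128))
  onset <- fx$values[110:150]               # around t = 1 s
  steady <- fx$values[300:(length(fx$values) - 50)]
  expect_gt(max(onset), max(steady) + 5 * sd(steady))
  expect_lt(sd(steady), 0.05 * max(fx$values))

  # equal-RMS pitch alternation: flux peaks, envelope stays flat
  spec <- stimulus_spec(2, 8, fs_audio = fs, pitch_cycle = c(220, 330),
                        amplitude_jitter = 0, seed = 1)
  a <- gen_audio(spec, pitch_only = TRUE)
  fxa <- spectral_flux(a, fs, frame_len = round(fs / 128))
  env <- hilbert_envelope(a, fs)
  n <- min(length(fxa$values), length(env$values))
  core <- 64:(n - 64)
  raw_flux <- fxa$values[core] - min(fxa$values[core])
  expect_gt(max(raw_flux), 5 * median(raw_flux))
  expect_lt(abs(cor(fxa$values[core], env$values[core])), 0.3)

  expect_error(spectral_flux(tone, fs, frame_len = 0),
               class = "beatsync_invalid_argument")
})

test_that("flux is invariant to time shift away from the seam", {
  fs <- 8000
  spec <- stimulus_spec(2, 4, fs_audio = fs, seed = 5)
  a <- as.numeric(gen_audio(spec))
  fx2 <- spectral_flux(c(a, a), fs, frame_len = round(fs / 128))
  period <- round(4 * 128)                  # the first copy spans 4 s
  first <- fx2$values[10:(period - 20)]
  second <- fx2$values[(period + 10):(2 * period - 20)]
  expect_gt(cor(first, second), 0.9)
})

test_that("beat vectors place and standardize onsets correctly", {
  b <- beats_to_vector(c(0.5, 1.0), 128, 2, standardize = FALSE)
  expect_equal(which(b$values == 1), c(64, 128) + 1L)

  empty <- beats_to_vector(numeric(0), 128, 2)
  expect_true(empty$degenerate)

  expect_warning(collided <- beats_to_vector(c(0.500, 0.501), 128, 2,
                                             standardize = FALSE),
                 "collide")
  expect_equal(sum(collided$values), 1)

  expect_error(beats_to_vector(c(-0.1), 128, 2),
               class = "beatsync_invalid_argument")
  expect_error(beats_to_vector(c(2.5), 128, 2),
               class = "beatsync_invalid_argument")
})

test_that("feature spectra locate sinusoids and beat harmonics", {
  fs <- 128
  t <- (0:(fs * 20 - 1)) / fs
  s <- sin(2 * pi * 2 * t)
  sp <- feature_spectrum(s, fs = fs, target_resolution_hz = 0.01)
  expect_lt(abs(sp$frequency[which.max(sp$amplitude)] - 2), 0.02)

  bt <- gen_beat_train(1.25, 60, fs)
  spb <- feature_spectrum(bt, fs = fs, target_resolution_hz = 0.01)
  for (f0 in c(1.25, 2.5, 3.75)) {
    band <- abs(spb$frequency - f0) < 0.05
    off <- spb$frequency > 0.3 & spb$frequency < 5 &
      abs(spb$frequency - 1.25 * round(spb$frequency / 1.25)) > 0.2
    expect_gt(max(spb$amplitude[band]), 5 * median(spb$amplitude[off]))
  }

  expect_error(feature_spectrum(s, fs = fs, target_resolution_hz = 0),
               class = "beatsync_invalid_argument")
})

test_that("white-noise spectra show no spurious peaks across seeds", {
  fs <- 128
  for (seed in 1:20) {
    set.seed(seed)
    sp <- feature_spectrum(rnorm(fs * 8), fs = fs, target_resolution_hz = 0.05)
    keep <- sp$frequency > 0.2
    expect_lt(max(sp$amplitude[keep]), 5 * median(sp$amplitude[keep]))
  }
})

test_that("standardization is idempotent and trimming aligns lengths", {
  set.seed(1)
  x <- rnorm(500) * 3 + 2
  z1 <- as.numeric(zscore(x))
  z2 <- as.numeric(zscore(z1))
  expect_equal(z1, z2, tolerance = 1e-12)

  f <- make_audio_features(2, 6, seed = 3)
  lens <- vapply(f$features, function(x) length(x$values), integer(1))
  expect_true(all(lens == lens[1L]))
  for (ft in f$features[c("envelope", "derivative", "flux")]) {
    expect_lt(abs(mean(ft$values)), 1e-9)
    expect_lt(abs(sd(ft$values) - 1), 1e-9)
  }
})
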