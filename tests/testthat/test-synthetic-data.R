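test_that("beat trains place ones exactly on the beat grid", {
  bt <- gen_beat_train(2, 10, 128)
  expect_equal(sum(bt), 20)
  expect_equal(which(bt == 1)[1:3], c(0, 64, 128) + 1L)

  bt1 <- gen_beat_train(1, 4, 128)
  expect_equal(which(bt1 == 1), c(0, 128, 256, 384) + 1L)

  # count equals floor(duration * tempo) when the period is integer samples
  for (tempo in c(1, 2, 4)) {
    bt <- gen_beat_train(tempo, 7, 128)
    expect_equal(sum(bt), floor(7 * tempo))
  }
  expect_error(gen_beat_train(-1, 10, 128), class = "beatsync_invalid_argument")
  expect_error(gen_beat_train(2, 0, 128), class = "beatsync_invalid_argument")
  expect_error(gen_beat_train(65, 10, 128), class = "beatsync_invalid_argument")
})

test_that("beat-train spectrum concentrates at tempo multiples", {
  bt <- gen_beat_train(1.25, 40, 128)
  sp <- feature_spectrum(bt, fs = 128, target_resolution_hz = 0.025)
  nz <- sp$frequency > 0.5 & sp$frequency < 10
  peaks <- sp$frequency[nz][sp$amplitude[nz] > 0.5 * max(sp$amplitude[nz])]
  # every strong bin sits within a bin width of a multiple of 1.25 Hz
  expect_true(all(abs(peaks / 1.25 - round(peaks / 1.25)) * 1.25 < 0.05))
})

test_that("audio generation is a pure function of its spec", {
  spec <- stimulus_spec(2, 3, fs_audio = 8000, seed = 42)
  a1 <- gen_audio(spec)
  a2 <- gen_audio(spec)
  expect_identical(as.numeric(a1), as.numeric(a2))
  expect_lte(max(abs(a1)), 1)
  expect_error(gen_audio(stimulus_spec(2, 3, fs_audio = 8000,
                                       pitch_cycle = 5000)),
               class = "beatsync_invalid_argument")
})

test_that("a single-beat stimulus is one tone starting at t = 0", {
  spec <- stimulus_spec(0.2, 4, fs_audio = 4000, pitch_cycle = 220,
                        amplitude_jitter = 0, seed = 1)
  a <- gen_audio(spec)
  expect_equal(length(attr(a, "beat_onsets_s")), 1L)
  expect_equal(attr(a, "beat_onsets_s"), 0)
  expect_gt(max(abs(a[1:100])), 0)   # energy right at onset
})

test_that("stimulus envelope spectrum peaks at the beat rate or harmonics", {
  spec <- stimulus_spec(2, 30, fs_audio = 8000, seed = 7)
  a <- gen_audio(spec)
  env <- hilbert_envelope(a, 8000)
  sp <- feature_spectrum(env, target_resolution_hz = 0.01)
  keep <- sp$frequency > 0.5          # exclude DC leakage
  f_max <- sp$frequency[keep][which.max(sp$amplitude[keep])]
  expect_lt(min(abs(f_max - 2 * (1:4))), 0.1)
})

test_that("simulated EEG honours the forward model in the noise-free limit", {
  n <- 256
  feat <- smooth_noise_feature(n)
  sim <- eeg_sim_spec(n_participants = 2, n_trials = 1, trial_duration_s = 2,
                      n_channels = 4, snr_db = Inf, seed = 1)
  ds <- gen_eeg_dataset(feat, sim)
  src <- ds$source[[1L]]
  for (p in 1:2) {
    got <- ds$participants[[p]][[1L]]
    expect_equal(got, outer(src, sim$topography), tolerance = 1e-12)
  }
})

test_that("zero topography yields pure noise with unit-scale variance", {
  n <- 512
  feat <- smooth_noise_feature(n)
  sim <- eeg_sim_spec(n_participants = 1, n_trials = 1, trial_duration_s = 4,
                      n_channels = 8, topography = rep(0, 8), snr_db = 10,
                      seed = 2)
  ds <- gen_eeg_dataset(feat, sim)
  v <- mean(apply(ds$participants[[1L]][[1L]], 2, var))
  expect_gt(v, 0.5); expect_lt(v, 2)
})

test_that("empirical SNR matches the requested 10 dB within 10%", {
  fs <- 128
  n <- fs * 64                       # > 60 s of data
  set.seed(3)
  feat <- smooth_noise_feature(n)
  sim_sig <- eeg_sim_spec(n_participants = 1, n_trials = 1,
                          trial_duration_s = n / fs, n_channels = 6,
                          snr_db = Inf, seed = 5)
  sim_10 <- eeg_sim_spec(n_participants = 1, n_trials = 1,
                         trial_duration_s = n / fs, n_channels = 6,
                         snr_db = 10, seed = 5)
  sig <- gen_eeg_dataset(feat, sim_sig)$participants[[1L]][[1L]]
  tot <- gen_eeg_dataset(feat, sim_10)$participants[[1L]][[1L]]
  noise <- tot - sig
  ratio <- mean(apply(sig, 2, var)) / mean(apply(noise, 2, var))
  expect_gt(ratio, 9); expect_lt(ratio, 11)
})

test_that("identical simulation specs regenerate identical datasets", {
  feat <- smooth_noise_feature(256)
  sim <- eeg_sim_spec(n_participants = 2, n_trials = 2, trial_duration_s = 2,
                      n_channels = 4, snr_db = 5, seed = 11)
  d1 <- gen_eeg_dataset(feat, sim)
  d2 <- gen_eeg_dataset(feat, sim)
  expect_identical(d1$participants, d2$participants)
})

test_that("kernel lag axis is validated against the 0-400 ms window", {
  k <- rnorm(60); attr(k, "lag_ms") <- seq(0, 460, length.out = 60)
  expect_error(eeg_sim_spec(kernel = k), class = "beatsync_invalid_argument")
  expect_error(eeg_sim_spec(n_channels = 8, topography = rep(1, 5)),
               class = "beatsync_invalid_argument")
})

test_that("WAV and array containers round-trip", {
  x <- sin(2 * pi * 5 * seq(0, 1, length.out = 800))
  tmp <- tempfile(fileext = ".wav")
  write_wav(x, tmp, fs = 800, format = "float32")
  got <- read_wav(tmp)
  expect_equal(got$fs, 800)
  expect_equal(got$x, x, tolerance = 1e-6)
  write_wav(x, tmp, fs = 800, format = "pcm16")
  expect_equal(read_wav(tmp)$x, x, tolerance = 1e-4)

  arr <- array(rnorm(24), dim = c(2, 3, 4))
  ap <- tempfile()
  write_array(arr, ap, meta = list(fs = 128, label = "demo"))
  back <- read_array(ap)
  expect_equal(dim(back), dim(arr))
  expect_equal(as.numeric(back), as.numeric(arr))
  expect_equal(attr(back, "meta")$fs, 128)

  bp <- tempfile()
  write_beats(c(0.5, 1.25, 2), bp)
  expect_equal(read_beats(bp), c(0.5, 1.25, 2))
})
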