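# Signal conditioning: zero-phase filtering, downsampling, referencing,
# envelope, and the 5-s epoch artifact-scoring rules.

make_rec <- function(x, fs, nch = 1, modality = "LFP") {
  if (is.matrix(x)) ts_recording(x, fs, modality = modality)
  else ts_recording(matrix(rep(x, nch), nrow = nch, byrow = TRUE), fs,
                    modality = modality)
}

test_that("band-pass keeps passband sinusoids and removes drift", {
  fs <- 1000
  t <- seq(0, 10, by = 1 / fs)[-1]
  rec <- make_rec(sin(2 * pi * 10 * t), fs)
  out <- bandpass_filter(rec, 2, 100)$data[1, ]
  core <- 2000:8000                      # avoid the edge transients
  amp <- max(abs(out[core]))
  expect_gt(amp, 0.95); expect_lt(amp, 1.05)
  # phase preservation: cross-correlation peak at zero lag
  cc <- ccf(out[core], sin(2 * pi * 10 * t)[core], lag.max = 5, plot = FALSE)
  expect_equal(as.numeric(cc$lag[which.max(cc$acf)]), 0)
  drift <- bandpass_filter(make_rec(sin(2 * pi * 0.2 * t), fs), 2, 100)$data[1, ]
  expect_lt(max(abs(drift[core])), 0.05)
})

test_that("MUA band isolates 600 Hz tones that the LFP band suppresses", {
  fs <- 20000
  t <- seq(0, 2, by = 1 / fs)[-1]
  tone <- sin(2 * pi * 600 * t)
  core <- 10000:30000
  kept <- bandpass_filter(make_rec(tone, fs), 500, 5000)$data[1, core]
  cut <- bandpass_filter(make_rec(tone, fs), 2, 100)$data[1, core]
  expect_gt(max(abs(kept)), 0.7)      # 600 Hz sits near the 500 Hz edge
  expect_lt(max(abs(cut)), 0.05)
})

test_that("band edges outside Nyquist are rejected", {
  rec <- make_rec(rnorm(1000), 250)
  expect_error(bandpass_filter(rec, 2, 150), "Nyquist")
  expect_error(bandpass_filter(rec, 0, 100), "Nyquist")
})

test_that("filtering commutes with time reversal (zero-phase property)", {
  set.seed(1)
  rec <- make_rec(rnorm(8000), 1000)
  a <- bandpass_filter(rec, 2, 100)$data[1, ]
  rev_rec <- make_rec(rev(rec$data[1, ]), 1000)
  b <- rev(bandpass_filter(rev_rec, 2, 100)$data[1, ])
  core <- 2000:6000    # the 2 Hz edge rings for ~2 s; compare the interior
  expect_lt(max(abs(a[core] - b[core])), 1e-6)
})

test_that("downsampling preserves in-band content and rejects bad targets", {
  fs <- 32000
  t <- seq(0, 4, by = 1 / fs)[-1]
  rec <- make_rec(sin(2 * pi * 40 * t), fs)
  ds <- downsample(rec, 1000)
  expect_identical(ds$sampling_rate_hz, 1000)
  expect_identical(ncol(ds$data), ncol(rec$data) %/% 32L)
  p_lo <- band_power(signal_psd(ds, 1), c(35, 45))
  expect_gt(p_lo, 0.95 * 0.5); expect_lt(p_lo, 1.05 * 0.5)
  expect_identical(downsample(rec, fs), rec)          # identity
  expect_error(downsample(rec, 64000), "above")
  expect_error(downsample(rec, 7000), "divide")
  # 1024 -> 256 Hz EEG keeps the envelope
  set.seed(2)
  x <- one_over_f_noise(1024 * 30, 1024, -1)
  r2 <- downsample(make_rec(x, 1024, modality = "EEG"), 256)
  env_hi <- amplitude_envelope(make_rec(x, 1024))$data[1, seq(1, 1024 * 30, by = 4)]
  env_lo <- amplitude_envelope(r2)$data[1, ]
  expect_gt(cor(env_hi, env_lo), 0.99)
})

test_that("common average reference zeroes the cross-channel mean", {
  set.seed(3)
  m <- matrix(rnorm(5 * 200), 5)
  rec <- ts_recording(m, 100, modality = "EEG")
  out <- common_average_reference(rec)
  expect_lt(max(abs(colMeans(out$data))), 1e-12)
  # two antisymmetric channels are already referenced
  rec2 <- ts_recording(rbind(m[1, ], -m[1, ]), 100, modality = "EEG")
  expect_equal(common_average_reference(rec2)$data, rec2$data)
  # a common offset is removed entirely
  rec3 <- ts_recording(m + 7.5, 100, modality = "EEG")
  expect_equal(common_average_reference(rec3)$data,
               common_average_reference(ts_recording(m, 100, modality = "EEG"))$data)
  expect_error(common_average_reference(rec, rec$channel_labels), ">= 2")
})

test_that("amplitude envelope equals the brute-force windowed mean", {
  set.seed(4)
  fs <- 100
  x <- rnorm(3 * fs)
  env <- amplitude_envelope(make_rec(x, fs), 1.0)$data[1, ]
  w <- fs
  brute <- vapply(seq_along(x), function(i) {
    lo <- max(1, i - (w - 1) %/% 2); hi <- min(length(x), i + w %/% 2)
    mean(abs(x[lo:hi]))
  }, numeric(1))
  expect_equal(env, brute)
  # invariants: nonnegative, sign-flip invariant, |constant| identity
  expect_true(all(env >= 0))
  expect_equal(amplitude_envelope(make_rec(-x, fs))$data[1, ], env)
  expect_equal(amplitude_envelope(make_rec(rep(-2.5, 300), fs))$data[1, ],
               rep(2.5, 300))
  # fast-alternating square wave averages to its amplitude
  sq <- rep(c(1, -1), 150) * 3
  env_sq <- amplitude_envelope(make_rec(sq, fs), 1.0)$data[1, 100:200]
  expect_true(all(abs(env_sq - 3) < 0.05))
  expect_error(amplitude_envelope(make_rec(x, fs), 10), "longer")
})

# toy EEG builder for the scoring rules: 3 channels, 256 Hz, value 5 uV
scoring_rec <- function(n_min = 3, fs = 256) {
  n <- n_min * 60 * fs
  ts_recording(matrix(5, 3, n) * matrix(c(1, -1, 0.5), 3, n), fs,
               modality = "EEG")
}

test_that("epoch scoring applies the amplitude, median and saturation rules", {
  fs <- 256
  rec <- scoring_rec(2)
  clean <- score_epochs(rec, list(rail_uv = 400))
  expect_true(all(clean$epoch_valid))
  expect_true(all(clean$minute_valid))
  # one 160 uV sample in epoch 3 rejects exactly that epoch
  rec2 <- rec
  rec2$data[1, 2 * 5 * fs + 10] <- 160
  m2 <- score_epochs(rec2, list(rail_uv = 400))
  expect_false(m2$epoch_valid[3])
  expect_identical(sum(!m2$epoch_valid), 1L)
  expect_identical(m2$reasons[3], "amplitude")
  # cross-channel median envelope of 35 uV rejects via the 30 uV rule
  rec3 <- rec
  idx <- (5 * 5 * fs + 1):(6 * 5 * fs)
  rec3$data[, idx] <- 35 * matrix(rep(c(1, -1), length.out = length(idx)),
                                  3, length(idx), byrow = TRUE)
  m3 <- score_epochs(rec3, list(rail_uv = 400))
  expect_false(m3$epoch_valid[6])
  # saturation: >= 3 consecutive samples at the rail
  rec4 <- rec
  rec4$data[2, 100:110] <- 400
  m4 <- score_epochs(rec4, list(rail_uv = 400))
  expect_false(m4$epoch_valid[1])
  expect_identical(m4$reasons[1], "saturation")
  # 2 samples at a sub-150-uV rail are not saturation; 3 are
  rec5 <- rec
  rec5$data[2, 100:101] <- 100
  expect_true(score_epochs(rec5, list(rail_uv = 100))$epoch_valid[1])
  rec5$data[2, 100:102] <- 100
  m5 <- score_epochs(rec5, list(rail_uv = 100))
  expect_false(m5$epoch_valid[1])
  expect_identical(m5$reasons[1], "saturation")
})

test_that("minutes are removed only above 10 s of contamination", {
  fs <- 256
  rec <- scoring_rec(3)
  # two bad epochs in minute 2 (10 s): retained
  rec$data[1, c(13 * 5 * fs + 5, 14 * 5 * fs + 5)] <- 200
  m <- score_epochs(rec, list(rail_uv = 400))
  expect_identical(sum(!m$epoch_valid), 2L)
  expect_true(m$minute_valid[2])
  # three bad epochs (15 s): removed
  rec$data[1, 15 * 5 * fs + 5] <- 200
  m2 <- score_epochs(rec, list(rail_uv = 400))
  expect_false(m2$minute_valid[2])
  expect_true(m2$minute_valid[1] && m2$minute_valid[3])
})

test_that("epoch scoring is idempotent and channel-order independent", {
  set.seed(6)
  fs <- 256
  dat <- matrix(rnorm(4 * 90 * fs, sd = 8), 4)
  dat[2, 5000:5002] <- 400
  dat[3, 20000] <- 180
  rec <- ts_recording(dat, fs, modality = "EEG")
  m1 <- score_epochs(rec, list(rail_uv = 400))
  m2 <- score_epochs(rec, list(rail_uv = 400))
  expect_identical(m1$epoch_valid, m2$epoch_valid)
  perm <- c(3, 1, 4, 2)
  rec_p <- ts_recording(dat[perm, ], fs, modality = "EEG")
  m3 <- score_epochs(rec_p, list(rail_uv = 400))
  expect_identical(m1$epoch_valid, m3$epoch_valid)
  expect_identical(m1$minute_valid, m3$minute_valid)
})

test_that("low- and high-variance channels are flagged", {
  set.seed(7)
  dat <- rbind(rnorm(5000), rnorm(5000), rnorm(5000) * 25, rnorm(5000) * 0.05)
  rec <- ts_recording(dat, 250, modality = "EEG")
  flagged <- flag_bad_channels(rec)
  expect_setequal(flagged, c("ch3", "ch4"))
})
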