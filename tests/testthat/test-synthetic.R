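# Synthetic-session generators: reproducibility, dose law, within-burst
# spectral invariance, spike phase locking, artifact bookkeeping.

test_that("identical seed and parameters give bit-identical sessions", {
  p <- neonatal_lfp_params(duration_s = 60, seed = 7)
  a <- gen_neonatal_session(p)
  b <- gen_neonatal_session(p)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$truth$events, b$truth$events)
  expect_identical(a$truth$spike_times, b$truth$spike_times)
  pi1 <- infant_eeg_params(age_group = "4-6", seed = 9, duration_min = 24,
                           artifact_spec = list(n_saturation = 1,
                                                n_transient = 1,
                                                n_high_median = 1,
                                                rail_uv = 400))
  x <- gen_infant_session(pi1)
  y <- gen_infant_session(pi1)
  expect_identical(x$recording$data, y$recording$data)
  expect_identical(x$truth$artifact_mask, y$truth$artifact_mask)
})

test_that("parameter validation rejects degenerate configurations", {
  expect_error(neonatal_lfp_params(duration_s = -5), "positive")
  expect_error(neonatal_lfp_params(sampling_rate_hz = 0), "positive")
  expect_error(neonatal_lfp_params(burst_band_mix = c(delta = -1,
    theta_alpha = 1, beta = 1, gamma = 1)), "nonnegative")
  expect_error(neonatal_lfp_params(dose_response = function(c) 0.5 + 0 * c),
               "dose_response\\(0\\)")
  expect_error(neonatal_lfp_params(dose_response = function(c) pmax(0, 1 + 0.1 * c)),
               "nonincreasing")
  expect_error(infant_eeg_params(n_channels = 1), "common-average")
  expect_error(infant_eeg_params(age_group = "0-2", amplitude_dose_slope = 0.3),
               "nonpositive")
  expect_error(infant_eeg_params(age_group = "4-6", amplitude_dose_slope = -0.3),
               "nonnegative")
})

test_that("burst count matches the initiation rate in the sparse regime", {
  # low occupancy so overlap rejection is negligible; identity dose law
  counts <- vapply(1:6, function(s) {
    p <- neonatal_lfp_params(duration_s = 900, burst_rate_hz = 0.02,
                             dose_response = function(conc) rep(1, length(conc)),
                             seed = s)
    nrow(gen_neonatal_session(p, include_spikes = FALSE)$truth$events)
  }, numeric(1))
  expected <- 0.02 * 900
  # pooled count is Poisson(6 * expected) up to a small rejection loss
  expect_lt(abs(sum(counts) - 6 * expected), 3.5 * sqrt(6 * expected))
})

test_that("dose ladder suppresses true occurrence monotonically", {
  p <- neonatal_lfp_params(duration_s = 3600, seed = 3)
  ses <- gen_neonatal_session(p, isoflurane_ladder(), include_spikes = FALSE)
  ev <- ses$truth$events
  occ <- vapply(0:3, function(l) {
    sum(pmax(0, pmin(ev$stop_s, l * 900 + 900) - pmax(ev$start_s, l * 900))) / 900
  }, numeric(1))
  expect_true(all(diff(occ) < 0))
  expect_identical(ses$truth$concentration_per_minute,
                   rep(c(0, 1, 2, 3), each = 15))
})

test_that("within-burst spectra keep their band mix across dose levels", {
  p <- neonatal_lfp_params(duration_s = 3600, seed = 12)
  ses <- gen_neonatal_session(p, isoflurane_ladder(), include_spikes = FALSE)
  ev <- ses$truth$events
  ratio_at <- function(l) {
    sub <- ev[ev$start_s >= l * 900 & ev$stop_s <= l * 900 + 900, ]
    psd <- signal_psd(ses$recording, "PFC", events = sub)
    band_power(psd, "delta") / band_power(psd, "gamma")
  }
  r0 <- ratio_at(0); r3 <- ratio_at(3)
  expect_lt(abs(log(r0 / r3)), log(1.6))   # equal within estimation tolerance
})

test_that("true events are sorted, non-overlapping and the mask has 5-s grid length", {
  p <- neonatal_lfp_params(duration_s = 307, seed = 2)
  tr <- gen_neonatal_session(p, include_spikes = FALSE)$truth
  ev <- tr$events
  if (nrow(ev) > 1) {
    expect_true(all(diff(ev$start_s) > 0))
    expect_true(all(ev$start_s[-1] - ev$stop_s[-nrow(ev)] > 0))
  }
  expect_true(all(ev$duration_s > 1))
  expect_length(tr$artifact_mask, ceiling(307 / 5))
})

test_that("spike phases follow the configured von Mises concentration", {
  for (kap in c(1, 4)) {
    p <- neonatal_lfp_params(duration_s = 600, spike_lock_kappa = kap,
                             spike_rate_hz = 15, seed = 40 + kap)
    tr <- gen_neonatal_session(p, regions = "PFC")$truth
    ph <- tr$spike_phases$PFC
    expect_gt(length(ph), 300)
    r_emp <- Mod(mean(exp(1i * ph)))
    r_exp <- besselI(kap, 1) / besselI(kap, 0)
    expect_lt(abs(r_emp - r_exp), 3 / sqrt(length(ph)) + 0.03)
  }
})

test_that("juvenile mode shifts band power with the configured slopes", {
  slopes <- c(delta = 0.3, theta_alpha = 0, beta = -0.2, gamma = -0.3)
  p <- neonatal_lfp_params(duration_s = 240, seed = 5,
                           band_dose_slopes = slopes)
  ses <- gen_juvenile_session(p, data.frame(start_s = c(0, 120),
                                            level = c(0, 1)))
  pre <- signal_psd(ses$recording, 1, from_s = 0, to_s = 120)
  post <- signal_psd(ses$recording, 1, from_s = 120, to_s = 240)
  mi <- vapply(c("delta", "beta", "gamma"), function(b)
    modulation_index(band_power(pre, b), band_power(post, b)), numeric(1))
  expect_gt(mi[["delta"]], 0)
  expect_lt(mi[["beta"]], 0)
  expect_lt(mi[["gamma"]], 0)
  # zero slopes: pre/post equal within estimation error
  p0 <- neonatal_lfp_params(duration_s = 240, seed = 6)
  s0 <- gen_juvenile_session(p0, data.frame(start_s = c(0, 120),
                                            level = c(0, 1)))
  pre0 <- signal_psd(s0$recording, 1, from_s = 0, to_s = 120)
  post0 <- signal_psd(s0$recording, 1, from_s = 120, to_s = 240)
  mi0 <- modulation_index(band_power(pre0, c(2, 100)),
                          band_power(post0, c(2, 100)))
  expect_lt(abs(mi0), 0.06)
})

test_that("doubling the delta slope doubles the log-power offset", {
  sched <- data.frame(start_s = c(0, 120), level = c(0, 1))
  offset_for <- function(slope, seed) {
    p <- neonatal_lfp_params(duration_s = 240, seed = seed,
      band_dose_slopes = c(delta = slope, theta_alpha = 0, beta = 0, gamma = 0))
    ses <- gen_juvenile_session(p, sched)
    pre <- signal_psd(ses$recording, 1, from_s = 0, to_s = 120)
    post <- signal_psd(ses$recording, 1, from_s = 120, to_s = 240)
    log10(band_power(post, "delta") / band_power(pre, "delta"))
  }
  o1 <- offset_for(0.2, 31); o2 <- offset_for(0.4, 31)
  expect_lt(abs(o1 - 0.2), 0.06)
  expect_lt(abs(o2 - 0.4), 0.06)
  expect_lt(abs(o2 - 2 * o1), 0.1)
})

test_that("infant sessions encode the age-dependent amplitude-dose law", {
  for (cfg in list(list(age = "0-2", sign = -1), list(age = "4-6", sign = 1))) {
    p <- infant_eeg_params(age_group = cfg$age, duration_min = 24,
                           artifact_spec = list(n_saturation = 0,
                                                n_transient = 0,
                                                n_high_median = 0,
                                                rail_uv = 400),
                           seed = 17)
    ses <- gen_infant_session(p)
    env <- amplitude_envelope(ses$recording)
    avg <- colMeans(env$data)
    n_min <- floor(duration_s(ses$recording) / 60)
    med <- vapply(seq_len(n_min), function(m)
      median(avg[anesdepth:::sample_range(ses$recording, (m - 1) * 60, m * 60)]),
      numeric(1))
    rho <- spearman_rho(med, minute_labels(ses$recording))
    expect_gt(cfg$sign * rho, 0.5)
  }
})

test_that("slope zero gives only a null-level amplitude correlation", {
  p <- infant_eeg_params(age_group = "2-4", amplitude_dose_slope = 0,
                         band_dose_slopes = rep(0, 10), duration_min = 24,
                         artifact_spec = list(n_saturation = 0, n_transient = 0,
                                              n_high_median = 0, rail_uv = 400),
                         amp_jitter_sd = 0, seed = 23)
  ses <- gen_infant_session(p)
  env <- amplitude_envelope(ses$recording)
  avg <- colMeans(env$data)
  n_min <- floor(duration_s(ses$recording) / 60)
  med <- vapply(seq_len(n_min), function(m)
    median(avg[anesdepth:::sample_range(ses$recording, (m - 1) * 60, m * 60)]),
    numeric(1))
  rho <- spearman_rho(med, minute_labels(ses$recording))
  expect_lt(abs(rho), 2 / sqrt(n_min - 1) + 0.15)
})

test_that("requested artifact epochs are injected and recorded exactly", {
  p <- infant_eeg_params(age_group = "0-2", duration_min = 24, seed = 5,
                         artifact_spec = list(n_saturation = 3, n_transient = 0,
                                              n_high_median = 0, rail_uv = 400))
  tr <- gen_infant_session(p)$truth
  expect_identical(sum(tr$artifact_mask), 3L)
  expect_identical(tr$artifact_types, rep("saturation", 3))
})
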