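# Synthetic-session generators: neonatal mouse LFP (discontinuous), juvenile
# mouse LFP (continuous) and infant scalp EEG, each returning the recording
# plus ground truth for every downstream pipeline stage.

# canonical analysis bands
lfp_bands <- function() {
  list(delta = c(2, 4), theta_alpha = c(4, 12),
       beta = c(12, 30), gamma = c(30, 100))
}

# default isoflurane dose law: occurrence factors 1/0.6/0.3/0.1 at 0/1/2/3%
default_dose_response <- function(concentration) {
  stats::approx(x = c(0, 1, 2, 3), y = c(1, 0.6, 0.3, 0.1),
                xout = pmin(pmax(concentration, 0), 3), rule = 2)$y
}

#' Parameters of the neonatal / juvenile mouse LFP generator
#'
#' Encodes discontinuous neonatal activity: active periods (bursts) of
#' mixed-frequency oscillations riding on a 1/f background, alternating with
#' silent periods. Anesthetic dose suppresses the *occurrence* of bursts via
#' `dose_response` while the within-burst spectral mix and firing are
#' preserved. The same parameter object drives [gen_juvenile_session()],
#' where the burst process is disabled and `band_dose_slopes` instead scale
#' band log-power with concentration (continuous, adult-like mode).
#'
#' @param sampling_rate_hz sampling rate (Hz); 1000 by default, which covers
#'   the 1-100 Hz analysis band with margin at desk-scale runtime.
#' @param duration_s session duration (s).
#' @param burst_rate_hz baseline burst initiation rate (events/s) before
#'   dose thinning.
#' @param burst_duration_s list with `mean` and `sd` (s) of the lognormal
#'   burst duration law; durations are floored at 1.2 s so true events pass
#'   the >1 s detector rule.
#' @param burst_band_mix nonnegative named weights for the relative power of
#'   delta (2-4 Hz), theta_alpha (4-12 Hz), beta (12-30 Hz) and gamma
#'   (30-100 Hz) within bursts.
#' @param aperiodic_exponent exponent of the 1/f background (negative).
#' @param noise_sd_uv background noise scale (uV).
#' @param burst_amp_uv list with `mean` (uV, burst RMS) and `sdlog` of the
#'   lognormal burst-amplitude law. The source study does not quantify burst
#'   amplitude distributions; these are free generator parameters.
#' @param spike_rate_hz within-burst multi-unit firing rate (Hz).
#' @param spike_lock_kappa von Mises concentration of spike phases relative
#'   to the `spike_lock_band` oscillation.
#' @param spike_lock_band band name the spikes are locked to.
#' @param dose_response function mapping concentration to a multiplicative
#'   burst-occurrence factor in \[0, 1\]; must satisfy `dose_response(0) == 1`
#'   and be nonincreasing.
#' @param band_dose_slopes named per-band signed slopes (log10-power per unit
#'   concentration) used only by the continuous juvenile mode.
#' @param seed integer RNG seed.
#'
#' @return an object of class `neonatal_lfp_params`.
#' @export
neonatal_lfp_params <- function(sampling_rate_hz = 1000,
                                duration_s = 300,
                                burst_rate_hz = 0.25,
                                burst_duration_s = list(mean = 3, sd = 1.2),
                                burst_band_mix = c(delta = 0.4, theta_alpha = 0.3,
                                                   beta = 0.2, gamma = 0.1),
                                aperiodic_exponent = -1,
                                noise_sd_uv = 5,
                                burst_amp_uv = list(mean = 40, sdlog = 0.3),
                                spike_rate_hz = 10,
                                spike_lock_kappa = 2,
                                spike_lock_band = "theta_alpha",
                                dose_response = default_dose_response,
                                band_dose_slopes = c(delta = 0, theta_alpha = 0,
                                                     beta = 0, gamma = 0),
                                seed = 1L) {
  if (sampling_rate_hz <= 0) stop("invalid parameter: sampling_rate_hz must be positive")
  if (duration_s <= 0) stop("invalid parameter: duration_s must be positive")
  if (burst_rate_hz < 0) stop("invalid parameter: burst_rate_hz must be >= 0")
  if (burst_duration_s$mean <= 1) stop("invalid parameter: mean burst duration must exceed 1 s")
  if (any(burst_band_mix < 0)) stop("invalid parameter: burst_band_mix weights must be nonnegative")
  if (sum(burst_band_mix) <= 0) stop("invalid parameter: burst_band_mix must have positive total")
  if (!setequal(names(burst_band_mix), names(lfp_bands())))
    stop("invalid parameter: burst_band_mix must name delta, theta_alpha, beta, gamma")
  if (aperiodic_exponent >= 0) stop("invalid parameter: aperiodic_exponent must be negative")
  if (spike_lock_kappa < 0) stop("invalid parameter: spike_lock_kappa must be >= 0")
  if (!spike_lock_band %in% names(lfp_bands()))
    stop("invalid parameter: unknown spike_lock_band")
  if (!is.function(dose_response)) stop("invalid parameter: dose_response must be a function")
  if (abs(dose_response(0) - 1) > 1e-9)
    stop("invalid parameter: dose_response(0) must be 1")
  dgrid <- dose_response(seq(0, 4, by = 0.25))
  if (any(diff(dgrid) > 1e-9) || any(dgrid < -1e-9) || any(dgrid > 1 + 1e-9))
    stop("invalid parameter: dose_response must be nonincreasing with values in [0, 1]")
  structure(list(sampling_rate_hz = sampling_rate_hz, duration_s = duration_s,
                 burst_rate_hz = burst_rate_hz, burst_duration_s = burst_duration_s,
                 burst_band_mix = burst_band_mix,
                 aperiodic_exponent = aperiodic_exponent,
                 noise_sd_uv = noise_sd_uv, burst_amp_uv = burst_amp_uv,
                 spike_rate_hz = spike_rate_hz,
                 spike_lock_kappa = spike_lock_kappa,
                 spike_lock_band = spike_lock_band,
                 dose_response = dose_response,
                 band_dose_slopes = band_dose_slopes,
                 seed = as.integer(seed)),
            class = "neonatal_lfp_params")
}

# validate a concentrations schedule: data.frame(start_s, level)
check_concentrations <- function(concentrations, duration_s) {
  if (!is.data.frame(concentrations) ||
      !all(c("start_s", "level") %in% names(concentrations)))
    stop("invalid parameter: `concentrations` needs columns start_s and level")
  concentrations <- concentrations[order(concentrations$start_s), , drop = FALSE]
  if (concentrations$start_s[1] > 0)
    stop("invalid parameter: concentration schedule must cover the trace from t = 0")
  if (any(concentrations$start_s >= duration_s))
    stop("invalid parameter: concentration segment starts beyond the trace")
  concentrations
}

# level as a function of time for a step schedule
level_at_time <- function(concentrations, t) {
  idx <- findInterval(t, concentrations$start_s)
  idx[idx < 1L] <- 1L
  concentrations$level[idx]
}

# lognormal(meanlog, sdlog) from a target mean and sd on the natural scale
lognormal_pars <- function(mean, sd) {
  sdlog2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

# draw burst intervals: thinned Poisson initiations, lognormal durations,
# sequential placement with overlap rejection (min 0.5 s inter-burst gap so
# distinct true events stay separable from the detector's 200 ms merge rule)
draw_burst_events <- function(params, concentrations) {
  dur <- params$duration_s
  exp_n <- params$burst_rate_hz * dur
  n_cand <- stats::rpois(1, exp_n)
  if (n_cand == 0) return(data.frame(start_s = numeric(0), stop_s = numeric(0)))
  arr <- sort(stats::runif(n_cand, 0, dur))
  keep <- stats::runif(n_cand) < params$dose_response(level_at_time(concentrations, arr))
  arr <- arr[keep]
  lp <- lognormal_pars(params$burst_duration_s$mean, params$burst_duration_s$sd)
  durs <- pmax(1.2, stats::rlnorm(length(arr), lp$meanlog, lp$sdlog))
  starts <- numeric(0); stops <- numeric(0)
  last_stop <- -Inf
  for (i in seq_along(arr)) {
    if (arr[i] < last_stop + 0.5) next
    stop_i <- arr[i] + durs[i]
    if (stop_i > dur - 0.2) next
    starts <- c(starts, arr[i]); stops <- c(stops, stop_i)
    last_stop <- stop_i
  }
  data.frame(start_s = starts, stop_s = stops)
}

# place phase-locked spikes inside bursts; phi is the instantaneous phase of
# the lock-band carrier over the whole trace
place_locked_spikes <- function(events, phi, fs, rate_hz, kappa) {
  times <- numeric(0); phases <- numeric(0)
  for (e in seq_len(nrow(events))) {
    i0 <- floor(events$start_s[e] * fs) + 1L
    i1 <- min(length(phi), ceiling(events$stop_s[e] * fs))
    idx <- i0:i1
    n_sp <- stats::rpois(1, rate_hz * (events$stop_s[e] - events$start_s[e]))
    if (n_sp == 0) next
    th <- rvonmises(n_sp, 0, kappa)
    pick <- integer(n_sp)
    for (k in seq_len(n_sp)) {
      d <- abs(wrap_angle(phi[idx] - th[k]))
      near <- which(d < 0.15)
      pick[k] <- if (length(near)) near[sample.int(length(near), 1)] else which.min(d)
    }
    sel <- idx[pick]
    times <- c(times, (sel - 1) / fs)
    phases <- c(phases, phi[sel])
  }
  o <- order(times)
  list(times_s = times[o], phases = phases[o])
}

new_ground_truth <- function(events, spike_times, spike_phases, duration_s,
                             concentration_per_minute,
                             artifact_mask = NULL) {
  n_ep <- ceiling(duration_s / 5)
  if (is.null(artifact_mask)) artifact_mask <- rep(FALSE, n_ep)
  structure(list(events = events, spike_times = spike_times,
                 spike_phases = spike_phases, artifact_mask = artifact_mask,
                 concentration_per_minute = concentration_per_minute),
            class = "ground_truth")
}

#' Generate a discontinuous neonatal mouse LFP session
#'
#' The signal is a 1/f background plus bursts placed by a thinned Poisson
#' process whose initiation rate is `burst_rate_hz * dose_response(level)`.
#' Bursts carry a stationary mixed-band oscillation (so the *within-burst*
#' spectral mix is identical across concentration levels), are gated with
#' 100 ms cosine ramps, and contain multi-unit spikes phase-locked to the
#' configured band by a von Mises law.
#'
#' @param params a [neonatal_lfp_params()] object.
#' @param concentrations data frame with columns `start_s` and `level`
#'   giving the stepwise anesthetic schedule (default: 0 throughout).
#' @param regions character vector of recorded regions (one channel each).
#' @param include_spikes logical; skip spike placement for speed when only
#'   the LFP is needed.
#'
#' @return list with `recording` (a [ts_recording()]) and `truth` (a
#'   `ground_truth` with true burst intervals, spike times/phases, artifact
#'   mask and per-minute concentration).
#' @export
gen_neonatal_session <- function(params,
                                 concentrations = data.frame(start_s = 0, level = 0),
                                 regions = c("PFC", "HP"),
                                 include_spikes = TRUE) {
  stopifnot(inherits(params, "neonatal_lfp_params"))
  concentrations <- check_concentrations(concentrations, params$duration_s)
  fs <- params$sampling_rate_hz
  n <- round(params$duration_s * fs)
  set.seed(params$seed)

  events <- draw_burst_events(params, concentrations)
  lp_amp <- stats::rlnorm(nrow(events),
                          log(params$burst_amp_uv$mean) - params$burst_amp_uv$sdlog^2 / 2,
                          params$burst_amp_uv$sdlog)
  # burst gate with per-event amplitude
  env <- numeric(n)
  ramp_n <- round(0.1 * fs)
  for (e in seq_len(nrow(events))) {
    i0 <- floor(events$start_s[e] * fs) + 1L
    i1 <- min(n, ceiling(events$stop_s[e] * fs))
    env <- env + lp_amp[e] * taper_gate(n, i0, i1, ramp_n)
  }

  bands <- lfp_bands()
  w <- params$burst_band_mix / sum(params$burst_band_mix)
  n_reg <- length(regions)
  # per-region band components; consecutive regions share one complex FFT
  comp <- lapply(seq_len(n_reg), function(r)
    stats::setNames(vector("list", length(bands)), names(bands)))
  for (b in names(bands)) {
    r <- 1L
    while (r <= n_reg) {
      pair <- band_limited_noise_pair(n, fs, bands[[b]][1], bands[[b]][2])
      comp[[r]][[b]] <- pair[[1]]
      if (r + 1L <= n_reg) comp[[r + 1L]][[b]] <- pair[[2]]
      r <- r + 2L
    }
  }
  data <- matrix(0, n_reg, n)
  spike_times <- stats::setNames(vector("list", n_reg), regions)
  spike_phases <- spike_times
  for (r in seq_len(n_reg)) {
    carrier <- Reduce(`+`, Map(function(b, x) sqrt(w[[b]]) * x,
                               names(comp[[r]]), comp[[r]]))
    bg <- one_over_f_noise(n, fs, params$aperiodic_exponent)
    data[r, ] <- params$noise_sd_uv * bg + env * carrier
    if (include_spikes && nrow(events) > 0 && params$spike_rate_hz > 0) {
      phi <- Arg(analytic_signal(comp[[r]][[params$spike_lock_band]]))
      sp <- place_locked_spikes(events, phi, fs, params$spike_rate_hz,
                                params$spike_lock_kappa)
      spike_times[[r]] <- sp$times_s
      spike_phases[[r]] <- sp$phases
    } else {
      spike_times[[r]] <- numeric(0)
      spike_phases[[r]] <- numeric(0)
    }
  }

  timeline <- data.frame(time_s = concentrations$start_s,
                         concentration = concentrations$level)
  rec <- ts_recording(data, fs, channel_labels = regions, regions = regions,
                      modality = "LFP", timeline = timeline)
  events$duration_s <- events$stop_s - events$start_s
  events$amplitude_uv <- lp_amp
  events$snr <- lp_amp / params$noise_sd_uv
  cpm <- level_at_time(concentrations,
                       (seq_len(floor(params$duration_s / 60)) - 1) * 60)
  truth <- new_ground_truth(events, spike_times, spike_phases,
                            params$duration_s, cpm)
  list(recording = rec, truth = truth)
}

#' Generate a continuous juvenile/adult-like mouse LFP session
#'
#' Continuous mode: the burst process is disabled and oscillatory activity
#' covers the full trace. Anesthetized segments scale each band's log10
#' power by `band_dose_slopes[band] * level`, emulating the adult-like
#' dose-dependent delta increase and beta/gamma decrease.
#'
#' @inheritParams gen_neonatal_session
#' @return list with `recording` and `truth` (no burst events).
#' @export
gen_juvenile_session <- function(params,
                                 concentrations = data.frame(start_s = 0, level = 0),
                                 regions = "PFC") {
  stopifnot(inherits(params, "neonatal_lfp_params"))
  concentrations <- check_concentrations(concentrations, params$duration_s)
  fs <- params$sampling_rate_hz
  n <- round(params$duration_s * fs)
  set.seed(params$seed)

  lev <- level_at_time(concentrations, (seq_len(n) - 1) / fs)
  bands <- lfp_bands()
  w <- params$burst_band_mix / sum(params$burst_band_mix)
  slopes <- params$band_dose_slopes
  data <- matrix(0, length(regions), n)
  for (r in seq_along(regions)) {
    osc <- numeric(n)
    for (b in names(bands)) {
      gain <- 10^(slopes[[b]] * lev / 2)
      osc <- osc + sqrt(w[[b]]) * gain *
        band_limited_noise(n, fs, bands[[b]][1], bands[[b]][2])
    }
    bg <- one_over_f_noise(n, fs, params$aperiodic_exponent)
    data[r, ] <- params$noise_sd_uv * (0.5 * bg + osc)
  }
  timeline <- data.frame(time_s = concentrations$start_s,
                         concentration = concentrations$level)
  rec <- ts_recording(data, fs, channel_labels = regions, regions = regions,
                      modality = "LFP", timeline = timeline)
  cpm <- level_at_time(concentrations,
                       (seq_len(floor(params$duration_s / 60)) - 1) * 60)
  truth <- new_ground_truth(
    data.frame(start_s = numeric(0), stop_s = numeric(0),
               duration_s = numeric(0), amplitude_uv = numeric(0),
               snr = numeric(0)),
    stats::setNames(rep(list(numeric(0)), length(regions)), regions),
    stats::setNames(rep(list(numeric(0)), length(regions)), regions),
    params$duration_s, cpm)
  list(recording = rec, truth = truth)
}

# default 10/20-style montage used by the infant generator
default_eeg_montage <- function() {
  c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4", "Cz",
    "F7", "F8", "Fpz", "O1", "O2", "T3", "T4", "T5", "T6", "Pz", "Fz", "Oz",
    paste0("E", 22:41))
}

#' Parameters of the infant EEG generator
#'
#' Emulates multichannel scalp EEG under volatile anesthesia. All channels
#' share a common amplitude-versus-concentration law
#' `gain = exp(amplitude_dose_slope * concentration)` with per-channel static
#' gain noise and slow per-minute amplitude jitter; the sign of the slope is
#' negative for 0-2 month subjects (broadband suppression) and positive for
#' 4-6 month subjects, reproducing the developmental switch. `band_dose_slopes`
#' (one per 5-Hz band, 1-50 Hz) add frequency-specific modulation. Artifacts
#' (digitizer-rail saturation, >150 uV transients, high cross-channel-median
#' segments) are injected per `artifact_spec` and recorded in ground truth.
#'
#' @param age_group one of `"0-2"`, `"2-4"`, `"4-6"` (months).
#' @param n_channels number of scalp channels (2-41).
#' @param sampling_rate_hz sampling rate (Hz); 256 by default at desk scale.
#' @param duration_min session length in minutes; must leave at least 20
#'   artifact-free minutes.
#' @param concentration_profile data frame with columns `minute` and
#'   `concentration` (end-tidal, dimensionless fraction of an age-adjusted
#'   reference); step-interpolated to a 1 Hz timeline.
#' @param amplitude_dose_slope signed log-amplitude slope per concentration
#'   unit; defaults to -0.25 / +0.08 / +0.25 for the three age groups, and is
#'   sign-checked against `age_group`.
#' @param band_dose_slopes numeric length-10 per-band slopes; defaults to 0
#'   for 0-2 months (purely broadband) and a delta-up / fast-down pattern for
#'   the older groups.
#' @param noise_sd_uv baseline broadband amplitude scale (uV).
#' @param amp_jitter_sd sd of the lognormal per-minute amplitude jitter.
#' @param artifact_spec list with counts `n_saturation`, `n_transient`,
#'   `n_high_median` (5-s epochs affected) and `rail_uv`, the digitizer rail.
#' @param age_months numeric age used as a model feature; defaults to the
#'   midpoint of `age_group`.
#' @param seed integer RNG seed.
#'
#' @return an object of class `infant_eeg_params`.
#' @export
infant_eeg_params <- function(age_group = c("0-2", "2-4", "4-6"),
                              n_channels = 9,
                              sampling_rate_hz = 256,
                              duration_min = 28,
                              concentration_profile = NULL,
                              amplitude_dose_slope = NULL,
                              band_dose_slopes = NULL,
                              noise_sd_uv = 10,
                              amp_jitter_sd = 0.03,
                              artifact_spec = list(n_saturation = 2,
                                                   n_transient = 3,
                                                   n_high_median = 2,
                                                   rail_uv = 400),
                              age_months = NULL,
                              seed = 1L) {
  age_group <- match.arg(age_group)
  if (n_channels < 2) stop("invalid parameter: need >= 2 channels (common-average reference undefined)")
  if (n_channels > 41) stop("invalid parameter: n_channels must be <= 41")
  if (sampling_rate_hz <= 0) stop("invalid parameter: sampling_rate_hz must be positive")
  if (is.null(concentration_profile)) {
    # induction -> plateau -> emergence
    concentration_profile <- data.frame(
      minute = c(0, 5, 6, 7, 8, 9, 18, 20, 22, 24),
      concentration = c(0, 1, 1.5, 2, 2.5, 3, 3, 2, 1.2, 0.6))
  }
  if (!all(c("minute", "concentration") %in% names(concentration_profile)))
    stop("invalid parameter: concentration_profile needs columns minute and concentration")
  if (any(concentration_profile$concentration < 0))
    stop("invalid parameter: concentration_profile must be nonnegative")
  default_slope <- c("0-2" = -0.25, "2-4" = 0.08, "4-6" = 0.25)[[age_group]]
  if (is.null(amplitude_dose_slope)) amplitude_dose_slope <- default_slope
  if (age_group == "0-2" && amplitude_dose_slope > 0)
    stop("invalid parameter: 0-2 month subjects require a nonpositive amplitude_dose_slope")
  if (age_group == "4-6" && amplitude_dose_slope < 0)
    stop("invalid parameter: 4-6 month subjects require a nonnegative amplitude_dose_slope")
  if (is.null(band_dose_slopes)) {
    band_dose_slopes <- if (age_group == "0-2") rep(0, 10)
      else c(0.15, 0.05, rep(-0.05, 4), rep(-0.1, 4))
  }
  if (length(band_dose_slopes) != 10)
    stop("invalid parameter: band_dose_slopes must have one value per 5-Hz band (10)")
  if (is.null(age_months))
    age_months <- c("0-2" = 1, "2-4" = 3, "4-6" = 5)[[age_group]]
  structure(list(age_group = age_group, n_channels = as.integer(n_channels),
                 sampling_rate_hz = sampling_rate_hz,
                 duration_min = duration_min,
                 concentration_profile = concentration_profile,
                 amplitude_dose_slope = amplitude_dose_slope,
                 band_dose_slopes = band_dose_slopes,
                 noise_sd_uv = noise_sd_uv, amp_jitter_sd = amp_jitter_sd,
                 artifact_spec = artifact_spec,
                 age_months = age_months, seed = as.integer(seed)),
            class = "infant_eeg_params")
}

# 5-Hz feature/generation bands over 1-50 Hz: [1,5), [5,10), ..., [45,50)
eeg_5hz_bands <- function() {
  lo <- c(1, seq(5, 45, by = 5))
  cbind(lo = lo, hi = c(seq(5, 50, by = 5)))
}

#' Generate an infant scalp EEG session
#'
#' @param params an [infant_eeg_params()] object.
#' @return list with `recording` (EEG `ts_recording` with a 1 Hz
#'   concentration timeline) and `truth` (artifact mask per 5-s epoch and
#'   per-minute concentration).
#' @export
gen_infant_session <- function(params) {
  stopifnot(inherits(params, "infant_eeg_params"))
  fs <- params$sampling_rate_hz
  dur_s <- params$duration_min * 60
  n <- round(dur_s * fs)
  nch <- params$n_channels
  spec <- params$artifact_spec
  n_art <- spec$n_saturation + spec$n_transient + spec$n_high_median
  if (floor(params$duration_min) - n_art < 20)
    stop("fewer than 20 artifact-free minutes would remain; extend duration_min")
  set.seed(params$seed)

  # 1 Hz concentration timeline from the minute-level profile
  prof <- params$concentration_profile[order(params$concentration_profile$minute), ]
  sec <- seq(0, dur_s - 1)
  conc_1hz <- prof$concentration[pmax(1, findInterval(sec / 60, prof$minute))]
  conc_smp <- conc_1hz[pmin(length(conc_1hz), floor((seq_len(n) - 1) / fs) + 1)]

  gain <- exp(params$amplitude_dose_slope * conc_smp)
  n_min <- ceiling(params$duration_min)
  jit <- exp(stats::rnorm(n_min, 0, params$amp_jitter_sd))
  jit_smp <- jit[pmin(n_min, floor((seq_len(n) - 1) / (60 * fs)) + 1)]

  bands <- eeg_5hz_bands()
  centers <- (bands[, "lo"] + bands[, "hi"]) / 2
  w <- (1 / centers) / sum(1 / centers)        # pink-like band weights
  band_gain <- lapply(seq_len(nrow(bands)), function(b)
    10^(params$band_dose_slopes[b] * conc_smp / 2))

  labels <- default_eeg_montage()[seq_len(nch)]
  ch_gain <- exp(stats::rnorm(nch, 0, 0.1))
  data <- matrix(0, nch, n)
  for (b in seq_len(nrow(bands))) {
    contrib <- sqrt(w[b]) * band_gain[[b]]
    ch <- 1L
    while (ch <= nch) {
      pair <- band_limited_noise_pair(n, fs, bands[b, "lo"], bands[b, "hi"])
      data[ch, ] <- data[ch, ] + contrib * pair[[1]]
      if (ch + 1L <= nch) data[ch + 1L, ] <- data[ch + 1L, ] + contrib * pair[[2]]
      ch <- ch + 2L
    }
  }
  scale_t <- params$noise_sd_uv * gain * jit_smp
  for (ch in seq_len(nch)) data[ch, ] <- ch_gain[ch] * scale_t * data[ch, ]

  # inject artifacts into distinct 5-s epochs (never the first epoch, so a
  # clean baseline sample always exists)
  n_ep <- floor(dur_s / 5)
  mask <- rep(FALSE, ceiling(dur_s / 5))
  art_types <- character(0)
  if (n_art > 0) {
    picked <- 1 + sample.int(n_ep - 1, n_art)
    art_types <- rep(c("saturation", "transient", "high_median"),
                     times = c(spec$n_saturation, spec$n_transient,
                               spec$n_high_median))
    for (k in seq_along(picked)) {
      ep <- picked[k]
      i0 <- (ep - 1) * 5 * fs + 1
      i1 <- min(n, ep * 5 * fs)
      if (art_types[k] == "saturation") {
        # >= 1.5 s pinned at the digitizer rail on every channel
        run <- i0:min(i1, i0 + round(1.5 * fs))
        data[, run] <- spec$rail_uv
      } else if (art_types[k] == "transient") {
        ch <- sample.int(nch, 1)
        run <- i0:min(i1, i0 + round(0.08 * fs))
        data[ch, run] <- data[ch, run] + 250
      } else {
        idx <- i0:i1
        t_rel <- (idx - i0) / fs
        common <- 60 * sin(2 * pi * 6 * t_rel)
        data[, idx] <- sweep(data[, idx, drop = FALSE], 2, common, `+`)
      }
      mask[ep] <- TRUE
    }
  }

  timeline <- data.frame(time_s = sec, concentration = conc_1hz)
  rec <- ts_recording(data, fs, channel_labels = labels,
                      regions = rep("scalp", nch), modality = "EEG",
                      timeline = timeline)
  cpm <- vapply(seq_len(floor(params$duration_min)), function(m)
    mean(conc_1hz[((m - 1) * 60 + 1):(m * 60)]), numeric(1))
  truth <- new_ground_truth(
    data.frame(start_s = numeric(0), stop_s = numeric(0)),
    list(), list(), dur_s, cpm, artifact_mask = mask)
  truth$artifact_types <- art_types
  list(recording = rec, truth = truth)
}
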