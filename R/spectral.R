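# Quantitative signal metrics: Welch PSD, modulation index, band power,
# imaginary coherence, pairwise phase consistency, aperiodic 1/f slope,
# sample entropy and Spearman correlation.

# one-sided periodogram of one window (density, uV^2/Hz); `win` is a taper
# of the window's length, normalized by its energy so Parseval holds
periodogram_1s <- function(x, fs, win = NULL) {
  n <- length(x)
  if (is.null(win)) win <- rep(1, n)
  X <- stats::fft(x * win)
  p <- (Mod(X)^2) / (fs * sum(win^2))
  half <- floor(n / 2) + 1L
  p <- p[seq_len(half)]
  if (n %% 2 == 0) {
    p[2:(half - 1L)] <- 2 * p[2:(half - 1L)]
  } else {
    p[2:half] <- 2 * p[2:half]
  }
  p
}

#' Welch power spectral density from 1-s windows
#'
#' Periodograms of concatenated 1-s windows are averaged (Welch's method
#' with non-overlapping rectangular windows), giving a 1 Hz frequency
#' resolution. Windows may come from the full signal or from concatenated
#' active periods.
#'
#' @param segments list of numeric windows, each exactly `round(fs)` samples.
#' @param fs sampling rate (Hz).
#' @param source provenance tag: `"full_signal"` or `"active_periods"`.
#' @param window per-window taper, `"hamming"` (the common Welch default;
#'   controls leakage from strong low-frequency components into the
#'   high-frequency tail) or `"rectangular"`.
#' @return a `psd_result`: `freqs_hz`, `power`, `n_windows`, `source`.
#' @export
welch_psd <- function(segments, fs, source = c("full_signal", "active_periods"),
                      window = c("hamming", "rectangular")) {
  source <- match.arg(source)
  window <- match.arg(window)
  if (length(segments) == 0) stop("no segments supplied")
  n <- round(fs)
  if (any(vapply(segments, length, integer(1)) != n))
    stop("invalid parameter: each segment must be exactly round(fs) samples (1 s)")
  win <- if (window == "hamming")
    0.54 - 0.46 * cos(2 * pi * seq(0, n - 1) / (n - 1)) else rep(1, n)
  p <- Reduce(`+`, lapply(segments, periodogram_1s, fs = fs, win = win)) /
    length(segments)
  structure(list(freqs_hz = seq(0, fs / 2, length.out = length(p)),
                 power = p, n_windows = length(segments), source = source),
            class = "psd_result")
}

# split a vector (or a channel of a recording) into non-overlapping 1-s windows
one_second_windows <- function(x, fs) {
  n <- round(fs)
  k <- length(x) %/% n
  if (k < 1) return(list())
  lapply(seq_len(k), function(i) x[((i - 1) * n + 1):(i * n)])
}

#' PSD of a recording channel
#'
#' Convenience wrapper around [welch_psd()]: either over the full signal or
#' over 1-s windows that lie entirely inside the given active periods
#' (event windows are concatenated, mirroring the event-restricted spectra).
#'
#' @param rec a [ts_recording()].
#' @param channel channel index or label.
#' @param events optional `oscillation_events`; when given, only windows
#'   fully covered by an event are used and `source` is `"active_periods"`.
#' @param from_s,to_s optional time range restriction (s).
#' @return a `psd_result`.
#' @export
signal_psd <- function(rec, channel = 1, events = NULL,
                       from_s = 0, to_s = duration_s(rec)) {
  ch <- if (is.character(channel)) match(channel, rec$channel_labels) else channel
  fs <- rec$sampling_rate_hz
  x <- rec$data[ch, sample_range(rec, from_s, to_s)]
  if (is.null(events)) return(welch_psd(one_second_windows(x, fs), fs))
  segs <- list()
  n1 <- round(fs)
  for (e in seq_len(nrow(events))) {
    s0 <- max(events$start_s[e], from_s)
    s1 <- min(events$stop_s[e], to_s)
    if (s1 - s0 < 1) next
    i0 <- floor((s0 - from_s) * fs) + 1L
    k <- floor((s1 - s0))
    for (j in seq_len(k)) {
      idx <- (i0 + (j - 1) * n1):(i0 + j * n1 - 1L)
      if (max(idx) <= length(x)) segs[[length(segs) + 1L]] <- x[idx]
    }
  }
  welch_psd(segs, fs, source = "active_periods")
}

#' Modulation index
#'
#' `MI = (post - pre) / (post + pre)`, elementwise over a frequency grid or
#' on band scalars; bounded in \[-1, 1\], antisymmetric in its arguments.
#' Entries where both inputs are zero are returned as `NA`.
#'
#' @param p_pre,p_post nonnegative power values (scalars or vectors).
#' @return numeric MI value(s).
#' @export
modulation_index <- function(p_pre, p_post) {
  if (any(p_pre < 0, na.rm = TRUE) || any(p_post < 0, na.rm = TRUE))
    stop("invalid parameter: power values must be nonnegative")
  denom <- p_post + p_pre
  out <- (p_post - p_pre) / denom
  out[denom == 0] <- NA_real_
  out
}

#' Integrated band power
#'
#' Trapezoidal integral of the PSD over the grid points falling in
#' `[lo, hi]`.
#'
#' @param psd a `psd_result`.
#' @param band numeric `c(lo_hz, hi_hz)` or a band name from the canonical
#'   set (`"delta"`, `"theta_alpha"`, `"beta"`, `"gamma"`).
#' @return scalar power (uV^2).
#' @export
band_power <- function(psd, band) {
  if (is.character(band)) band <- lfp_bands()[[band]]
  if (is.null(band) || length(band) != 2 || band[1] >= band[2])
    stop("invalid parameter: band must be c(lo, hi) with lo < hi")
  f <- psd$freqs_hz
  if (band[1] < min(f) || band[2] > max(f))
    stop("invalid parameter: band outside the PSD range")
  idx <- which(f >= band[1] & f <= band[2])
  if (length(idx) < 2) stop("invalid parameter: band narrower than the grid")
  sum(diff(f[idx]) * (psd$power[idx][-1] + psd$power[idx][-length(idx)]) / 2)
}

#' Imaginary coherence
#'
#' Absolute value of the imaginary part of the normalized cross-spectrum,
#' insensitive to zero-lag (volume-conducted) coupling. Spectra are
#' estimated Welch-style from 1-s Hann windows with 50% overlap.
#'
#' @param x,y equal-length signals.
#' @param fs sampling rate (Hz).
#' @param seg_s segment length (s).
#' @param overlap fractional overlap between segments.
#' @return list with `freqs_hz`, `icoh` (in \[0,1\]) and `coherence` (the
#'   magnitude coherence, which bounds `icoh` from above).
#' @export
imaginary_coherence <- function(x, y, fs, seg_s = 1, overlap = 0.5) {
  if (length(x) != length(y)) stop("invalid parameter: signals must have equal length")
  w <- round(seg_s * fs)
  h <- max(1L, round(w * (1 - overlap)))
  starts <- seq(1L, length(x) - w + 1L, by = h)
  if (length(starts) < 2) stop("need >= 2 segments for a normalized cross-spectrum")
  win <- 0.5 * (1 - cos(2 * pi * seq_len(w) / (w + 1)))   # Hann
  half <- floor(w / 2) + 1L
  sxx <- syy <- numeric(half)
  sxy <- complex(real = numeric(half), imaginary = numeric(half))
  for (s in starts) {
    xs <- (x[s:(s + w - 1L)] - mean(x[s:(s + w - 1L)])) * win
    ys <- (y[s:(s + w - 1L)] - mean(y[s:(s + w - 1L)])) * win
    X <- stats::fft(xs)[seq_len(half)]
    Y <- stats::fft(ys)[seq_len(half)]
    sxx <- sxx + Mod(X)^2
    syy <- syy + Mod(Y)^2
    sxy <- sxy + X * Conj(Y)
  }
  cxy <- sxy / sqrt(sxx * syy)
  cxy[!is.finite(cxy)] <- 0
  list(freqs_hz = seq(0, fs / 2, length.out = half),
       icoh = abs(Im(cxy)), coherence = Mod(cxy))
}

#' Pairwise phase consistency (PPC)
#'
#' Spike-field phase locking: the band-of-interest phase is extracted with
#' the Hilbert transform and the mean cosine of the angular distance over all
#' unordered spike pairs is computed via the closed-form identity
#' `(|sum exp(i theta)|^2 - n) / (n (n - 1))`, which is unbiased by spike
#' count.
#'
#' @param spike_times spike times (s).
#' @param lfp the field signal (numeric vector).
#' @param band `c(lo, hi)` band of interest (Hz).
#' @param fs sampling rate (Hz).
#' @return scalar PPC (NA when fewer than 2 spikes).
#' @export
ppc <- function(spike_times, lfp, band, fs) {
  if (length(spike_times) < 2) return(NA_real_)
  phi <- instantaneous_phase(lfp, fs, band)
  idx <- pmin(length(phi), pmax(1L, round(spike_times * fs) + 1L))
  ppc_from_phases(phi[idx])
}

#' PPC from phases
#'
#' @param phases spike phases (radians).
#' @return scalar PPC.
#' @export
ppc_from_phases <- function(phases) {
  n <- length(phases)
  if (n < 2) return(NA_real_)
  rsum2 <- Mod(sum(exp(1i * phases)))^2
  (rsum2 - n) / (n * (n - 1))
}

#' Aperiodic 1/f slope
#'
#' Robust (iteratively reweighted) linear fit of `log10(power)` on
#' `log10(frequency)`, restricted to the 20-40 Hz range by default. Grid
#' points with nonpositive power are dropped.
#'
#' @param psd a `psd_result` (typically of a 1-min bin).
#' @param fit_range frequency range of the fit (Hz).
#' @return a `slope_estimate`: `slope` (log-power per log-frequency decade),
#'   `intercept`, `fit_range_hz`, `n_points`.
#' @export
aperiodic_slope <- function(psd, fit_range = c(20, 40)) {
  idx <- which(psd$freqs_hz >= fit_range[1] & psd$freqs_hz <= fit_range[2])
  if (length(idx) < 10)
    stop("invalid parameter: PSD must cover the fit range with >= 10 points")
  f <- psd$freqs_hz[idx]; p <- psd$power[idx]
  ok <- p > 0
  f <- f[ok]; p <- p[ok]
  if (length(f) < 3)
    return(structure(list(slope = NA_real_, intercept = NA_real_,
                          fit_range_hz = fit_range, n_points = length(f)),
                     class = "slope_estimate"))
  fit <- MASS::rlm(log10(p) ~ log10(f), maxit = 50)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 fit_range_hz = fit_range, n_points = length(f)),
            class = "slope_estimate")
}

#' Per-minute 1/f slope time course
#'
#' Welch PSD per `bin_s` bin followed by [aperiodic_slope()].
#'
#' @param rec a [ts_recording()].
#' @param channel channel index or label.
#' @param bin_s bin width (s), 60 by default.
#' @param fit_range fit range (Hz).
#' @return data frame with `bin`, `slope`, `intercept`.
#' @export
slope_timecourse <- function(rec, channel = 1, bin_s = 60,
                             fit_range = c(20, 40)) {
  n_bin <- floor(duration_s(rec) / bin_s)
  out <- lapply(seq_len(n_bin), function(b) {
    psd <- signal_psd(rec, channel, from_s = (b - 1) * bin_s, to_s = b * bin_s)
    est <- aperiodic_slope(psd, fit_range)
    data.frame(bin = b, slope = est$slope, intercept = est$intercept)
  })
  do.call(rbind, out)
}

#' Sample entropy
#'
#' `SampEn = -ln(A/B)` where `B` counts template pairs of length `m` and `A`
#' pairs of length `m + 1` matching within Chebyshev tolerance `r`
#' (self-matches excluded, embedding lag `tau`).
#'
#' @param x numeric window.
#' @param m template length (2 by default).
#' @param r tolerance; defaults to `0.2 * sd(x)`.
#' @param tau embedding lag.
#' @return scalar sample entropy (0 for a constant window; `NA` when no
#'   template pair matches).
#' @export
sample_entropy <- function(x, m = 2, r = 0.2 * stats::sd(x), tau = 1) {
  n <- length(x)
  n_t <- n - m * tau
  if (n_t < 2) stop("invalid parameter: window too short for the embedding")
  if (!is.finite(r)) return(NA_real_)
  # Chebyshev distances between m-length templates, built up by lag offsets
  idx <- seq_len(n_t)
  cheb <- matrix(0, n_t, n_t)
  for (k in 0:(m - 1)) {
    v <- x[idx + k * tau]
    cheb <- pmax(cheb, abs(outer(v, v, `-`)))
  }
  b_mat <- cheb <= r
  v <- x[idx + m * tau]
  cheb1 <- pmax(cheb, abs(outer(v, v, `-`)))
  a_mat <- cheb1 <= r
  B <- (sum(b_mat) - n_t) / 2
  A <- (sum(a_mat) - n_t) / 2
  if (B == 0 || A == 0) return(NA_real_)
  -log(A / B)
}

#' Sample entropy per window and 2-Hz frequency bin
#'
#' The signal is band-passed into 2-Hz bins (4th-order zero-phase
#' Butterworth; grid anchored at 1 Hz, up to 49 Hz) and sample entropy is
#' computed in non-overlapping 1.5-s windows with `r = 0.2 * sd` of each
#' windowed band signal and `tau = 1`.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param window_s window length (s).
#' @param m template length.
#' @param band_lo_hz lower edges of the 2-Hz bins.
#' @return matrix windows x bands of sample entropies.
#' @export
sample_entropy_profile <- function(x, fs, window_s = 1.5, m = 2,
                                   band_lo_hz = seq(1, 47, by = 2)) {
  w <- round(window_s * fs)
  if (w < 50) stop("invalid parameter: window yields fewer than 50 samples")
  n_win <- length(x) %/% w
  out <- matrix(NA_real_, n_win, length(band_lo_hz))
  colnames(out) <- sprintf("band_%g_%g", band_lo_hz, band_lo_hz + 2)
  for (b in seq_along(band_lo_hz)) {
    bf <- signal::butter(4, c(band_lo_hz[b], band_lo_hz[b] + 2) / (fs / 2),
                         type = "pass")
    xb <- signal::filtfilt(bf, x)
    for (i in seq_len(n_win)) {
      seg <- xb[((i - 1) * w + 1):(i * w)]
      out[i, b] <- sample_entropy(seg, m = m, r = 0.2 * stats::sd(seg), tau = 1)
    }
  }
  out
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties).
#'
#' @param x,y equal-length numeric vectors (length >= 3).
#' @return rho in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("invalid parameter: unequal lengths")
  if (length(x) < 3) stop("invalid parameter: need >= 3 observations")
  stats::cor(x, y, method = "spearman")
}
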