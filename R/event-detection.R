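# Multi-unit spike detection and unsupervised detection of the discontinuous
# active periods that characterize neonatal LFP/EEG.

# topographic prominence of local maxima of y at indices peaks (y = -signal
# for negative-deflection spikes): height above the higher of the two key
# saddles toward the nearest taller samples (trace edges count as walls)
peak_prominence <- function(y, peaks) {
  n <- length(y)
  vapply(peaks, function(i) {
    h <- y[i]
    left_min <- h
    j <- i - 1L
    while (j >= 1L && y[j] <= h) {
      if (y[j] < left_min) left_min <- y[j]
      j <- j - 1L
    }
    right_min <- h
    j <- i + 1L
    while (j <= n && y[j] <= h) {
      if (y[j] < right_min) right_min <- y[j]
      j <- j + 1L
    }
    h - max(left_min, right_min)
  }, numeric(1))
}

#' Detect multi-unit activity (MUA)
#'
#' Spikes are peaks of negative deflections that exceed `k_sd` times the
#' standard deviation of the (500-5000 Hz band-passed) signal and whose
#' topographic prominence is larger than half the peak amplitude itself. The
#' SD is computed over the full trace.
#'
#' @param rec a high-pass filtered [ts_recording()].
#' @param k_sd threshold multiplier (5 by default).
#' @return a list with one `spike_train` per channel: `channel`, sorted
#'   `times_s`, `threshold_used_uv`.
#' @export
detect_mua <- function(rec, k_sd = 5) {
  lapply(seq_len(nrow(rec$data)), function(ch) {
    x <- rec$data[ch, ]
    s <- stats::sd(x)
    thr <- -k_sd * s
    times <- numeric(0)
    if (is.finite(s) && s > 0) {
      n <- length(x)
      cand <- which(x < thr)
      cand <- cand[cand > 1L & cand < n]
      cand <- cand[x[cand] < x[cand - 1L] & x[cand] <= x[cand + 1L]]
      if (length(cand)) {
        prom <- peak_prominence(-x, cand)
        keep <- prom > abs(x[cand]) / 2
        times <- (cand[keep] - 1L) / rec$sampling_rate_hz
      }
    }
    structure(list(channel = rec$channel_labels[ch], times_s = times,
                   threshold_used_uv = thr),
              class = "spike_train")
  })
}

#' Firing rate over time windows
#'
#' Total spike count divided by total window duration, in Hz. With
#' `union = TRUE` the windows are pooled (one rate over the union of
#' intervals, e.g. "within active periods"); otherwise one rate per window.
#'
#' @param train a `spike_train` (or numeric vector of spike times).
#' @param windows data frame / matrix with columns `start_s`, `stop_s`.
#' @param union pool all windows into a single rate?
#' @return numeric rate(s) in Hz.
#' @export
firing_rate <- function(train, windows, union = FALSE) {
  times <- if (inherits(train, "spike_train")) train$times_s else train
  windows <- as.data.frame(windows)
  if (!all(c("start_s", "stop_s") %in% names(windows)))
    stop("invalid parameter: windows need start_s and stop_s")
  durs <- windows$stop_s - windows$start_s
  if (any(durs <= 0)) stop("invalid parameter: zero-length window")
  counts <- vapply(seq_len(nrow(windows)), function(i)
    sum(times >= windows$start_s[i] & times < windows$stop_s[i]), numeric(1))
  if (union) sum(counts) / sum(durs) else counts / durs
}

# sliding RMS of a vector: window w samples, hop h samples; returns the RMS
# values plus the window start times in samples (1-based)
sliding_rms <- function(x, w, h) {
  n <- length(x)
  starts <- seq(1L, n - w + 1L, by = h)
  cs <- c(0, cumsum(x^2))
  vals <- sqrt((cs[starts + w] - cs[starts]) / w)
  list(values = vals, starts = starts)
}

#' Fit the variance-dependent detection threshold
#'
#' The root mean square of the 1-100 Hz band-passed signal is computed in
#' sliding windows; a Gaussian is fitted (least squares on bin counts) to the
#' RMS histogram restricted to the bins from 0 up to and including the
#' histogram's global-maximum (modal) bin, which captures the silent-period
#' noise floor. The threshold is `mu + k_sigma * sigma`.
#'
#' @param rec a [ts_recording()].
#' @param channel channel index or label to fit on.
#' @param band analysis band (Hz).
#' @param rms_window_s RMS window length (s); windows overlap by 50%.
#' @param k_sigma threshold multiplier.
#' @param n_bins number of histogram bins from 0 to the maximum RMS.
#' @param filtered optional pre-computed band-filtered trace of `channel`.
#' @return a `detection_threshold`: `rms_window_s`, `band`, `histogram_bins`,
#'   `gaussian_mu`, `gaussian_sigma`, `k_sigma`, `threshold_value`, `channel`.
#' @export
fit_detection_threshold <- function(rec, channel = 1, band = c(1, 100),
                                    rms_window_s = 0.2, k_sigma = 3.5,
                                    n_bins = 100, filtered = NULL) {
  ch <- if (is.character(channel)) match(channel, rec$channel_labels) else channel
  if (is.na(ch) || ch < 1 || ch > nrow(rec$data))
    stop("invalid parameter: unknown channel")
  if (stats::sd(rec$data[ch, ]) == 0)
    stop("no noise floor: constant trace")
  x <- if (is.null(filtered)) filter_one_channel(rec, ch, band) else filtered
  fs <- rec$sampling_rate_hz
  w <- max(2L, round(rms_window_s * fs))
  h <- max(1L, w %/% 2L)
  rms <- sliding_rms(x, w, h)$values
  if (length(rms) < 100)
    stop("trace too short: need >= 100 RMS samples")
  if (max(rms) - min(rms) < 1e-12 * max(rms, 1e-300))
    stop("no noise floor: constant trace")

  breaks <- seq(0, max(rms), length.out = n_bins + 1)
  hst <- graphics::hist(rms, breaks = breaks, plot = FALSE)
  modal <- which.max(hst$counts)
  if (modal < 10) {
    # high-amplitude events stretch the RMS range and squash the noise floor
    # into the first bins: re-histogram over the noise-floor region so the
    # Gaussian fit sees a resolved mode
    cap <- 3 * breaks[modal + 1]
    breaks <- seq(0, cap, length.out = n_bins + 1)
    hst <- graphics::hist(rms[rms <= cap], breaks = breaks, plot = FALSE)
  }
  counts <- hst$counts
  mids <- hst$mids
  modal <- which.max(counts)
  fit_idx <- seq_len(modal)
  mu0 <- mids[modal]
  sd0 <- max(stats::sd(rms[rms <= breaks[modal + 1]]), diff(breaks)[1] / 2)
  mu <- mu0; sig <- sd0
  if (length(fit_idx) >= 4) {
    obj <- function(p) {
      sum((counts[fit_idx] - p[1] * exp(-(mids[fit_idx] - p[2])^2 /
                                          (2 * p[3]^2)))^2)
    }
    opt <- try(stats::optim(c(max(counts), mu0, sd0), obj,
                            method = "L-BFGS-B",
                            lower = c(1e-6, 0, diff(breaks)[1] / 10)),
               silent = TRUE)
    if (!inherits(opt, "try-error") && opt$convergence == 0) {
      mu <- opt$par[2]; sig <- opt$par[3]
    }
  }
  structure(list(rms_window_s = rms_window_s, band = band,
                 histogram_bins = n_bins, gaussian_mu = mu,
                 gaussian_sigma = sig, k_sigma = k_sigma,
                 threshold_value = mu + k_sigma * sig, channel = ch),
            class = "detection_threshold")
}

# merge sorted intervals whose gaps are below merge_gap
merge_intervals <- function(iv, merge_gap) {
  if (nrow(iv) == 0) return(iv)
  iv <- iv[order(iv$start_s), , drop = FALSE]
  out_start <- iv$start_s[1]; out_stop <- iv$stop_s[1]
  starts <- numeric(0); stops <- numeric(0)
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv$start_s[i] - out_stop < merge_gap) {
      out_stop <- max(out_stop, iv$stop_s[i])
    } else {
      starts <- c(starts, out_start); stops <- c(stops, out_stop)
      out_start <- iv$start_s[i]; out_stop <- iv$stop_s[i]
    }
  }
  data.frame(start_s = c(starts, out_start), stop_s = c(stops, out_stop))
}

#' Detect discontinuous active periods (oscillation events)
#'
#' Runs of the sliding RMS strictly above the fitted threshold become
#' candidate events; candidates closer than `merge_gap_s` (200 ms) are
#' considered one event; events lasting no more than `min_duration_s` (1 s)
#' are dropped. Event amplitude is the maximum absolute deflection of the
#' detection-band-filtered trace within the event.
#'
#' @param rec a [ts_recording()].
#' @param thr a `detection_threshold` from [fit_detection_threshold()]
#'   (fitted on the same channel and band).
#' @param merge_gap_s merge events separated by less than this (s).
#' @param min_duration_s drop events of duration <= this (s).
#' @param filtered optional pre-computed detection-band-filtered trace of the
#'   threshold's channel (reused to avoid refiltering long sessions).
#' @return data frame of class `oscillation_events` with `start_s`,
#'   `stop_s`, `duration_s`, `amplitude_uv` (possibly 0 rows).
#' @export
detect_active_periods <- function(rec, thr, merge_gap_s = 0.2,
                                  min_duration_s = 1.0, filtered = NULL) {
  stopifnot(inherits(thr, "detection_threshold"))
  x <- if (is.null(filtered)) filter_one_channel(rec, thr$channel, thr$band)
       else filtered
  fs <- rec$sampling_rate_hz
  w <- max(2L, round(thr$rms_window_s * fs))
  h <- max(1L, w %/% 2L)
  rms <- sliding_rms(x, w, h)
  supra <- rms$values > thr$threshold_value
  empty <- data.frame(start_s = numeric(0), stop_s = numeric(0),
                      duration_s = numeric(0), amplitude_uv = numeric(0))
  class(empty) <- c("oscillation_events", "data.frame")
  if (!any(supra)) return(empty)
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1L
  runs <- which(r$values)
  iv <- data.frame(
    start_s = (rms$starts[begins[runs]] - 1L) / fs,
    stop_s = (rms$starts[ends[runs]] - 1L + w) / fs)
  iv <- merge_intervals(iv, merge_gap_s)
  iv <- iv[iv$stop_s - iv$start_s > min_duration_s, , drop = FALSE]
  if (nrow(iv) == 0) return(empty)
  iv$duration_s <- iv$stop_s - iv$start_s
  iv$amplitude_uv <- vapply(seq_len(nrow(iv)), function(e) {
    i0 <- max(1L, floor(iv$start_s[e] * fs) + 1L)
    i1 <- min(length(x), ceiling(iv$stop_s[e] * fs))
    max(abs(x[i0:i1]))
  }, numeric(1))
  rownames(iv) <- NULL
  class(iv) <- c("oscillation_events", "data.frame")
  iv
}

#' Occurrence time course of active periods
#'
#' Fraction of each time bin covered by events ("relative occurrence of
#' active periods normalized to total recording time"). Events are split at
#' bin edges; a partial trailing bin is normalized by its actual span.
#'
#' @param events an `oscillation_events` data frame.
#' @param bin_s bin width in seconds (60 = per-minute).
#' @param total_s total recording duration (s).
#' @return numeric vector of per-bin fractions in \[0, 1\].
#' @export
occurrence_timecourse <- function(events, bin_s = 60, total_s) {
  if (nrow(events) > 0 &&
      (min(events$start_s) < 0 || max(events$stop_s) > total_s + 1e-9))
    stop("invalid parameter: events outside [0, total_s]")
  n_bin <- ceiling(total_s / bin_s)
  out <- numeric(n_bin)
  for (b in seq_len(n_bin)) {
    b0 <- (b - 1) * bin_s
    b1 <- min(total_s, b * bin_s)
    if (nrow(events) > 0) {
      cov <- sum(pmax(0, pmin(events$stop_s, b1) - pmax(events$start_s, b0)))
    } else cov <- 0
    out[b] <- cov / (b1 - b0)
  }
  out
}

#' Compare detected events with ground truth
#'
#' Event-wise recall/precision (an event counts as hit when it overlaps a
#' counterpart) and the mean temporal Jaccard index, computed per true event
#' against the union of detected events.
#'
#' @param detected,truth_events data frames with `start_s`, `stop_s`.
#' @return list with `recall`, `precision`, `mean_jaccard`.
#' @export
evaluate_detection <- function(detected, truth_events) {
  overlap_len <- function(a0, a1, b0, b1) pmax(0, pmin(a1, b1) - pmax(a0, b0))
  n_t <- nrow(truth_events); n_d <- nrow(detected)
  if (n_t == 0) return(list(recall = NA_real_, precision = NA_real_,
                            mean_jaccard = NA_real_))
  hit_t <- logical(n_t); jac <- numeric(n_t)
  for (i in seq_len(n_t)) {
    t0 <- truth_events$start_s[i]; t1 <- truth_events$stop_s[i]
    if (n_d == 0) next
    ov <- overlap_len(t0, t1, detected$start_s, detected$stop_s)
    touching <- ov > 0
    hit_t[i] <- any(touching)
    if (hit_t[i]) {
      inter <- sum(ov[touching])
      uni <- (t1 - t0) +
        sum(detected$stop_s[touching] - detected$start_s[touching]) - inter
      jac[i] <- inter / uni
    }
  }
  hit_d <- if (n_d == 0) logical(0) else vapply(seq_len(n_d), function(j)
    any(overlap_len(detected$start_s[j], detected$stop_s[j],
                    truth_events$start_s, truth_events$stop_s) > 0), logical(1))
  list(recall = mean(hit_t),
       precision = if (n_d == 0) NA_real_ else mean(hit_d),
       mean_jaccard = mean(jac))
}
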