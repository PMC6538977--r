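# Signal conditioning: zero-phase Butterworth filtering, anti-aliased
# downsampling, common-average referencing, amplitude envelope, and the
# 5-s-epoch artifact scoring scheme for infant EEG.

#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward (phase preserving) Butterworth filtering of every
#' channel. The default third-order design matches the 2-100 Hz LFP band;
#' the 500-5000 Hz setting isolates multi-unit activity.
#'
#' @param rec a [ts_recording()].
#' @param low_hz,high_hz band edges (Hz); `0 < low < high < Nyquist`.
#' @param order Butterworth order (the forward-backward pass doubles the
#'   effective order).
#' @return filtered `ts_recording`.
#' @export
bandpass_filter <- function(rec, low_hz, high_hz, order = 3) {
  nyq <- rec$sampling_rate_hz / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop("invalid parameter: need 0 < low_hz < high_hz < Nyquist (", nyq, " Hz)")
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  out <- rec
  for (ch in seq_len(nrow(rec$data)))
    out$data[ch, ] <- signal::filtfilt(bf, rec$data[ch, ])
  out
}

#' Anti-aliased downsampling
#'
#' Applies a zero-phase low-pass (cut at 80% of the target Nyquist) and
#' decimates by an integer factor. The concentration timeline is untouched.
#'
#' @param rec a [ts_recording()].
#' @param target_hz new sampling rate; must divide the current rate.
#' @return downsampled `ts_recording`.
#' @export
downsample <- function(rec, target_hz) {
  fs <- rec$sampling_rate_hz
  if (target_hz > fs) stop("invalid parameter: target rate above source rate")
  if (target_hz == fs) return(rec)
  fac <- fs / target_hz
  if (abs(fac - round(fac)) > 1e-9)
    stop("invalid parameter: target_hz must divide the sampling rate")
  fac <- as.integer(round(fac))
  bf <- signal::butter(4, 0.8 * target_hz / fs, type = "low")
  idx <- seq(1L, ncol(rec$data), by = fac)
  newdata <- matrix(0, nrow(rec$data), length(idx))
  for (ch in seq_len(nrow(rec$data)))
    newdata[ch, ] <- signal::filtfilt(bf, rec$data[ch, ])[idx]
  out <- rec
  out$data <- newdata
  out$sampling_rate_hz <- target_hz
  out
}

#' Common average reference
#'
#' Re-references each retained channel to the mean over retained channels, so
#' the cross-channel mean of the output is exactly zero at every sample.
#' Excluded (bad) channels are dropped from the output.
#'
#' @param rec a [ts_recording()].
#' @param excluded_channels labels of channels to drop before referencing.
#' @return re-referenced `ts_recording` containing the retained channels.
#' @export
common_average_reference <- function(rec, excluded_channels = character(0)) {
  keep <- !(rec$channel_labels %in% excluded_channels)
  if (sum(keep) < 2)
    stop("invalid parameter: need >= 2 retained channels for a common average reference")
  sub <- rec$data[keep, , drop = FALSE]
  ref <- colMeans(sub)
  out <- rec
  out$data <- sweep(sub, 2, ref, `-`)
  out$channel_labels <- rec$channel_labels[keep]
  out$regions <- rec$regions[keep]
  out
}

# zero-phase band-pass of a single channel (avoids filtering channels that
# are not analyzed)
filter_one_channel <- function(rec, channel, band, order = 3) {
  nyq <- rec$sampling_rate_hz / 2
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < nyq))
    stop("invalid parameter: need 0 < low < high < Nyquist (", nyq, " Hz)")
  bf <- signal::butter(order, band / nyq, type = "pass")
  signal::filtfilt(bf, rec$data[channel, ])
}

# centered moving average with shrinking edge windows, via cumulative sums
moving_average <- function(x, w) {
  n <- length(x)
  s <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(1L, i - ((w - 1L) %/% 2L))
  hi <- pmin(n, i + (w %/% 2L))
  (s[hi + 1L] - s[lo]) / (hi - lo + 1L)
}

#' Amplitude envelope by smoothed rectification
#'
#' Per channel, the centered moving average of the absolute signal with a
#' window of `round(window_s * fs)` samples (1 s by default, the 1024-point
#' window at 1024 Hz); edges use shrinking windows.
#'
#' @param rec a [ts_recording()].
#' @param window_s smoothing window length in seconds.
#' @return `ts_recording` holding the nonnegative envelope.
#' @export
amplitude_envelope <- function(rec, window_s = 1.0) {
  if (window_s <= 0) stop("invalid parameter: window_s must be positive")
  w <- max(1L, round(window_s * rec$sampling_rate_hz))
  if (w > ncol(rec$data)) stop("invalid parameter: window longer than the trace")
  out <- rec
  for (ch in seq_len(nrow(rec$data)))
    out$data[ch, ] <- moving_average(abs(rec$data[ch, ]), w)
  out
}

#' Flag channels with implausible broadband variance
#'
#' Automated proxy for the visual rejection of low signal-to-noise channels:
#' a channel is flagged when its broadband variance falls below 1% or above
#' 100 times the cross-channel median variance.
#'
#' @param rec a [ts_recording()].
#' @return character vector of flagged channel labels.
#' @export
flag_bad_channels <- function(rec) {
  v <- apply(rec$data, 1, stats::var)
  med <- stats::median(v)
  if (med == 0) return(character(0))
  rec$channel_labels[v < 0.01 * med | v > 100 * med]
}

# longest run of consecutive TRUEs
max_run <- function(b) {
  if (!any(b)) return(0L)
  r <- rle(b)
  max(r$lengths[r$values])
}

# per-column median of a small-row matrix without per-column function calls:
# repeatedly eliminate the column maximum down to the middle order statistic
col_medians <- function(m) {
  k <- nrow(m)
  if (k == 1) return(m[1, ])
  pop_max <- function(mm) {
    cm <- mm[1, ]
    for (i in 2:nrow(mm)) cm <- pmax(cm, mm[i, ])
    done <- rep(FALSE, ncol(mm))
    for (i in seq_len(nrow(mm))) {
      hit <- !done & mm[i, ] == cm
      mm[i, hit] <- -Inf
      done <- done | hit
    }
    list(m = mm, max = cm)
  }
  drop_n <- (k - 1L) %/% 2L             # eliminate down to the upper middle
  for (j in seq_len(drop_n)) m <- pop_max(m)$m
  res <- pop_max(m)
  upper <- res$max
  if (k %% 2 == 1) return(upper)
  lower <- pop_max(res$m)$max
  (upper + lower) / 2
}

# epochs (1-based ids) touched by runs of TRUE of length >= min_run
epochs_with_runs <- function(flag, min_run, ep_len, n_ep) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  sel <- which(r$values & r$lengths >= min_run)
  out <- logical(n_ep)
  for (s in sel) {
    i1 <- ends[s]; i0 <- i1 - r$lengths[s] + 1L
    e0 <- (i0 - 1L) %/% ep_len + 1L
    e1 <- min(n_ep, (i1 - 1L) %/% ep_len + 1L)
    if (e0 <= n_ep) out[e0:e1] <- TRUE
  }
  out
}

#' Score 5-s EEG epochs for artifact contamination
#'
#' Implements the automatic infant-EEG rejection scheme. An epoch is rejected
#' when (a) any retained channel is saturated, i.e. sits at the digitizer
#' rail value for at least `min_rail_run` consecutive samples, (b) any
#' retained channel exceeds `max_abs_uv` (150 uV) in absolute amplitude, or
#' (c) the per-sample median across retained channels of the 1-s amplitude
#' envelope exceeds `median_env_uv` (30 uV) at any sample. A minute is
#' removed when its contaminated time strictly exceeds
#' `max_contaminated_s_per_min` (10 s). The epoch grid is anchored at t = 0;
#' a partial trailing epoch is scored if at least half of it is present.
#'
#' @param rec an EEG [ts_recording()] with amplitudes in microvolts.
#' @param rules list overriding any of `epoch_length_s` (5), `max_abs_uv`
#'   (150), `median_env_uv` (30), `rail_uv` (400), `min_rail_run` (3),
#'   `max_contaminated_s_per_min` (10), `exclude_channels` (labels scored
#'   out; defaults to [flag_bad_channels()]).
#' @return an `epoch_mask`: list with `epoch_length_s`, `epoch_valid`,
#'   `minute_valid`, `per_channel_excluded` and `reasons` (per-epoch label).
#' @export
score_epochs <- function(rec, rules = list()) {
  if (ncol(rec$data) == 0) stop("empty recording")
  def <- list(epoch_length_s = 5, max_abs_uv = 150, median_env_uv = 30,
              rail_uv = 400, min_rail_run = 3L,
              max_contaminated_s_per_min = 10,
              exclude_channels = NULL)
  rules <- utils::modifyList(def, rules)
  if (is.null(rules$exclude_channels))
    rules$exclude_channels <- flag_bad_channels(rec)
  keep <- !(rec$channel_labels %in% rules$exclude_channels)
  if (!any(keep)) stop("all channels excluded")
  x <- rec$data[keep, , drop = FALSE]
  fs <- rec$sampling_rate_hz
  n <- ncol(x)
  ep_len <- round(rules$epoch_length_s * fs)

  env <- amplitude_envelope(
    ts_recording(x, fs, channel_labels = rec$channel_labels[keep],
                 modality = rec$modality), 1.0)$data
  med_env <- col_medians(env)

  n_full <- n %/% ep_len
  rem <- n - n_full * ep_len
  n_ep <- n_full + as.integer(rem >= ep_len / 2)
  if (n_ep < 1) stop("recording shorter than one epoch")
  scored_n <- min(n, n_ep * ep_len)
  ep_id <- (seq_len(scored_n) - 1L) %/% ep_len + 1L

  saturated <- logical(n_ep)
  abs_flag <- rep(FALSE, scored_n)
  for (ch in seq_len(nrow(x))) {
    xi <- x[ch, seq_len(scored_n)]
    at_rail <- xi == rules$rail_uv | xi == -rules$rail_uv
    if (any(at_rail))
      saturated <- saturated |
        epochs_with_runs(at_rail, rules$min_rail_run, ep_len, n_ep)
    abs_flag <- abs_flag | abs(xi) > rules$max_abs_uv
  }
  over_abs <- as.logical(tapply(abs_flag, ep_id, any))
  over_med <- as.logical(tapply(med_env[seq_len(scored_n)] >
                                  rules$median_env_uv, ep_id, any))
  epoch_valid <- !(saturated | over_abs | over_med)
  reasons <- ifelse(saturated, "saturation",
                    ifelse(over_abs, "amplitude",
                           ifelse(over_med, "median", "clean")))

  n_min <- ceiling(n / fs / 60)
  minute_valid <- logical(n_min)
  ep_start <- (seq_len(n_ep) - 1) * rules$epoch_length_s
  ep_stop <- pmin(n / fs, ep_start + rules$epoch_length_s)
  for (m in seq_len(n_min)) {
    m0 <- (m - 1) * 60; m1 <- m * 60
    bad <- !epoch_valid
    contaminated <- sum(pmax(0, pmin(ep_stop[bad], m1) - pmax(ep_start[bad], m0)))
    minute_valid[m] <- contaminated <= rules$max_contaminated_s_per_min
  }

  structure(list(epoch_length_s = rules$epoch_length_s,
                 epoch_valid = epoch_valid, minute_valid = minute_valid,
                 per_channel_excluded = rec$channel_labels[!keep],
                 reasons = reasons),
            class = "epoch_mask")
}
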