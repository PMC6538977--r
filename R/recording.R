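#' Multichannel time-series recording
#'
#' Container for an intracranial LFP or scalp EEG recording: a channels x
#' samples amplitude matrix (microvolts) with sampling rate, channel labels,
#' per-channel region tags and an anesthetic-concentration timeline.
#'
#' @param data numeric matrix, channels x samples (a vector is treated as one
#'   channel). Amplitudes in microvolts.
#' @param sampling_rate_hz positive sampling rate in Hz.
#' @param channel_labels character vector of channel names (10/20 names for
#'   EEG, region+site for LFP). Defaults to `ch1, ch2, ...`.
#' @param regions character vector mapping each channel to a region
#'   (`"PFC"`, `"HP"`, `"LEC"`, `"OB"` or `"scalp"`).
#' @param modality `"LFP"` or `"EEG"`.
#' @param timeline data frame with columns `time_s` and `concentration`
#'   describing the anesthetic concentration as a right-continuous step
#'   function of time. Defaults to concentration 0 throughout.
#' @param units amplitude units, `"uV"`.
#'
#' @return An object of class `ts_recording`.
#' @export
ts_recording <- function(data, sampling_rate_hz, channel_labels = NULL,
                         regions = NULL, modality = c("LFP", "EEG"),
                         timeline = NULL, units = "uV") {
  if (is.vector(data) && is.numeric(data)) data <- matrix(data, nrow = 1)
  if (!is.matrix(data) || !is.numeric(data))
    stop("invalid parameter: `data` must be a numeric channels x samples matrix")
  modality <- match.arg(modality)
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1L ||
      !is.finite(sampling_rate_hz) || sampling_rate_hz <= 0)
    stop("invalid parameter: `sampling_rate_hz` must be a positive number")
  nch <- nrow(data)
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(nch))
  if (length(channel_labels) != nch)
    stop("invalid parameter: one label per channel required")
  if (anyDuplicated(channel_labels))
    stop("invalid parameter: channel labels must be unique")
  if (is.null(regions))
    regions <- rep(if (modality == "EEG") "scalp" else "PFC", nch)
  if (length(regions) != nch)
    stop("invalid parameter: one region per channel required")
  dur <- ncol(data) / sampling_rate_hz
  if (is.null(timeline)) timeline <- data.frame(time_s = 0, concentration = 0)
  if (!is.data.frame(timeline) ||
      !all(c("time_s", "concentration") %in% names(timeline)))
    stop("invalid parameter: `timeline` needs columns time_s and concentration")
  if (any(timeline$time_s < 0) || any(timeline$time_s > dur))
    stop("invalid parameter: timeline times must lie within [0, duration]")
  if (is.unsorted(timeline$time_s)) timeline <- timeline[order(timeline$time_s), ]
  structure(
    list(data = unname(data), sampling_rate_hz = sampling_rate_hz,
         channel_labels = as.character(channel_labels),
         regions = as.character(regions), modality = modality,
         timeline = timeline, units = units),
    class = "ts_recording")
}

#' @export
print.ts_recording <- function(x, ...) {
  cat(sprintf("<ts_recording> %s, %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              x$modality, nrow(x$data), ncol(x$data), x$sampling_rate_hz,
              duration_s(x)))
  cat("  channels:", paste(utils::head(x$channel_labels, 8), collapse = ", "),
      if (length(x$channel_labels) > 8) "..." else "", "\n")
  cat(sprintf("  concentration: %s\n",
              paste(sprintf("%g@%gs", x$timeline$concentration,
                            x$timeline$time_s), collapse = " ")))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec a `ts_recording`.
#' @return duration in seconds.
#' @export
duration_s <- function(rec) ncol(rec$data) / rec$sampling_rate_hz

#' Number of channels of a recording
#' @param rec a `ts_recording`.
#' @return integer channel count.
#' @export
n_channels <- function(rec) nrow(rec$data)

#' Anesthetic concentration at given times
#'
#' Evaluates the recording's concentration timeline (a right-continuous step
#' function) at arbitrary times.
#'
#' @param rec a `ts_recording`.
#' @param times_s numeric vector of times in seconds.
#' @return numeric vector of concentrations.
#' @export
concentration_at <- function(rec, times_s) {
  tl <- rec$timeline
  idx <- findInterval(times_s, tl$time_s)
  idx[idx < 1L] <- 1L
  tl$concentration[idx]
}

#' Per-minute concentration labels
#'
#' Mean concentration over each 1-minute bin, evaluated on a 1 Hz grid, which
#' mirrors the 1 Hz end-tidal samples of anesthesia monitors.
#'
#' @param rec a `ts_recording`.
#' @return numeric vector, one value per full minute of the recording.
#' @export
minute_labels <- function(rec) {
  n_min <- floor(duration_s(rec) / 60)
  if (n_min < 1) return(numeric(0))
  vapply(seq_len(n_min), function(m) {
    mean(concentration_at(rec, seq((m - 1) * 60, m * 60 - 1, by = 1)))
  }, numeric(1))
}

# extract a [from_s, to_s) sample index range, clipped to the trace
sample_range <- function(rec, from_s, to_s) {
  n <- ncol(rec$data)
  i0 <- max(1L, floor(from_s * rec$sampling_rate_hz) + 1L)
  i1 <- min(n, ceiling(to_s * rec$sampling_rate_hz))
  if (i1 < i0) integer(0) else i0:i1
}

#' Restrict a recording to a subset of channels
#'
#' Used to emulate reduced EEG montages (e.g. the four-channel `F4, P4, F3,
#' P3` or two-channel `P4, P3` long-term monitoring sets).
#'
#' @param rec a `ts_recording`.
#' @param subset character vector of channel labels to retain.
#' @return a `ts_recording` with only the requested channels, in the
#'   requested order.
#' @export
select_channels <- function(rec, subset) {
  if (length(subset) < 1) stop("invalid parameter: empty channel subset")
  idx <- match(subset, rec$channel_labels)
  if (anyNA(idx))
    stop("unknown channel label(s): ",
         paste(subset[is.na(idx)], collapse = ", "))
  ts_recording(rec$data[idx, , drop = FALSE], rec$sampling_rate_hz,
               channel_labels = rec$channel_labels[idx],
               regions = rec$regions[idx], modality = rec$modality,
               timeline = rec$timeline, units = rec$units)
}
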