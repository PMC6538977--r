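# Per-1-minute feature tables for mouse LFP and infant EEG sessions, with
# baseline normalization, exactly as fed to the concentration predictor.

# construct a feature_table data frame with bookkeeping attributes
new_feature_table <- function(meta, features, normalization = NULL) {
  stopifnot(nrow(meta) == nrow(features))
  tab <- cbind(meta, features)
  attr(tab, "feature_cols") <- colnames(features)
  attr(tab, "normalization") <- normalization
  class(tab) <- c("feature_table", "data.frame")
  tab
}

#' Feature columns of a feature table
#' @param tab a `feature_table`.
#' @return character vector of feature column names.
#' @export
feature_cols <- function(tab) attr(tab, "feature_cols")

# divide every feature column by its median over baseline rows; a zero
# baseline median leaves the column unscaled (divider 1)
normalize_to_baseline <- function(features, baseline_rows) {
  if (!any(baseline_rows)) stop("empty baseline: normalization undefined")
  med <- apply(features[baseline_rows, , drop = FALSE], 2, stats::median)
  med[!is.finite(med) | med == 0] <- 1
  list(features = sweep(features, 2, med, `/`), constants = med)
}

#' Stack feature tables from several subjects
#' @param tabs list of `feature_table`s with identical feature columns.
#' @return combined `feature_table`.
#' @export
bind_feature_tables <- function(tabs) {
  fc <- feature_cols(tabs[[1]])
  for (t in tabs) stopifnot(identical(feature_cols(t), fc))
  out <- do.call(rbind, lapply(tabs, as.data.frame))
  attr(out, "feature_cols") <- fc
  class(out) <- c("feature_table", "data.frame")
  rownames(out) <- NULL
  out
}

# per-minute features for one LFP region: 10 power bins (1-100 Hz in 10 Hz
# bins), % active, median event length, event count, median/max envelope
region_minute_features <- function(rec, channel, events, prefix) {
  fs <- rec$sampling_rate_hz
  n_min <- floor(duration_s(rec) / 60)
  env <- amplitude_envelope(select_channels(rec, channel), 1.0)$data[1, ]
  bins <- cbind(lo = c(1, seq(10, 90, by = 10)), hi = seq(10, 100, by = 10))
  occ <- occurrence_timecourse(events, 60, duration_s(rec))
  feats <- matrix(NA_real_, n_min, 15)
  colnames(feats) <- paste0(prefix, "_",
                            c(sprintf("pow_%d_%d", bins[, 1], bins[, 2]),
                              "pct_active", "median_event_len", "n_events",
                              "median_amp", "max_amp"))
  for (m in seq_len(n_min)) {
    m0 <- (m - 1) * 60; m1 <- m * 60
    psd <- signal_psd(rec, channel, from_s = m0, to_s = m1)
    pw <- vapply(seq_len(nrow(bins)), function(b)
      band_power(psd, bins[b, ]), numeric(1))
    ev <- events[events$stop_s > m0 & events$start_s < m1, , drop = FALSE]
    if (nrow(ev) > 0) {
      lens <- pmin(ev$stop_s, m1) - pmax(ev$start_s, m0)
      med_len <- stats::median(lens); n_ev <- nrow(ev)
    } else {
      med_len <- 0; n_ev <- 0
    }
    idx <- sample_range(rec, m0, m1)
    feats[m, ] <- c(pw, 100 * occ[m], med_len, n_ev,
                    stats::median(env[idx]), max(env[idx]))
  }
  feats
}

#' Per-minute mouse LFP feature table
#'
#' For each 1-min bin and each region (PFC and HP): LFP power in the
#' 1-100 Hz range in 10 Hz bins (10 features), percentage of time in active
#' periods, median event length, number of oscillations, and median and
#' maximum envelope amplitude - 15 features per region, 30 columns total.
#' Every column is divided by its median over the non-anesthetized baseline
#' minutes.
#'
#' @param rec_pfc,rec_hp single-region [ts_recording()]s (same session).
#' @param events_pfc,events_hp detected `oscillation_events` per region.
#' @param baseline_window `c(from_s, to_s)` of the concentration-0 baseline
#'   (the non-anesthetized first 15 min by default).
#' @param subject_id subject tag carried into the table.
#' @return a `feature_table` with columns `minute`, `concentration`,
#'   `subject_id` and 30 normalized feature columns.
#' @export
mouse_features <- function(rec_pfc, rec_hp, events_pfc, events_hp,
                           baseline_window = c(0, 900),
                           subject_id = "subject1") {
  stopifnot(duration_s(rec_pfc) == duration_s(rec_hp))
  n_min <- floor(duration_s(rec_pfc) / 60)
  if (n_min < 1) stop("recording shorter than one minute")
  f_pfc <- region_minute_features(rec_pfc, rec_pfc$channel_labels[1],
                                  events_pfc, "pfc")
  f_hp <- region_minute_features(rec_hp, rec_hp$channel_labels[1],
                                 events_hp, "hp")
  features <- cbind(f_pfc, f_hp)
  label <- concentration_at(rec_pfc, (seq_len(n_min) - 1) * 60)
  minute_start <- (seq_len(n_min) - 1) * 60
  baseline <- minute_start >= baseline_window[1] &
    minute_start < baseline_window[2] & label == 0
  norm <- normalize_to_baseline(features, baseline)
  meta <- data.frame(minute = seq_len(n_min), concentration = label,
                     subject_id = subject_id)
  new_feature_table(meta, as.data.frame(norm$features), norm$constants)
}

# quartile cut points of a vector (type-7)
amplitude_quartiles <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(q1 = q[1], q2 = q[2], q3 = q[3])
}

# percentage of samples in the four quartile classes [0,q1), [q1,q2),
# [q2,q3), [q3, Inf) - half-open, top class closed
quartile_percentages <- function(x, q) {
  cls <- findInterval(x, c(q$q1, q$q2, q$q3))
  100 * vapply(0:3, function(k) mean(cls == k), numeric(1))
}

#' Per-minute infant EEG feature table
#'
#' For the unfiltered signal and each 5-Hz band (1-50 Hz, 10 bands): the
#' channel-averaged median envelope amplitude plus the percentage of envelope
#' samples falling in each amplitude quartile (quartiles computed once on the
#' entire channel-averaged envelope) - 5 features x 11 signals = 55 columns,
#' one row per artifact-free minute. Each column is divided by its median
#' over the non-anesthetized minutes (or the lowest-concentration minutes
#' when no anesthetic-free minute exists).
#'
#' @param rec an EEG [ts_recording()] (already re-referenced).
#' @param mask an `epoch_mask` from [score_epochs()].
#' @param subject_id,age_months,age_group subject metadata carried into the
#'   table.
#' @param min_valid_minutes inclusion rule: subjects with fewer artifact-free
#'   minutes are excluded (error of class `subject_excluded`).
#' @param normalize divide by the baseline median? (disable to inspect raw
#'   percentages, which sum to 100 per minute and band).
#' @return a `feature_table` with columns `minute`, `concentration`,
#'   `subject_id`, `age_months`, `age_group` and 55 feature columns.
#' @export
infant_features <- function(rec, mask, subject_id = "subject1",
                            age_months = NA_real_, age_group = NA_character_,
                            min_valid_minutes = 20, normalize = TRUE) {
  keep <- setdiff(rec$channel_labels, mask$per_channel_excluded)
  if (length(keep) < 1) stop("all channels excluded")
  rec <- select_channels(rec, keep)
  fs <- rec$sampling_rate_hz
  n_min <- floor(duration_s(rec) / 60)
  valid <- which(mask$minute_valid[seq_len(n_min)])
  if (length(valid) < min_valid_minutes)
    stop(structure(class = c("subject_excluded", "error", "condition"),
                   list(message = sprintf(
                     "subject excluded: %d artifact-free minutes (< %d required)",
                     length(valid), min_valid_minutes), call = NULL)))

  bands <- rbind(c(NA, NA), eeg_5hz_bands())
  signames <- c("broadband", sprintf("band_%d_%d", eeg_5hz_bands()[, "lo"],
                                     eeg_5hz_bands()[, "hi"]))
  feats <- matrix(NA_real_, length(valid), 5 * length(signames))
  colnames(feats) <- as.vector(vapply(signames, function(s)
    paste0(s, "_", c("median_amp", "q1_pct", "q2_pct", "q3_pct", "q4_pct")),
    character(5)))
  for (b in seq_along(signames)) {
    r <- rec
    if (b > 1)
      r$data <- fft_bandpass_rows(rec$data, fs, bands[b, 1], bands[b, 2])
    env <- amplitude_envelope(r, 1.0)$data
    avg <- if (nrow(env) == 1) env[1, ] else colMeans(env)
    q <- amplitude_quartiles(avg)
    for (i in seq_along(valid)) {
      m <- valid[i]
      idx <- sample_range(rec, (m - 1) * 60, m * 60)
      seg <- avg[idx]
      feats[i, (b - 1) * 5 + 1:5] <- c(stats::median(seg),
                                       quartile_percentages(seg, q))
    }
  }

  label <- minute_labels(rec)[valid]
  norm_const <- NULL
  if (normalize) {
    baseline <- label == 0
    if (!any(baseline)) baseline <- label == min(label)
    norm <- normalize_to_baseline(feats, baseline)
    feats <- norm$features
    norm_const <- norm$constants
  }
  meta <- data.frame(minute = valid, concentration = label,
                     subject_id = subject_id, age_months = age_months,
                     age_group = age_group)
  new_feature_table(meta, as.data.frame(feats), norm_const)
}
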