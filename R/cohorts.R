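# End-to-end experiment helpers: simulate a cohort, run the full detection /
# scoring / feature pipeline, and hand back model-ready feature tables.

#' Isoflurane dose-ladder schedule
#'
#' Stepwise 0/1/2/3% schedule, 15 minutes per level (the neonatal mouse
#' protocol).
#'
#' @param levels concentration levels (%).
#' @param block_min minutes per level.
#' @return data frame with `start_s`, `level`.
#' @export
isoflurane_ladder <- function(levels = c(0, 1, 2, 3), block_min = 15) {
  data.frame(start_s = (seq_along(levels) - 1) * block_min * 60,
             level = levels)
}

#' Detect active periods and build the feature table for one mouse session
#'
#' Runs the full single-session pipeline: per-region threshold fit (on the
#' non-anesthetized baseline), active-period detection, and per-minute
#' feature engineering with baseline normalization.
#'
#' @param rec two-channel LFP [ts_recording()] with regions PFC and HP.
#' @param subject_id subject tag.
#' @param baseline_window `c(from_s, to_s)` non-anesthetized window used for
#'   threshold fitting and feature normalization.
#' @return list with `features` (a `feature_table`), `events` (per-region
#'   `oscillation_events`) and `thresholds`.
#' @export
mouse_session_pipeline <- function(rec, subject_id = "subject1",
                                   baseline_window = c(0, 900)) {
  out_ev <- list(); thr <- list()
  for (region in c("PFC", "HP")) {
    ch <- match(region, rec$channel_labels)
    xf <- filter_one_channel(rec, ch, c(1, 100))
    t_r <- fit_detection_threshold(rec, channel = region, filtered = xf)
    out_ev[[region]] <- detect_active_periods(rec, t_r, filtered = xf)
    thr[[region]] <- t_r
  }
  rec_pfc <- select_channels(rec, "PFC")
  rec_hp <- select_channels(rec, "HP")
  feats <- mouse_features(rec_pfc, rec_hp, out_ev$PFC, out_ev$HP,
                          baseline_window = baseline_window,
                          subject_id = subject_id)
  list(features = feats, events = out_ev, thresholds = thr)
}

#' Simulate a neonatal mouse dose-ladder cohort
#'
#' Generates `n_subjects` discontinuous LFP sessions under the isoflurane
#' ladder (15 min per level at 0/1/2/3%, occurrence dose factors
#' 1/0.6/0.3/0.1), runs the detection-to-features pipeline on each and
#' stacks the per-minute feature tables.
#'
#' @param n_subjects number of pups.
#' @param seed master seed (per-subject seeds are derived from it).
#' @param schedule concentration schedule, see [isoflurane_ladder()].
#' @param params_fn function(seed) returning the [neonatal_lfp_params()] of
#'   one subject; its `duration_s` must cover the schedule.
#' @return list with `features` (combined `feature_table`), `sessions`
#'   (recordings + ground truth) and `detections`.
#' @export
simulate_mouse_cohort <- function(n_subjects = 8, seed = 1,
                                  schedule = isoflurane_ladder(),
                                  params_fn = NULL) {
  total_s <- max(schedule$start_s) + 15 * 60
  if (is.null(params_fn))
    params_fn <- function(s) neonatal_lfp_params(duration_s = total_s, seed = s)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max %/% 2, n_subjects)
  tabs <- vector("list", n_subjects)
  sessions <- vector("list", n_subjects)
  detections <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    ses <- gen_neonatal_session(params_fn(seeds[i]), schedule,
                                include_spikes = FALSE)
    pipe <- mouse_session_pipeline(ses$recording,
                                   subject_id = sprintf("pup%02d", i))
    tabs[[i]] <- pipe$features
    sessions[[i]] <- ses
    detections[[i]] <- pipe$events
  }
  list(features = bind_feature_tables(tabs), sessions = sessions,
       detections = detections)
}

#' Score, re-reference and featurize one infant EEG session
#'
#' Epoch scoring (150 uV / 30 uV-median / saturation rules), common average
#' referencing over retained channels, optional montage reduction, and
#' per-minute feature engineering.
#'
#' @param rec an infant EEG [ts_recording()].
#' @param subject_id,age_months,age_group subject metadata.
#' @param channels optional channel subset (reduced montage) applied before
#'   feature computation.
#' @param rules overrides for [score_epochs()].
#' @return list with `features` (a `feature_table`) and `mask` (the
#'   `epoch_mask`).
#' @export
infant_session_pipeline <- function(rec, subject_id = "subject1",
                                    age_months = NA_real_,
                                    age_group = NA_character_,
                                    channels = NULL, rules = list()) {
  mask <- score_epochs(rec, rules)
  car <- common_average_reference(rec, mask$per_channel_excluded)
  if (!is.null(channels)) car <- select_channels(car, channels)
  feats <- infant_features(car, mask, subject_id = subject_id,
                           age_months = age_months, age_group = age_group)
  list(features = feats, mask = mask)
}

#' Simulate an age-stratified infant EEG cohort
#'
#' `n_per_group` subjects per age group (0-2, 2-4, 4-6 months) with the
#' age-dependent amplitude-dose sign (negative for 0-2, positive for 4-6
#' months), scored and featurized per subject.
#'
#' @param n_per_group subjects per age group.
#' @param seed master seed.
#' @param channels optional reduced montage (labels).
#' @param params_fn function(age_group, seed) returning
#'   [infant_eeg_params()] for one subject.
#' @return list with `features` (combined `feature_table`), `sessions`,
#'   `masks` and `discarded_pct` (per-subject % of 5-s epochs rejected).
#' @export
simulate_infant_cohort <- function(n_per_group = 4, seed = 1,
                                   channels = NULL, params_fn = NULL) {
  if (is.null(params_fn))
    params_fn <- function(age_group, s)
      infant_eeg_params(age_group = age_group, seed = s)
  groups <- c("0-2", "2-4", "4-6")
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max %/% 2,
                             3 * n_per_group), nrow = 3)
  tabs <- list(); sessions <- list(); masks <- list(); discarded <- numeric(0)
  for (g in seq_along(groups)) {
    for (i in seq_len(n_per_group)) {
      id <- sprintf("%s_s%02d", gsub("-", "to", groups[g]), i)
      p <- params_fn(groups[g], seeds[g, i])
      ses <- gen_infant_session(p)
      pipe <- infant_session_pipeline(ses$recording, subject_id = id,
                                      age_months = p$age_months,
                                      age_group = groups[g],
                                      channels = channels)
      tabs[[id]] <- pipe$features
      sessions[[id]] <- ses
      masks[[id]] <- pipe$mask
      discarded[id] <- 100 * mean(!pipe$mask$epoch_valid)
    }
  }
  list(features = bind_feature_tables(tabs), sessions = sessions,
       masks = masks, discarded_pct = discarded)
}
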