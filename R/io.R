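# Recording and feature-table I/O: a plain-text recording container (JSON
# metadata + full-precision CSV signal), a minimal EDF reader/writer for EEG
# interchange, and CSV round-tripping of feature tables.

#' Write / read a recording container
#'
#' The container is a directory holding `meta.json` (sampling rate, channel
#' labels, regions, modality, units, concentration timeline) and
#' `signal.csv` (one column per channel, full `%.17g` precision so the
#' round trip is bit-exact for doubles).
#'
#' @param rec a [ts_recording()].
#' @param path container directory (created if missing).
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns the `ts_recording`.
#' @export
write_recording <- function(rec, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(format = "anesdepth-recording", version = 1L,
               sampling_rate_hz = rec$sampling_rate_hz,
               channel_labels = rec$channel_labels, regions = rec$regions,
               modality = rec$modality, units = rec$units,
               n_samples = ncol(rec$data),
               timeline = rec$timeline)
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(file.path(path, "signal.csv"), "w")
  on.exit(close(con))
  writeLines(paste(rec$channel_labels, collapse = ","), con)
  txt <- apply(rec$data, 2, function(col)
    paste(sprintf("%.17g", col), collapse = ","))
  writeLines(txt, con)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta_path <- file.path(path, "meta.json")
  sig_path <- file.path(path, "signal.csv")
  if (!file.exists(meta_path) || !file.exists(sig_path))
    stop("malformed recording container: missing meta.json or signal.csv in ", path)
  meta <- try(jsonlite::read_json(meta_path, simplifyVector = TRUE),
              silent = TRUE)
  if (inherits(meta, "try-error") ||
      !identical(meta$format, "anesdepth-recording"))
    stop("malformed recording container: unreadable or foreign meta.json")
  sig <- utils::read.csv(sig_path, check.names = FALSE)
  if (nrow(sig) != meta$n_samples)
    stop("malformed recording container: signal length does not match metadata")
  meta$timeline <- as.data.frame(lapply(as.data.frame(meta$timeline), as.numeric))
  ts_recording(t(as.matrix(sig)), as.numeric(meta$sampling_rate_hz),
               channel_labels = meta$channel_labels, regions = meta$regions,
               modality = meta$modality,
               timeline = as.data.frame(meta$timeline), units = meta$units)
}

# ---- EDF --------------------------------------------------------------------

pad <- function(x, width) formatC(as.character(x), width = width, flag = "-")

#' Write a recording as EDF
#'
#' Minimal European Data Format writer (one data record per second,
#' 16-bit integers, physical range spanning the observed signal). Intended
#' for interchange and for building EDF test inputs.
#'
#' @param rec a [ts_recording()]; the sampling rate must be an integer.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  fs <- rec$sampling_rate_hz
  if (abs(fs - round(fs)) > 1e-9) stop("invalid parameter: EDF needs an integer sampling rate")
  fs <- as.integer(round(fs))
  nch <- nrow(rec$data)
  n_rec <- ncol(rec$data) %/% fs
  if (n_rec < 1) stop("invalid parameter: trace shorter than one EDF record")
  pmin_ <- min(rec$data, -1); pmax_ <- max(rec$data, 1)
  dmin <- -32768L; dmax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad("0", 8), pad("anesdepth export", 80), pad("", 80),
                pad("01.01.00", 8), pad("00.00.00", 8),
                pad(256L * (1L + nch), 8), pad("", 44), pad(n_rec, 8),
                pad(1, 8), pad(nch, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- list(pad(rec$channel_labels, 16),
                 pad(rep("", nch), 80),
                 pad(rep(rec$units, nch), 8),
                 pad(rep(sprintf("%.6g", pmin_), nch), 8),
                 pad(rep(sprintf("%.6g", pmax_), nch), 8),
                 pad(rep(dmin, nch), 8), pad(rep(dmax, nch), 8),
                 pad(rep("", nch), 80), pad(rep(fs, nch), 8),
                 pad(rep("", nch), 32))
  for (f in fields) writeChar(paste(f, collapse = ""), con, eos = NULL)
  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (ch in seq_len(nch)) {
      dig <- as.integer(round((rec$data[ch, idx] - pmin_) * scale + dmin))
      writeBin(pmax(dmin, pmin(dmax, dig)), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Minimal EDF importer: channel labels, per-channel sampling rate and
#' physical scaling are honored; all channels must share one rate.
#'
#' @param path EDF file.
#' @param modality modality tag of the returned recording.
#' @return a [ts_recording()].
#' @export
read_edf <- function(path, modality = "EEG") {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    s <- readChar(con, n, useBytes = TRUE)
    if (length(s) == 0 || nchar(s, type = "bytes") < n)
      stop("malformed EDF: truncated header")
    trimws(s)
  }
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                      # header length (recomputed below)
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  if (is.na(nch) || nch < 1 || is.na(n_rec) || n_rec < 1)
    stop("malformed EDF: bad channel or record count")
  rdv <- function(w) vapply(seq_len(nch), function(i) rd(w), character(1))
  labels <- rdv(16); rdv(80); units <- rdv(8)
  pmin_ <- as.numeric(rdv(8)); pmax_ <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  rdv(80)
  ns <- as.integer(rdv(8)); rdv(32)
  if (length(unique(ns)) != 1) stop("malformed EDF: mixed sampling rates")
  fs <- ns[1] / rec_dur
  data <- matrix(0, nch, n_rec * ns[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(nch)) {
      dig <- readBin(con, integer(), n = ns[1], size = 2, endian = "little",
                     signed = TRUE)
      if (length(dig) < ns[1]) stop("malformed EDF: truncated data record")
      phys <- (dig - dmin[ch]) * (pmax_[ch] - pmin_[ch]) /
        (dmax[ch] - dmin[ch]) + pmin_[ch]
      data[ch, ((r - 1L) * ns[1] + 1L):(r * ns[1])] <- phys
    }
  }
  ts_recording(data, fs, channel_labels = labels, modality = modality,
               units = if (all(units == units[1]) && nzchar(units[1]))
                 units[1] else "uV")
}

# ---- feature tables ---------------------------------------------------------

#' Write / read a feature table
#'
#' CSV of the rows plus a JSON sidecar (`<path>.json`) holding the column
#' roles and the baseline normalization constants.
#'
#' @param tab a `feature_table`.
#' @param path CSV path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` the `feature_table`.
#' @export
write_feature_table <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  side <- list(feature_cols = feature_cols(tab),
               normalization = as.list(attr(tab, "normalization")))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  side_path <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(side_path))
    stop("malformed feature table: missing CSV or JSON sidecar")
  tab <- utils::read.csv(path, check.names = FALSE)
  if ("age_months" %in% names(tab)) tab$age_months <- as.numeric(tab$age_months)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  attr(tab, "feature_cols") <- side$feature_cols
  attr(tab, "normalization") <- unlist(side$normalization)
  class(tab) <- c("feature_table", "data.frame")
  tab
}
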