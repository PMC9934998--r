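#' Write a recording to disk (CSV signals + JSON sidecar)
#'
#' The signal matrix goes to `<name>_signals.csv` (column `time_ms` plus one
#' column per channel); sampling rate, channel roles, pacing-spike times and
#' the dofetilide start go to `<name>_meta.json`. The same schema is
#' accepted for real exported data.
#'
#' @param recording A `cavb_recording`.
#' @param dir Output directory (created if needed).
#' @param name Basename for the file pair.
#' @return Invisibly, the two file paths.
#' @export
write_recording <- function(recording, dir, name = "recording") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sig_path <- file.path(dir, paste0(name, "_signals.csv"))
  meta_path <- file.path(dir, paste0(name, "_meta.json"))
  n <- nrow(recording$signals)
  dt <- 1000 / recording$fs_hz
  df <- data.table::as.data.table(recording$signals)
  df <- cbind(data.table::data.table(time_ms = (seq_len(n) - 1) * dt), df)
  data.table::fwrite(df, sig_path)
  meta <- list(fs_hz = recording$fs_hz, duration_s = recording$duration_s,
               channels = recording$channels,
               spike_times_ms = recording$spike_times_ms,
               dofetilide_start_s = recording$dofetilide_start_s)
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(c(signals = sig_path, meta = meta_path))
}

#' Read a recording written by [write_recording()]
#'
#' @param dir Directory holding the file pair.
#' @param name Basename used when writing.
#' @return A `cavb_recording`.
#' @export
read_recording <- function(dir, name = "recording") {
  sig_path <- file.path(dir, paste0(name, "_signals.csv"))
  meta_path <- file.path(dir, paste0(name, "_meta.json"))
  if (!file.exists(sig_path) || !file.exists(meta_path))
    stop("recording files not found under ", dir, call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  df <- data.table::fread(sig_path)
  sig <- as.matrix(df[, -1L, with = FALSE])
  structure(list(signals = sig,
                 channels = as.data.frame(meta$channels),
                 fs_hz = meta$fs_hz, duration_s = meta$duration_s,
                 spike_times_ms = as.numeric(meta$spike_times_ms),
                 dofetilide_start_s = meta$dofetilide_start_s %||% NA_real_),
            class = "cavb_recording")
}

#' Write the per-beat ground truth and scripted event log as CSV
#'
#' `<name>_beats.csv` holds the schedule plus true fiducials (one row per
#' beat), `<name>_at.csv` / `<name>_ari.csv` the beat x electrode matrices
#' and `<name>_events.csv` the scripted episodes. All times in ms.
#'
#' @param truth A `cavb_truth` from [synth_ground_truth()].
#' @param dir Output directory.
#' @param name Basename.
#' @return Invisibly, the file paths.
#' @export
write_ground_truth <- function(truth, dir, name = "truth") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(name, c("_beats.csv", "_at.csv",
                                         "_ari.csv", "_events.csv")))
  data.table::fwrite(as.data.frame(truth$beats), paths[1L])
  at <- as.data.frame(truth$at); names(at) <- paste0("EGM", 1:10)
  ari <- as.data.frame(truth$ari); names(ari) <- paste0("EGM", 1:10)
  data.table::fwrite(at, paths[2L])
  data.table::fwrite(ari, paths[3L])
  data.table::fwrite(truth$events, paths[4L])
  invisible(paths)
}

#' Write/read classified arrhythmia events as CSV
#'
#' @param events An event table (see [group_episodes()]).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_events <- function(events, path) {
  data.table::fwrite(as.data.frame(events), path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- as.data.frame(data.table::fread(path))
  class(ev) <- c("arrhythmia_events", "data.frame")
  ev
}

#' Write/read strain curves as long-format CSV (segment, time_ms,
#' strain_pct, wall)
#'
#' @param curves A `strain_curves` set.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_strain <- function(curves, path) {
  seg <- curves$segments
  long <- do.call(rbind, lapply(seq_len(nrow(seg)), function(i) {
    data.frame(segment = seg$segment[i], wall = seg$wall[i],
               time_ms = curves$time_ms, strain_pct = curves$strain[, i])
  }))
  data.table::fwrite(long, path)
  invisible(path)
}

#' @rdname write_strain
#' @export
read_strain <- function(path) {
  long <- as.data.frame(data.table::fread(path))
  segs <- unique(long[, c("segment", "wall")])
  t0 <- long$time_ms[long$segment == segs$segment[1L]]
  m <- vapply(segs$segment, function(s) long$strain_pct[long$segment == s],
              numeric(length(t0)))
  colnames(m) <- segs$segment
  fs <- 1000 / (t0[2L] - t0[1L])
  structure(list(time_ms = t0, strain = m,
                 segments = data.frame(segment = segs$segment,
                                       wall = segs$wall),
                 ref_time_ms = 0, fs_hz = fs),
            class = "strain_curves")
}
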