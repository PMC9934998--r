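#' Group ectopic beats into arrhythmic events
#'
#' A maximal run of consecutive ectopic beats uninterrupted by a non-ectopic
#' beat forms one event; `n_beats` is the run length, so events conserve the
#' total number of ectopic-flagged beats.
#'
#' @param beats A [detect_beats()] annotation table (chronologically
#'   ordered, with `ectopic` flags).
#' @return A data.frame of class `arrhythmia_events`: `event`, `start_ms`,
#'   `end_ms`, `n_beats`, `polymorphism_index` (NA until classified),
#'   `is_tdp` (NA until classified), `defibrillations` (0 until a
#'   defibrillation log is attached).
#' @export
group_episodes <- function(beats) {
  b <- as.data.frame(beats)
  empty <- data.frame(event = integer(), start_ms = numeric(),
                      end_ms = numeric(), n_beats = integer(),
                      polymorphism_index = numeric(), is_tdp = logical(),
                      defibrillations = integer())
  class(empty) <- c("arrhythmia_events", "data.frame")
  if (!nrow(b) || !any(b$ectopic)) return(empty)
  r <- rle(b$ectopic)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  out <- data.frame(
    event = seq_along(runs),
    start_ms = b$beat_time_ms[starts[runs]],
    end_ms = b$beat_time_ms[ends[runs]],
    n_beats = r$lengths[runs],
    polymorphism_index = NA_real_,
    is_tdp = NA,
    defibrillations = 0L)
  attr(out, "beat_runs") <- lapply(runs, function(i) starts[i]:ends[i])
  class(out) <- c("arrhythmia_events", "data.frame")
  out
}

#' Classify events as Torsade de Pointes
#'
#' TdP is a polymorphic ventricular tachycardia of at least 5 beats twisting
#' around the isoelectric line. The polymorphism index combines the fraction
#' of successive within-run beat pairs whose dominant QRS polarity differs
#' with the modulation depth of the QRS amplitude envelope
#' (`index = 0.5 * polarity_flip_fraction + 0.5 * depth`); when amplitudes
#' are unavailable the classification falls back to polarity alone and is
#' flagged degraded. An event is TdP when `n_beats >= 5` and the index
#' reaches `index_threshold`.
#'
#' @param events A [group_episodes()] table.
#' @param beats The annotation table the events were grouped from.
#' @param index_threshold Polymorphism-index threshold (default 0.3,
#'   separating monomorphic runs, index near 0, from rotating runs,
#'   index >= 0.5).
#' @return `events` with `polymorphism_index`, `is_tdp` and `degraded`
#'   filled in.
#' @export
classify_tdp <- function(events, beats, index_threshold = 0.3) {
  b <- as.data.frame(beats)
  runs <- attr(events, "beat_runs")
  if (is.null(runs)) {
    # reconstruct runs by time window membership
    runs <- lapply(seq_len(nrow(events)), function(i)
      which(b$ectopic & b$beat_time_ms >= events$start_ms[i] &
              b$beat_time_ms <= events$end_ms[i]))
  }
  ev <- as.data.frame(events)
  ev$degraded <- logical(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    idx <- runs[[i]]
    pol <- b$polarity_sign[idx]
    amp <- if ("qrs_amp" %in% names(b)) b$qrs_amp[idx] else rep(NA_real_,
                                                                length(idx))
    frac <- if (length(idx) > 1L)
      mean(pol[-1L] != pol[-length(pol)], na.rm = TRUE) else 0
    if (all(is.finite(amp)) && max(amp) > 0) {
      depth <- 1 - min(amp) / max(amp)
      ev$polymorphism_index[i] <- 0.5 * frac + 0.5 * depth
    } else {
      ev$polymorphism_index[i] <- frac
      ev$degraded[i] <- TRUE
    }
    ev$is_tdp[i] <- ev$n_beats[i] >= 5L &&
      ev$polymorphism_index[i] >= index_threshold
  }
  attr(ev, "beat_runs") <- runs
  class(ev) <- c("arrhythmia_events", "data.frame")
  ev
}

#' Attach a defibrillation log to classified events
#'
#' @param events An event table.
#' @param log A data.frame with columns `event` and `defibrillations`.
#' @return The event table with `defibrillations` updated.
#' @export
attach_defibrillations <- function(events, log) {
  if (!all(c("event", "defibrillations") %in% names(log)))
    stop("`log` needs columns event, defibrillations", call. = FALSE)
  m <- match(log$event, events$event)
  if (any(is.na(m))) stop("defibrillation log names unknown events",
                          call. = FALSE)
  events$defibrillations[m] <- as.integer(log$defibrillations)
  events
}

#' Torsade de Pointes inducibility
#'
#' Inducible means at least 3 TdP events starting within 10 minutes after
#' the start of dofetilide infusion. The window is half-open:
#' `(t0, t0 + 600 s]`, membership by event start.
#'
#' @param events A classified event table (`is_tdp` filled in).
#' @param dofetilide_start_s Start of infusion, seconds.
#' @return Logical flag.
#' @export
inducibility <- function(events, dofetilide_start_s) {
  if (!nrow(events)) return(FALSE)
  if (any(is.na(events$is_tdp)))
    stop("events must be classified first (see classify_tdp)", call. = FALSE)
  t0 <- dofetilide_start_s * 1000
  n <- sum(events$is_tdp & events$start_ms > t0 &
             events$start_ms <= t0 + 600000)
  n >= 3L
}

#' Arrhythmia score
#'
#' Every event is scored by the n + 1 rule (n = number of ectopic beats in
#' the event); an event that required 1, 2 or >= 3 defibrillations scores
#' 50, 75 or 100 points instead. The final score is the mean of the three
#' most severe episode scores inside the 10-minute window after the start of
#' dofetilide (mean of fewer if fewer occurred; `zero_score`, default 0,
#' when none did).
#'
#' @param events An event table (classified when inducibility is wanted).
#' @param dofetilide_start_s Start of infusion, seconds.
#' @param zero_score Score assigned when no event falls in the window.
#' @return A list of class `arrhythmia_score`: `episode_scores` (all scored
#'   window events, most severe first), `final_as`, `window_s`, `inducible`
#'   (NA when events are unclassified).
#' @export
arrhythmia_score <- function(events, dofetilide_start_s, zero_score = 0) {
  ev <- as.data.frame(events)
  if (nrow(ev) && (any(ev$n_beats < 1L) || any(ev$defibrillations < 0L)))
    stop("events need n_beats >= 1 and defibrillations >= 0", call. = FALSE)
  t0 <- dofetilide_start_s * 1000
  inw <- ev[ev$start_ms > t0 & ev$start_ms <= t0 + 600000, , drop = FALSE]
  scores <- if (nrow(inw)) {
    s <- inw$n_beats + 1
    s[inw$defibrillations == 1L] <- 50
    s[inw$defibrillations == 2L] <- 75
    s[inw$defibrillations >= 3L] <- 100
    sort(s, decreasing = TRUE)
  } else numeric(0)
  final <- if (length(scores)) mean(scores[seq_len(min(3L, length(scores)))])
           else zero_score
  ind <- if (nrow(ev) == 0L) FALSE else if (any(is.na(ev$is_tdp))) NA else
    inducibility(ev, dofetilide_start_s)
  structure(list(episode_scores = scores, final_as = final,
                 window_s = c(dofetilide_start_s, dofetilide_start_s + 600),
                 inducible = ind),
            class = "arrhythmia_score")
}

#' @export
print.arrhythmia_score <- function(x, ...) {
  cat(sprintf("<arrhythmia_score> AS = %.2f (%d scored episodes), inducible: %s\n",
              x$final_as, length(x$episode_scores),
              ifelse(is.na(x$inducible), "unclassified", x$inducible)))
  invisible(x)
}
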