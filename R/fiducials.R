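#' Detect beats and per-beat ECG fiducials
#'
#' QRS complexes are located on a smoothed absolute-derivative envelope of
#' the ECG channel (slope-based detection separates QRS from T waves by an
#' order of magnitude). Per beat, QRS onset/offset are refined on the raw
#' trace as the samples bounding the suprathreshold deflection, the T peak is
#' the raw maximum in the ST-T window and the T end is found by the tangent
#' method (steepest-descent tangent of the terminal T limb extrapolated to
#' baseline). A beat is flagged ectopic when its QRS morphology correlates
#' poorly with the beat template or it is premature relative to the dominant
#' cycle length.
#'
#' @param recording A `cavb_recording` (or compatible list with `signals`,
#'   `channels`, `fs_hz`, optional `spike_times_ms`).
#' @param min_gap_ms Minimum separation between QRS complexes.
#' @param corr_threshold Template-correlation floor below which a beat is
#'   called ectopic.
#' @param premature_frac A beat is premature when its preceding interval is
#'   below this fraction of the median cycle length.
#' @return A data.frame of class `beat_annotation`: `beat`, `beat_time_ms`
#'   (pacing spike when one matches, else QRS onset), `qrs_on_ms`,
#'   `qrs_off_ms`, `t_peak_ms`, `t_end_ms`, `ectopic`, `polarity_sign`,
#'   `qrs_amp`, `template_corr`.
#' @export
detect_beats <- function(recording, min_gap_ms = 150,
                         corr_threshold = 0.9, premature_frac = 0.8) {
  ecg <- channel(recording, role = "ecg")
  fs <- recording$fs_hz
  dt <- 1000 / fs
  n <- length(ecg)
  if (!any(is.finite(ecg)) || stats::sd(ecg) == 0)
    stop("no detectable beats: ECG channel is flat", call. = FALSE)

  denv <- smooth_ma(abs(cderiv(smooth_ma(ecg, max(3L, round(5 / dt))), dt)),
                    max(3L, round(9 / dt)))
  dmax <- stats::quantile(denv, 0.999, names = FALSE)
  thr <- 0.3 * dmax
  above <- which(denv > thr)
  if (!length(above)) stop("no detectable beats: ECG channel is flat",
                           call. = FALSE)
  # merge suprathreshold runs closer than min_gap into one QRS region
  brk <- which(diff(above) * dt > min_gap_ms)
  starts <- above[c(1L, brk + 1L)]
  ends <- above[c(brk, length(above))]

  noise_est <- stats::mad(ecg[denv <= stats::quantile(denv, 0.5, names = FALSE)])
  tgrid <- (seq_len(n) - 1) * dt

  nb <- length(starts)
  qrs_on <- qrs_off <- t_peak <- t_end <- rep(NA_real_, nb)
  pol <- amp <- rep(NA_real_, nb)
  for (i in seq_len(nb)) {
    lo <- max(1L, starts[i] - round(15 / dt))
    hi <- min(n, ends[i] + round(15 / dt))
    seg <- ecg[lo:hi]
    pk <- max(abs(seg))
    thr_raw <- max(0.02 * pk, 5 * noise_est)
    supra <- which(abs(seg) >= thr_raw)
    if (!length(supra)) next
    on_i <- lo + supra[1L] - 2L            # sample before first suprathreshold
    off_i <- lo + supra[length(supra)]     # sample after last suprathreshold
    qrs_on[i] <- tgrid[max(1L, on_i)]
    qrs_off[i] <- tgrid[min(n, off_i)]
    jmax <- which.max(abs(seg))
    pol[i] <- sign(seg[jmax])
    amp[i] <- pk
  }
  keep <- !is.na(qrs_on)
  qrs_on <- qrs_on[keep]; qrs_off <- qrs_off[keep]
  pol <- pol[keep]; amp <- amp[keep]
  nb <- length(qrs_on)
  if (nb == 0L) stop("no detectable beats: ECG channel is flat", call. = FALSE)
  t_peak <- t_end <- rep(NA_real_, nb)

  # ST-T fiducials per beat
  for (i in seq_len(nb)) {
    w0 <- qrs_off[i] + 10
    w1 <- if (i < nb) qrs_on[i + 1L] - 30 else min(tgrid[n], qrs_off[i] + 600)
    i0 <- floor(w0 / dt) + 1L; i1 <- min(n, floor(w1 / dt) + 1L)
    if (i1 - i0 < round(40 / dt)) next
    win <- ecg[i0:i1]; tw <- tgrid[i0:i1]
    t_amp <- max(win)
    if (t_amp < max(8 * noise_est, 0.02 * amp[i])) next
    jp <- which.max(win)
    t_peak[i] <- tw[jp]
    if (jp >= length(win) - 3L) next
    sm <- smooth_ma(win, max(3L, round(9 / dt)))
    dsm <- cderiv(sm, dt)
    post <- (jp + 1L):length(win)
    jd <- post[which.min(dsm[post])]
    s <- dsm[jd]
    if (is.finite(s) && s < 0) {
      te <- tw[jd] - sm[jd] / s
      t_end[i] <- min(max(te, t_peak[i]), w1)
    }
  }

  # template correlation over a fixed window aligned at QRS onset
  wlen <- round(150 / dt)
  segs <- matrix(0, nb, wlen)
  for (i in seq_len(nb)) {
    i0 <- floor(qrs_on[i] / dt) + 1L
    idx <- i0:min(n, i0 + wlen - 1L)
    segs[i, seq_along(idx)] <- ecg[idx]
  }
  templ <- apply(segs, 2L, stats::median)
  tc <- if (stats::sd(templ) == 0) rep(1, nb) else
    apply(segs, 1L, function(s) {
      if (stats::sd(s) == 0) 0 else stats::cor(s, templ)
    })

  rr_prev <- c(NA, diff(qrs_on))
  med_rr <- stats::median(rr_prev, na.rm = TRUE)
  premature <- !is.na(rr_prev) & rr_prev < premature_frac * med_rr
  ectopic <- (tc < corr_threshold) | premature

  beat_time <- qrs_on
  spikes <- recording$spike_times_ms
  if (!is.null(spikes) && length(spikes)) {
    for (i in seq_len(nb)) {
      d <- abs(spikes - qrs_on[i])
      if (min(d) <= 30) beat_time[i] <- spikes[which.min(d)]
    }
  }

  out <- data.frame(beat = seq_len(nb), beat_time_ms = beat_time,
                    qrs_on_ms = qrs_on, qrs_off_ms = qrs_off,
                    t_peak_ms = t_peak, t_end_ms = t_end,
                    ectopic = ectopic, polarity_sign = pol, qrs_amp = amp,
                    template_corr = tc)
  attr(out, "fs_hz") <- fs
  class(out) <- c("beat_annotation", "data.frame")
  out
}

#' Van de Water heart-rate correction of the QT interval
#'
#' `QTc = QT - 0.087 * (RR - 1000)` (ms), the standard correction for
#' anaesthetized dogs; no correction at RR = 1000 ms.
#'
#' @param qt_ms,rr_ms QT and RR intervals in ms (vectorized).
#' @return QTc in ms.
#' @export
qtc_van_der_water <- function(qt_ms, rr_ms) {
  if (any(qt_ms <= 0) || any(rr_ms <= 0))
    stop("`qt_ms` and `rr_ms` must be positive", call. = FALSE)
  qt_ms - 0.087 * (rr_ms - 1000)
}

#' Rate-corrected JT interval
#'
#' The ventricular repolarization interval free of depolarization time,
#' `JTc = QTc - QRS`.
#'
#' @param qtc_ms,qrs_ms Corrected QT and QRS duration in ms (vectorized).
#' @return JTc in ms.
#' @export
jtc <- function(qtc_ms, qrs_ms) {
  if (any(qtc_ms <= 0) || any(qrs_ms <= 0))
    stop("inputs must be positive", call. = FALSE)
  qtc_ms - qrs_ms
}

#' Averaged surface-ECG intervals over consecutive clean beats
#'
#' Each interval (PP, RR, QRS, QT, Tp-e) is the arithmetic mean over
#' `n_beats` consecutive non-ectopic beats; the beats are taken from the last
#' artefact-free stretch in the analysis window, mirroring measurement
#' "before the first ectopic beat". QTc uses the Van de Water formula on the
#' averaged QT/RR and JTc = QTc - QRS. With no atrial channel PP is reported
#' equal to RR (the drive interval).
#'
#' @param recording A `cavb_recording` (unused beyond validation; intervals
#'   come from the annotations). May be `NULL`.
#' @param beats A [detect_beats()] annotation table.
#' @param n_beats Number of consecutive beats to average (default 5).
#' @param window Optional `c(start_ms, end_ms)` analysis window; only beats
#'   with `beat_time_ms` inside it are considered.
#' @param phase Label used in error messages (e.g. "baseline").
#' @return One-row data.frame: `PP`, `RR`, `QRS`, `QT`, `QTc`, `JTc`,
#'   `TpTe` (ms), plus `n_beats`, `win_start_ms`, `win_end_ms`.
#' @export
measure_intervals <- function(recording = NULL, beats, n_beats = 5,
                              window = NULL, phase = "analysis") {
  b <- as.data.frame(beats)
  if (!is.null(window))
    b <- b[b$beat_time_ms >= window[1L] & b$beat_time_ms < window[2L], ,
           drop = FALSE]
  clean <- !b$ectopic & is.finite(b$t_end_ms) & is.finite(b$t_peak_ms)
  # last run of >= n_beats + 1 consecutive clean beats (the +1 supplies the
  # preceding interval for RR)
  r <- rle(clean)
  ends <- cumsum(r$lengths)
  ok <- which(r$values & r$lengths >= n_beats + 1L)
  if (!length(ok))
    stop(sprintf("fewer than %d consecutive clean beats in the %s window",
                 n_beats + 1L, phase), call. = FALSE)
  run_end <- ends[ok[length(ok)]]
  idx <- (run_end - n_beats):run_end          # n_beats + 1 beats
  sel <- b[idx, , drop = FALSE]
  rr <- diff(sel$beat_time_ms)                 # n_beats intervals
  meas <- sel[-1L, , drop = FALSE]             # the n_beats measured beats
  qrs <- meas$qrs_off_ms - meas$qrs_on_ms
  qt <- meas$t_end_ms - meas$qrs_on_ms
  tpe <- meas$t_end_ms - meas$t_peak_ms
  RR <- mean(rr); QRS <- mean(qrs); QT <- mean(qt)
  QTc <- qtc_van_der_water(QT, RR)
  data.frame(PP = RR, RR = RR, QRS = QRS, QT = QT, QTc = QTc,
             JTc = jtc(QTc, QRS), TpTe = mean(tpe), n_beats = n_beats,
             win_start_ms = sel$beat_time_ms[1L],
             win_end_ms = sel$beat_time_ms[nrow(sel)])
}

#' RV activation time and MAP duration at 80% repolarization
#'
#' The RV activation time is the interval from the pacing spike to the
#' steepest MAP upstroke (maximum dV/dt); the MAP duration (MAPD80) runs from
#' the upstroke to the first crossing of `baseline + 0.2 * amplitude` during
#' repolarization, where the baseline is the median diastolic level before
#' the upstroke and the amplitude is the plateau peak minus baseline. The
#' fractional threshold makes MAPD80 invariant to affine amplitude scaling.
#'
#' @param map A `cavb_recording` (its MAP channel is used) or a numeric
#'   signal vector.
#' @param spike_ms Pacing-spike (or beat-onset) time, ms.
#' @param end_ms End of the beat window (default `spike_ms + 600`).
#' @param fs_hz Sampling rate; taken from the recording when one is given.
#' @param slope_frac Minimum upstroke slope, as a fraction of the beat's
#'   amplitude per ms; below it the beat yields missing values.
#' @return Named numeric vector `c(rv_at_ms, mapd_ms)` (NA when no upstroke
#'   qualifies).
#' @export
mapd80 <- function(map, spike_ms, end_ms = spike_ms + 600, fs_hz = 1000,
                   slope_frac = 0.02) {
  if (inherits(map, "cavb_recording")) {
    fs_hz <- map$fs_hz
    map <- channel(map, role = "map")
  }
  dt <- 1000 / fs_hz
  n <- length(map)
  i_sp <- floor(spike_ms / dt) + 1L
  i_end <- min(n, floor(end_ms / dt) + 1L)
  if (i_sp < 1L || i_sp >= i_end)
    return(c(rv_at_ms = NA_real_, mapd_ms = NA_real_))
  base_lo <- max(1L, i_sp - round(100 / dt))
  baseline <- stats::median(map[base_lo:i_sp])
  win <- map[i_sp:i_end]
  tw <- (seq(i_sp, i_end) - 1) * dt
  amp <- max(win) - baseline
  if (!is.finite(amp) || amp <= 0)
    return(c(rv_at_ms = NA_real_, mapd_ms = NA_real_))
  dv <- cderiv(win, dt)   # raw derivative: the steep upstroke dominates noise
  up_search <- seq_len(min(length(win), round(150 / dt)))
  j <- up_search[which.max(dv[up_search])]
  if (dv[j] < slope_frac * amp)
    return(c(rv_at_ms = NA_real_, mapd_ms = NA_real_))
  up <- refine_peak(tw, dv, j)
  t_up <- up[1L]
  level <- baseline + 0.2 * amp
  jpk <- which.max(win)
  post <- win[jpk:length(win)]
  below <- which(post <= level)
  if (!length(below))
    return(c(rv_at_ms = t_up - spike_ms, mapd_ms = NA_real_))
  jc <- jpk + below[1L] - 1L
  t80 <- interp_cross(tw, win, jc - 1L, level)
  c(rv_at_ms = t_up - spike_ms, mapd_ms = t80 - t_up)
}

#' Local activation time from a unipolar electrogram
#'
#' The activation time is the interval from the pacing spike to the minimum
#' dV/dt of the electrogram within the QRS window. The derivative is
#' estimated by centered differences on a 5 ms moving-average-smoothed trace;
#' exact ties go to the earliest time.
#'
#' @param egm A `cavb_recording` (give `electrode`) or numeric signal vector.
#' @param spike_ms Pacing-spike time, ms.
#' @param electrode Electrode number 1-10 when `egm` is a recording.
#' @param window_ms QRS window length after the spike (default 160 ms).
#' @param fs_hz Sampling rate when `egm` is a plain vector.
#' @return Activation time in ms after the spike (NA for an empty window).
#' @export
egm_at <- function(egm, spike_ms, electrode = NULL, window_ms = 160,
                   fs_hz = 1000) {
  if (inherits(egm, "cavb_recording")) {
    fs_hz <- egm$fs_hz
    egm <- channel(egm, electrode = electrode)
  }
  dt <- 1000 / fs_hz
  n <- length(egm)
  i0 <- floor(spike_ms / dt) + 1L
  i1 <- min(n, floor((spike_ms + window_ms) / dt) + 1L)
  if (i0 < 1L || i1 - i0 < 3L) return(NA_real_)
  win <- egm[i0:i1]
  tw <- (seq(i0, i1) - 1) * dt
  dv <- cderiv(smooth_ma(win, max(3L, round(5 / dt))), dt)
  j <- which.min(dv)          # earliest index on exact ties
  refine_peak(tw, dv, j)[1L] - spike_ms
}

#' Activation-recovery interval from a unipolar electrogram
#'
#' The repolarization fiducial is the steepest T-wave deflection: the time of
#' maximum |dV/dt| within the T-wave window (for upright step-like T waves
#' this is the classic maximum-dV/dt point, and taking the absolute slope
#' makes the fiducial invariant under polarity inversion of the T wave).
#' ARI = fiducial time - activation time.
#'
#' @param egm A `cavb_recording` (give `electrode`) or numeric signal vector.
#' @param at_ms Absolute activation time of this beat (ms).
#' @param window `c(start_ms, end_ms)` T-wave search window.
#' @param electrode Electrode number 1-10 when `egm` is a recording.
#' @param fs_hz Sampling rate when `egm` is a plain vector.
#' @param slope_min Minimum |dV/dt| (signal units per ms); a flat T window
#'   yields a missing value.
#' @return ARI in ms, or NA when the window is flat/empty.
#' @export
egm_ari <- function(egm, at_ms, window, electrode = NULL, fs_hz = 1000,
                    slope_min = 0.02) {
  if (inherits(egm, "cavb_recording")) {
    fs_hz <- egm$fs_hz
    egm <- channel(egm, electrode = electrode)
  }
  dt <- 1000 / fs_hz
  n <- length(egm)
  i0 <- max(1L, floor(window[1L] / dt) + 1L)
  i1 <- min(n, floor(window[2L] / dt) + 1L)
  if (i1 - i0 < 3L) return(NA_real_)
  win <- egm[i0:i1]
  tw <- (seq(i0, i1) - 1) * dt
  dv <- cderiv(smooth_ma(win, max(3L, round(5 / dt))), dt)
  adv <- abs(dv)
  j <- which.max(adv)
  if (adv[j] < slope_min) return(NA_real_)
  refine_peak(tw, adv, j)[1L] - at_ms
}

#' Per-beat RV MAP measurements over a window
#'
#' @param recording A `cavb_recording` with a MAP channel.
#' @param beats A [detect_beats()] table.
#' @param window Optional `c(start_ms, end_ms)`.
#' @return data.frame `beat`, `time_ms`, `rv_at_ms`, `mapd_ms` for the
#'   non-ectopic beats in the window.
#' @export
map_series <- function(recording, beats, window = NULL) {
  b <- as.data.frame(beats)
  sel <- which(!b$ectopic)
  if (!is.null(window))
    sel <- sel[b$beat_time_ms[sel] >= window[1L] &
                 b$beat_time_ms[sel] < window[2L]]
  map <- channel(recording, role = "map")
  fs <- recording$fs_hz
  res <- t(vapply(sel, function(i) {
    nxt <- if (i < nrow(b)) b$beat_time_ms[i + 1L] - 30 else
      b$beat_time_ms[i] + 600
    mapd80(map, b$beat_time_ms[i], end_ms = nxt, fs_hz = fs)
  }, c(rv_at_ms = 0, mapd_ms = 0)))
  data.frame(beat = b$beat[sel], time_ms = b$beat_time_ms[sel],
             rv_at_ms = res[, 1L], mapd_ms = res[, 2L])
}

#' Per-beat activation times and ARIs for all LV electrodes
#'
#' Electrodes 1 and 10 (most distal and proximal, excluded from aggregates
#' for P-wave interference in the source protocol) are still measured here;
#' exclusion happens at aggregation (see [lv_aggregates()]).
#'
#' @param recording A `cavb_recording` with EGM channels.
#' @param beats A [detect_beats()] table.
#' @param window Optional `c(start_ms, end_ms)`.
#' @param qrs_window_ms AT search window after the spike.
#' @return List with `time_ms`, `beat`, and beat x electrode matrices `at`
#'   and `ari`.
#' @export
egm_series <- function(recording, beats, window = NULL, qrs_window_ms = 160) {
  b <- as.data.frame(beats)
  sel <- which(!b$ectopic)
  if (!is.null(window))
    sel <- sel[b$beat_time_ms[sel] >= window[1L] &
                 b$beat_time_ms[sel] < window[2L]]
  fs <- recording$fs_hz
  at <- ari <- matrix(NA_real_, length(sel), 10L)
  for (k in 1:10) {
    eg <- channel(recording, electrode = k)
    for (m in seq_along(sel)) {
      i <- sel[m]
      sp <- b$beat_time_ms[i]
      nxt <- if (i < nrow(b)) b$beat_time_ms[i + 1L] else sp + 900
      a <- egm_at(eg, sp, window_ms = qrs_window_ms, fs_hz = fs)
      at[m, k] <- a
      if (is.finite(a))
        ari[m, k] <- egm_ari(eg, sp + a,
                             window = c(sp + qrs_window_ms, nxt - 50),
                             fs_hz = fs)
    }
  }
  list(beat = b$beat[sel], time_ms = b$beat_time_ms[sel], at = at, ari = ari)
}

#' LV aggregates from per-electrode series
#'
#' Mean AT and ARI across the retained electrodes (2-9 by default; 1 and 10
#' are excluded). Means are over available (non-missing) electrodes; the
#' count used is reported.
#'
#' @param series An [egm_series()] result.
#' @param exclude Electrode numbers to exclude (default `c(1, 10)`).
#' @return List: `lv_at_ms`, `lv_ari_ms` (scalars: electrode means of
#'   per-beat means), `ari_mean_series` (per-beat mean-ARI series, for STV),
#'   `at_by_electrode`, `ari_by_electrode`, `electrodes`, `n_electrodes`.
#' @export
lv_aggregates <- function(series, exclude = c(1L, 10L)) {
  keep <- setdiff(1:10, exclude)
  at_e <- colMeans(series$at[, keep, drop = FALSE], na.rm = TRUE)
  ari_e <- colMeans(series$ari[, keep, drop = FALSE], na.rm = TRUE)
  ok <- is.finite(at_e) & is.finite(ari_e)
  list(lv_at_ms = mean(at_e[ok]), lv_ari_ms = mean(ari_e[ok]),
       ari_mean_series = rowMeans(series$ari[, keep, drop = FALSE],
                                  na.rm = TRUE),
       at_by_electrode = at_e, ari_by_electrode = ari_e,
       electrodes = keep[ok], n_electrodes = sum(ok))
}
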