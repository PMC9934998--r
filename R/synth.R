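#' Specify one ectopic episode for the synthetic generator
#'
#' An episode is a run of consecutive ectopic (ventricular) beats that
#' interrupts the regular paced/idioventricular rhythm. Polymorphic runs
#' rotate QRS polarity and amplitude beat-to-beat (the surrogate for the
#' "twisting" morphology of Torsade de Pointes); monomorphic runs keep a
#' fixed ectopic morphology.
#'
#' @param onset_s Episode onset, seconds from the start of the recording.
#' @param n_beats Number of ectopic beats in the run (>= 1).
#' @param polymorphic Logical; rotate QRS polarity/amplitude within the run.
#' @param cycle_ms Intra-run cycle length in ms.
#' @param defibrillations Number of defibrillations the episode required
#'   (0 for self-terminating runs).
#' @return A list of class `episode_spec`.
#' @export
episode_spec <- function(onset_s, n_beats, polymorphic = TRUE,
                         cycle_ms = 350, defibrillations = 0L) {
  stop_if_not_scalar_num(onset_s, "onset_s")
  stop_if_not_scalar_num(n_beats, "n_beats", positive = TRUE)
  stop_if_not_scalar_num(cycle_ms, "cycle_ms", positive = TRUE)
  if (n_beats < 1) stop("`n_beats` must be >= 1", call. = FALSE)
  if (defibrillations < 0) stop("`defibrillations` must be >= 0", call. = FALSE)
  structure(list(onset_s = onset_s, n_beats = as.integer(n_beats),
                 polymorphic = isTRUE(polymorphic), cycle_ms = cycle_ms,
                 defibrillations = as.integer(defibrillations)),
            class = "episode_spec")
}

#' Default left-ventricular electrode activation delays
#'
#' Ten activation delays (ms after the pacing spike) for the duo-decapolar
#' catheter electrodes, spanning an apex-to-base activation sequence.
#' @return Numeric vector of length 10.
#' @export
default_electrode_ats <- function() seq(16, 70, by = 6)

#' Parameters for the synthetic multi-channel recording generator
#'
#' Defines the beat schedule, the per-electrode activation delays, the
#' programmed activation-repolarization coupling (AT-ARI slope), the
#' beat-to-beat repolarization noise that downstream short-term variability
#' (STV) estimates, and an optional dofetilide challenge whose
#' activation-rank-weighted ARI prolongation ramps in over 5 minutes.
#'
#' All times are in ms from the start of the recording; the sampling grid is
#' `fs_hz` (default 1000 Hz, i.e. 1 ms resolution).
#'
#' @param rate_bpm Regular (paced or idioventricular) rate, beats/min.
#' @param duration_s Recording duration in seconds.
#' @param fs_hz Sampling rate in Hz.
#' @param electrode_ats Ten activation delays (ms) for EGM electrodes 1-10.
#' @param ari_base_ms Baseline activation-recovery interval (ms).
#' @param at_ari_slope Programmed slope of true ARI on AT across electrodes
#'   (dimensionless).
#' @param stv_sigma_ms SD of the iid per-beat Gaussian repolarization
#'   perturbation shared across LV electrodes (ms).
#' @param rv_stv_sigma_ms SD of the per-beat perturbation of RV MAP duration.
#' @param rv_at_ms RV activation time: pacing spike to steepest MAP upstroke.
#' @param mapd_base_ms Baseline RV MAP duration at 80% repolarization (ms).
#' @param ecg List with the programmed surface-ECG fiducials per beat:
#'   `qrs_ms`, `qt_ms` and `tpe_ms` (T-peak to T-end).
#' @param noise_sd Additive white-noise SD, as a fraction of each channel's
#'   nominal amplitude (0 = noise-free).
#' @param dofetilide `NULL`, or a list with `start_s`, `ari_gain_ms` and
#'   `gradient_weight`: after `start_s` every ARI is prolonged by
#'   `ari_gain_ms * (1 + gradient_weight * earliness)` where earliness is the
#'   rank-normalized earliness of the electrode's activation (earliest
#'   activated region = 1), ramped linearly over 5 min and then held. The MAP
#'   duration is prolonged by `ari_gain_ms` (no spatial gradient).
#' @param ectopy List of [episode_spec()] objects.
#' @param seed Integer seed; identical parameters give bit-identical output.
#' @return A list of class `synth_params`.
#' @export
synth_params <- function(rate_bpm = 60, duration_s = 120, fs_hz = 1000,
                         electrode_ats = default_electrode_ats(),
                         ari_base_ms = 250, at_ari_slope = -0.4,
                         stv_sigma_ms = 1.0, rv_stv_sigma_ms = stv_sigma_ms,
                         rv_at_ms = 25, mapd_base_ms = 210,
                         ecg = list(qrs_ms = 100, qt_ms = 340, tpe_ms = 50),
                         noise_sd = 0.02, dofetilide = NULL, ectopy = list(),
                         seed = 1L) {
  stop_if_not_scalar_num(rate_bpm, "rate_bpm", positive = TRUE)
  stop_if_not_scalar_num(duration_s, "duration_s", positive = TRUE)
  stop_if_not_scalar_num(fs_hz, "fs_hz", positive = TRUE)
  stop_if_not_scalar_num(stv_sigma_ms, "stv_sigma_ms")
  if (stv_sigma_ms < 0) stop("`stv_sigma_ms` must be >= 0", call. = FALSE)
  if (rv_stv_sigma_ms < 0) stop("`rv_stv_sigma_ms` must be >= 0", call. = FALSE)
  if (length(electrode_ats) != 10L || !all(is.finite(electrode_ats)))
    stop("`electrode_ats` must hold exactly 10 finite activation delays",
         call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  ecg <- utils::modifyList(list(qrs_ms = 100, qt_ms = 340, tpe_ms = 50), ecg)
  if (!is.null(dofetilide)) {
    dofetilide <- utils::modifyList(
      list(start_s = NA_real_, ari_gain_ms = 150, gradient_weight = 0.5),
      dofetilide)
    stop_if_not_scalar_num(dofetilide$start_s, "dofetilide$start_s")
  }
  if (inherits(ectopy, "episode_spec")) ectopy <- list(ectopy)
  ok <- vapply(ectopy, inherits, logical(1), "episode_spec")
  if (!all(ok)) stop("`ectopy` must be a list of episode_spec objects",
                     call. = FALSE)
  structure(list(rate_bpm = rate_bpm, duration_s = duration_s, fs_hz = fs_hz,
                 electrode_ats = as.numeric(electrode_ats),
                 ari_base_ms = ari_base_ms, at_ari_slope = at_ari_slope,
                 stv_sigma_ms = stv_sigma_ms,
                 rv_stv_sigma_ms = rv_stv_sigma_ms,
                 rv_at_ms = rv_at_ms, mapd_base_ms = mapd_base_ms,
                 ecg = ecg, noise_sd = noise_sd, dofetilide = dofetilide,
                 ectopy = ectopy, seed = as.integer(seed)),
            class = "synth_params")
}

# Amplitude rotation applied to ectopic QRS complexes within a polymorphic
# run (period-4 polarity/amplitude rotation, the TdP "twisting" surrogate).
poly_rotation <- function(j) c(1, -0.7, 0.85, -1)[((j - 1L) %% 4L) + 1L]

# Biphasic QRS primitive on u in [0, 1]: dominant first lobe, smaller
# terminal lobe (asymmetry gives every beat a well-defined dominant
# polarity); compact support with v(0) = v(1) = 0.
qrs_shape <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  sin(2 * pi * u) * ifelse(u <= 0.5, 1, 0.45)
}

#' Build the beat schedule for a synthetic recording
#'
#' Regular beats are placed at `60000 / rate_bpm` ms spacing (first beat at
#' half a cycle); each ectopic episode suspends the regular rhythm for its
#' duration plus one compensatory cycle. The schedule is deterministic.
#'
#' @param params A [synth_params()] object.
#' @return A data.frame of class `beat_schedule` with one row per beat:
#'   `beat`, `time_ms`, `ectopic`, `episode` (NA for regular beats) and
#'   `amp_factor` (QRS polarity/amplitude factor).
#' @export
make_beat_schedule <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  cl <- 60000 / params$rate_bpm
  dur_ms <- params$duration_s * 1000
  tail_ms <- params$ecg$qt_ms + 150
  if (dur_ms < cl / 2 + tail_ms)
    stop(sprintf("recording duration (%.1f s) too short for one beat at %.0f bpm",
                 params$duration_s, params$rate_bpm), call. = FALSE)
  reg <- seq(cl / 2, dur_ms - tail_ms, by = cl)

  eps <- params$ectopy
  if (length(eps)) {
    onset <- vapply(eps, `[[`, numeric(1), "onset_s") * 1000
    o <- order(onset)
    eps <- eps[o]; onset <- onset[o]
    end <- onset + vapply(eps, function(e) (e$n_beats - 1L) * e$cycle_ms,
                          numeric(1))
    if (any(onset < 0) || any(end > dur_ms))
      stop("ectopic episode extends outside the recording", call. = FALSE)
    if (length(eps) > 1L) {
      ov <- which(onset[-1L] <= end[-length(end)] + 0.5 *
                    vapply(eps[-length(eps)], `[[`, numeric(1), "cycle_ms"))
      if (length(ov))
        stop(sprintf("ectopic episodes %d and %d overlap", ov[1L], ov[1L] + 1L),
             call. = FALSE)
    }
  }

  rows <- data.frame(time_ms = reg, ectopic = FALSE, episode = NA_integer_,
                     amp_factor = 1)
  for (i in seq_along(eps)) {
    e <- eps[[i]]
    t0 <- e$onset_s * 1000
    times <- t0 + (seq_len(e$n_beats) - 1L) * e$cycle_ms
    amp <- if (e$polymorphic) vapply(seq_len(e$n_beats), poly_rotation,
                                     numeric(1)) else rep(1, e$n_beats)
    # suspend the regular rhythm during the run plus one compensatory cycle
    keep <- rows$ectopic | rows$time_ms < t0 - 0.25 * 60000 / params$rate_bpm |
      rows$time_ms > max(times) + 60000 / params$rate_bpm
    rows <- rows[keep, , drop = FALSE]
    rows <- rbind(rows, data.frame(time_ms = times, ectopic = TRUE,
                                   episode = i, amp_factor = amp))
  }
  rows <- rows[order(rows$time_ms), , drop = FALSE]
  rows$beat <- seq_len(nrow(rows))
  rows <- rows[, c("beat", "time_ms", "ectopic", "episode", "amp_factor")]
  rownames(rows) <- NULL
  class(rows) <- c("beat_schedule", "data.frame")
  rows
}

# Rank-normalized earliness per electrode: earliest activated -> 1,
# latest -> 0. Linear in AT when delays are equally spaced.
earliness <- function(ats) {
  rk <- rank(ats, ties.method = "average")
  k <- length(ats)
  if (k == 1L) return(1)
  (k - rk) / (k - 1)
}

# Dofetilide ramp factor at time t (ms): linear from start over 5 min, then
# held at 1 (measurements are taken 5 min after start of infusion).
dof_ramp <- function(t_ms, dof) {
  if (is.null(dof)) return(rep(0, length(t_ms)))
  pmin(pmax((t_ms - dof$start_s * 1000) / 300000, 0), 1)
}

#' Generate the per-beat ground truth for a parameter set
#'
#' Cheap (no waveform synthesis): the true activation times, ARIs, MAP
#' durations, ECG fiducials and the scripted event list implied by
#' [synth_params()]. [synth_recording()] uses the identical RNG stream, so
#' the truth returned here matches the truth embedded in its signals.
#'
#' @param params A [synth_params()] object.
#' @param schedule Optionally a precomputed [make_beat_schedule()] result.
#' @return A list of class `cavb_truth`: `beats` (schedule plus true ECG
#'   fiducials, RV AT and MAPD per beat), `at` and `ari` (beat x electrode
#'   matrices, NA rows for ectopic beats), `events` (scripted episode table)
#'   and `params`.
#' @export
synth_ground_truth <- function(params, schedule = make_beat_schedule(params)) {
  with_seed(params$seed, truth_core(params, schedule))
}

truth_core <- function(params, schedule) {
  b <- nrow(schedule)
  ats <- params$electrode_ats
  e_k <- earliness(ats)
  ramp <- dof_ramp(schedule$time_ms, params$dofetilide)
  eps_lv <- stats::rnorm(b, 0, params$stv_sigma_ms)
  eps_rv <- stats::rnorm(b, 0, params$rv_stv_sigma_ms)

  at <- matrix(rep(ats, each = b), nrow = b)
  ari <- matrix(NA_real_, b, 10L)
  base <- params$ari_base_ms + params$at_ari_slope * (ats - mean(ats))
  gain <- if (is.null(params$dofetilide)) 0 else params$dofetilide$ari_gain_ms
  gw <- if (is.null(params$dofetilide)) 0 else params$dofetilide$gradient_weight
  for (k in 1:10) ari[, k] <- base[k] + eps_lv + ramp * gain * (1 + gw * e_k[k])
  mapd <- params$mapd_base_ms + eps_rv + ramp * gain
  at[schedule$ectopic, ] <- NA_real_
  ari[schedule$ectopic, ] <- NA_real_
  mapd[schedule$ectopic] <- NA_real_

  beats <- schedule
  ecg <- params$ecg
  beats$qrs_on_ms <- beats$time_ms
  beats$qrs_off_ms <- beats$time_ms + ifelse(beats$ectopic, 140, ecg$qrs_ms)
  beats$t_end_ms <- ifelse(beats$ectopic, NA_real_, beats$time_ms + ecg$qt_ms)
  beats$t_peak_ms <- beats$t_end_ms - ecg$tpe_ms
  beats$rv_at_ms <- ifelse(beats$ectopic, NA_real_, params$rv_at_ms)
  beats$mapd_ms <- mapd
  beats$lv_ari_mean_ms <- rowMeans(ari[, 2:9, drop = FALSE])

  events <- if (length(params$ectopy)) {
    do.call(rbind, lapply(seq_along(params$ectopy), function(i) {
      e <- params$ectopy[[i]]
      idx <- which(schedule$episode == i)
      data.frame(episode = i, onset_ms = schedule$time_ms[idx[1L]],
                 end_ms = schedule$time_ms[idx[length(idx)]],
                 n_beats = e$n_beats, polymorphic = e$polymorphic,
                 cycle_ms = e$cycle_ms, defibrillations = e$defibrillations)
    }))
  } else {
    data.frame(episode = integer(), onset_ms = numeric(), end_ms = numeric(),
               n_beats = integer(), polymorphic = logical(),
               cycle_ms = numeric(), defibrillations = integer())
  }

  structure(list(beats = beats, at = at, ari = ari, events = events,
                 params = params),
            class = "cavb_truth")
}

# Channel amplitude constants (arbitrary units ~ mV).
.amp <- list(ecg_qrs = 1.0, ecg_t = 0.30, egm = 1.0, map = 30.0)

#' Synthesize a multi-channel electrophysiology recording with ground truth
#'
#' Produces a surface-ECG lead, an RV monophasic action potential channel and
#' ten LV unipolar electrograms on a common sampling grid. Waveform shapes
#' are simple analytic primitives; the contract is the fiducial placement:
#' each electrode's steepest negative EGM deflection falls at
#' `beat + electrode_ats[k]`, the steepest positive T-deflection at
#' `AT + true ARI`, the steepest MAP upstroke at `beat + rv_at_ms` and the
#' 80%-repolarization crossing at `upstroke + true MAPD`.
#'
#' @param params A [synth_params()] object.
#' @return A list with elements `recording` (class `cavb_recording`:
#'   `signals` matrix with one column per channel, `channels` table, `fs_hz`,
#'   `duration_s`, `spike_times_ms`, `dofetilide_start_s`) and `truth`
#'   (see [synth_ground_truth()]).
#' @export
synth_recording <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  schedule <- make_beat_schedule(params)
  dt <- 1000 / params$fs_hz
  n <- floor(params$duration_s * params$fs_hz)
  tgrid <- (seq_len(n) - 1) * dt

  out <- with_seed(params$seed, {
    truth <- truth_core(params, schedule)
    sig <- matrix(0, n, 12L)
    colnames(sig) <- c("ECG", "RVMAP", paste0("EGM", 1:10))

    add <- function(col, t0, t1, f) {
      i0 <- max(1L, floor(t0 / dt) + 1L)
      i1 <- min(n, ceiling(t1 / dt) + 1L)
      if (i0 > i1) return(invisible())
      tt <- tgrid[i0:i1]
      sig[i0:i1, col] <<- sig[i0:i1, col] + f(tt)
      invisible()
    }

    ecgp <- params$ecg
    t_rise <- min(110, ecgp$qt_ms - ecgp$tpe_ms - ecgp$qrs_ms - 10)
    if (t_rise < 20)
      stop("ECG timing parameters leave no room for a T wave", call. = FALSE)

    for (i in seq_len(nrow(schedule))) {
      tb <- schedule$time_ms[i]
      if (schedule$ectopic[i]) {
        w <- 140; a <- schedule$amp_factor[i]
        add("ECG", tb, tb + w,
            function(tt) a * .amp$ecg_qrs * qrs_shape((tt - tb) / w))
        cyc <- truth$events$cycle_ms[schedule$episode[i]]
        t_at <- tb + 20; t_rep <- tb + 0.6 * cyc
        add("RVMAP", tb + 10, tb + 0.55 * cyc + 40, function(tt) {
          .amp$map * stats::plogis((tt - tb - 15) / 1.2) *
            rep_phase3(tt, tb + 15 + 0.45 * cyc, 60)
        })
        for (k in 1:10) {
          ak <- schedule$amp_factor[i]
          add(paste0("EGM", k), t_at - 25, t_rep + 70, function(tt) {
            -ak * .amp$egm * (tanh((tt - t_at) / 2.5) - tanh((tt - t_rep) / 8))
          })
        }
      } else {
        # QRS: biphasic sine lobe with compact support [tb, tb + qrs]
        qw <- ecgp$qrs_ms
        add("ECG", tb, tb + qw,
            function(tt) .amp$ecg_qrs * qrs_shape((tt - tb) / qw))
        # T wave: raised-cosine rise to the peak, linear fall to T-end
        tp <- truth$beats$t_peak_ms[i]; te <- truth$beats$t_end_ms[i]
        add("ECG", tp - t_rise, te, function(tt) {
          .amp$ecg_t * ifelse(tt <= tp,
                              0.5 * (1 + cos(pi * (tt - tp) / t_rise)),
                              pmax(0, 1 - (tt - tp) / ecgp$tpe_ms))
        })
        # RV MAP: logistic upstroke, plateau, cosine phase-3 placed so the
        # 20%-of-amplitude crossing falls at upstroke + true MAPD
        t_up <- tb + params$rv_at_ms
        mapd <- truth$beats$mapd_ms[i]
        d3 <- 80
        t3 <- t_up + mapd - (acos(-0.6) / pi) * d3
        add("RVMAP", t_up - 15, t3 + d3 + 5, function(tt) {
          .amp$map * stats::plogis((tt - t_up) / 1.2) * rep_phase3(tt, t3, d3)
        })
        # LV EGMs: negative depolarization step at tb + AT_k, positive
        # repolarization step at AT + ARI (its steepest point is the
        # activation-recovery fiducial)
        for (k in 1:10) {
          t_at <- tb + truth$at[i, k]
          t_rep <- t_at + truth$ari[i, k]
          add(paste0("EGM", k), t_at - 30, t_rep + 90, function(tt) {
            -.amp$egm * (tanh((tt - t_at) / 2.5) - tanh((tt - t_rep) / 8))
          })
        }
      }
    }

    if (params$noise_sd > 0) {
      sig[, "ECG"] <- sig[, "ECG"] +
        stats::rnorm(n, 0, params$noise_sd * .amp$ecg_qrs)
      sig[, "RVMAP"] <- sig[, "RVMAP"] +
        stats::rnorm(n, 0, params$noise_sd * .amp$map)
      for (k in 1:10)
        sig[, paste0("EGM", k)] <- sig[, paste0("EGM", k)] +
          stats::rnorm(n, 0, params$noise_sd * 2 * .amp$egm)
    }
    list(truth = truth, sig = sig)
  })

  channels <- data.frame(
    name = colnames(out$sig),
    role = c("ecg", "map", rep("egm", 10L)),
    electrode = c(NA_integer_, NA_integer_, 1:10),
    amplitude = c(.amp$ecg_qrs, .amp$map, rep(2 * .amp$egm, 10L)))

  rec <- structure(list(
    signals = out$sig, channels = channels, fs_hz = params$fs_hz,
    duration_s = params$duration_s,
    spike_times_ms = schedule$time_ms[!schedule$ectopic],
    dofetilide_start_s = if (is.null(params$dofetilide)) NA_real_
                         else params$dofetilide$start_s),
    class = "cavb_recording")
  list(recording = rec, truth = out$truth)
}

# Phase-3 repolarization factor: 1 until t3, half-cosine fall over d3, 0 after.
rep_phase3 <- function(tt, t3, d3) {
  ifelse(tt <= t3, 1,
         ifelse(tt >= t3 + d3, 0, 0.5 * (1 + cos(pi * (tt - t3) / d3))))
}

#' @export
print.cavb_recording <- function(x, ...) {
  cat(sprintf("<cavb_recording> %.1f s at %g Hz, %d channels, %d pacing spikes\n",
              x$duration_s, x$fs_hz, ncol(x$signals), length(x$spike_times_ms)))
  if (is.finite(x$dofetilide_start_s))
    cat(sprintf("  dofetilide infusion starts at %.0f s\n", x$dofetilide_start_s))
  invisible(x)
}

# Extract one channel as a numeric vector by role or name.
channel <- function(recording, role = NULL, name = NULL, electrode = NULL) {
  ch <- recording$channels
  if (!is.null(electrode)) name <- ch$name[match(electrode, ch$electrode)]
  if (is.null(name)) name <- ch$name[match(role, ch$role)]
  if (is.na(name) || !name %in% colnames(recording$signals))
    stop(sprintf("recording has no channel for role/name '%s'",
                 role %||% name), call. = FALSE)
  recording$signals[, name]
}

#' Parameters for the synthetic radial-strain generator
#'
#' Six short-axis segments; each trace is a smooth unimodal pulse whose
#' *measured* features equal the requested ones: peak strain `ps_pct`
#' reached at `ttp_ms`, and a sustained 10%-of-peak crossing at `onset_ms`.
#'
#' @param segments A data.frame with columns `segment`, `wall`
#'   (`"freewall"`, `"septum"` or `"discard"`), `onset_ms`, `ttp_ms`,
#'   `ps_pct`, `noise_sd`. Exactly six rows, two per named wall.
#' @param duration_ms Trace length (one cycle from the reference time).
#' @param seed Integer seed for the additive noise.
#' @return A list of class `strain_synth_params`.
#' @export
strain_synth_params <- function(segments, duration_ms = 900, seed = 1L) {
  need <- c("segment", "wall", "onset_ms", "ttp_ms", "ps_pct")
  if (!is.data.frame(segments) || !all(need %in% names(segments)))
    stop("`segments` must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (nrow(segments) != 6L) stop("exactly six segments required", call. = FALSE)
  if (is.null(segments$noise_sd)) segments$noise_sd <- 0
  with(segments, {
    if (any(!is.finite(ps_pct))) stop("`ps_pct` must be finite", call. = FALSE)
    if (any(onset_ms < 0) || any(ttp_ms <= onset_ms))
      stop("segments need ttp_ms > onset_ms >= 0", call. = FALSE)
  })
  structure(list(segments = segments, duration_ms = duration_ms,
                 seed = as.integer(seed)),
            class = "strain_synth_params")
}

#' Convenience builder for two-wall strain parameters
#'
#' @param free_wall,septum Named numeric vectors/lists with `onset`, `ttp`,
#'   `ps` for the wall (values applied to both of its segments).
#' @param noise_sd Additive noise SD (strain %).
#' @param duration_ms,seed Passed to [strain_synth_params()].
#' @return A `strain_synth_params` object with the standard six-segment
#'   layout (anteroseptal/inferoseptal = septum, anterolateral/inferolateral
#'   = free wall, anterior/inferior discarded).
#' @export
wall_strain_params <- function(free_wall, septum, noise_sd = 0,
                               duration_ms = 900, seed = 1L) {
  fw <- as.list(free_wall); sp <- as.list(septum)
  mid <- list(onset = mean(c(fw$onset, sp$onset)),
              ttp = mean(c(fw$ttp, sp$ttp)),
              ps = mean(c(fw$ps, sp$ps)))
  seg <- data.frame(
    segment = c("AS", "IS", "A", "I", "AL", "IL"),
    wall = c("septum", "septum", "discard", "discard", "freewall", "freewall"),
    onset_ms = c(sp$onset, sp$onset, mid$onset, mid$onset, fw$onset, fw$onset),
    ttp_ms = c(sp$ttp, sp$ttp, mid$ttp, mid$ttp, fw$ttp, fw$ttp),
    ps_pct = c(sp$ps, sp$ps, mid$ps, mid$ps, fw$ps, fw$ps),
    noise_sd = noise_sd)
  strain_synth_params(seg, duration_ms = duration_ms, seed = seed)
}

#' Synthesize per-segment radial strain traces
#'
#' Each segment is a raised-cosine pulse, symmetric about its peak, placed so
#' that the measured time-to-peak equals `ttp_ms` and the sustained
#' 10%-of-peak onset crossing falls at `onset_ms` (the trace departs true
#' baseline slightly earlier by construction).
#'
#' @param params A [strain_synth_params()] object.
#' @param fs_hz Sampling rate of the strain traces (Hz).
#' @return A list of class `strain_curves`: `time_ms`, `strain`
#'   (samples x 6 matrix, percent), `segments` (segment/wall map),
#'   `ref_time_ms` (QRS-onset equivalent, 0) and `fs_hz`.
#' @export
synth_strain <- function(params, fs_hz = 1000) {
  stopifnot(inherits(params, "strain_synth_params"))
  dt <- 1000 / fs_hz
  tgrid <- seq(0, params$duration_ms, by = dt)
  seg <- params$segments
  u0 <- acos(0.8) / pi  # rise fraction at which the pulse crosses 10% of peak
  tr <- with_seed(params$seed, {
    m <- matrix(0, length(tgrid), 6L)
    for (i in 1:6) {
      start <- (seg$onset_ms[i] - u0 * seg$ttp_ms[i]) / (1 - u0)
      rise <- seg$ttp_ms[i] - start
      u <- (tgrid - start) / rise
      y <- ifelse(u <= 0 | u >= 2, 0, 0.5 * (1 - cos(pi * u)))
      m[, i] <- seg$ps_pct[i] * y
      if (seg$noise_sd[i] > 0)
        m[, i] <- m[, i] + stats::rnorm(length(tgrid), 0, seg$noise_sd[i])
    }
    colnames(m) <- seg$segment
    m
  })
  structure(list(time_ms = tgrid, strain = tr,
                 segments = seg[, c("segment", "wall")],
                 ref_time_ms = 0, fs_hz = fs_hz),
            class = "strain_curves")
}
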