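#' Short-term variability of repolarization (STV)
#'
#' Poincare-plot-derived beat-to-beat variability of a repolarization
#' duration series D (RV MAPD or LV ARI):
#' `STV = sum(|D[n+1] - D[n]|) / (n_diffs * sqrt(2))`.
#'
#' The conventional "30 consecutive beats" prescription is ambiguous about
#' whether 30 is the number of beats or of successive differences. The
#' default (`mode = "diffs"`) uses 30 successive differences (31 beats) so
#' every summand matches the divisor; `mode = "literal"` takes 30 beats
#' (29 differences) while keeping the divisor at `n_diffs * sqrt(2)`.
#' When the series is longer than needed, the latest beats are used.
#'
#' For iid Normal(0, sigma^2) perturbations E[STV] = sigma * sqrt(2/pi).
#'
#' @param d Numeric series of per-beat repolarization durations (ms),
#'   chronologically ordered, ectopic beats excluded.
#' @param n_diffs Number of successive differences to sum (default 30).
#' @param mode `"diffs"` (31 beats, 30 differences) or `"literal"`
#'   (30 beats, 29 differences).
#' @return STV in ms.
#' @export
stv <- function(d, n_diffs = 30, mode = c("diffs", "literal")) {
  mode <- match.arg(mode)
  d <- as.numeric(d)
  if (any(!is.finite(d)))
    stop("`d` must not contain missing values", call. = FALSE)
  need <- if (mode == "diffs") n_diffs + 1L else n_diffs
  if (length(d) < need)
    stop(sprintf("STV needs at least %d beats (%d supplied)", need, length(d)),
         call. = FALSE)
  dd <- utils::tail(d, need)
  sum(abs(diff(dd))) / (n_diffs * sqrt(2))
}

#' Interventricular dispersion of repolarization
#'
#' `dMAPD = mean LV ARI - RV MAPD`: the mean activation-recovery interval of
#' the LV electrograms minus the RV monophasic action potential duration.
#'
#' @param lv_ari_mean_ms Mean LV ARI (ms).
#' @param rv_mapd_ms RV MAPD (ms).
#' @return Dispersion in ms (vectorized).
#' @export
delta_mapd <- function(lv_ari_mean_ms, rv_mapd_ms) {
  if (any(!is.finite(lv_ari_mean_ms)) || any(!is.finite(rv_mapd_ms)))
    stop("inputs must be finite", call. = FALSE)
  lv_ari_mean_ms - rv_mapd_ms
}

#' Interventricular delay in activation
#'
#' `dAT = mean LV AT - RV AT`.
#'
#' @param lv_at_mean_ms Mean LV activation time (ms).
#' @param rv_at_ms RV activation time (ms).
#' @return Delay in ms (vectorized).
#' @export
delta_at <- function(lv_at_mean_ms, rv_at_ms) {
  if (any(!is.finite(lv_at_mean_ms)) || any(!is.finite(rv_at_ms)))
    stop("inputs must be finite", call. = FALSE)
  lv_at_mean_ms - rv_at_ms
}

#' Intraventricular activation-repolarization coupling (AT-ARI slope)
#'
#' Ordinary least-squares regression of per-electrode ARI on per-electrode
#' activation time. A negative slope means later-activated regions
#' repolarize earlier; steepening under an IKr challenge indicates that
#' repolarization reserve is smallest in early-activated regions.
#'
#' @param ats Per-electrode activation times (ms).
#' @param aris Per-electrode activation-recovery intervals (ms).
#' @param phase Optional label stored in the fit.
#' @return A list of class `at_ari_fit`: `slope`, `intercept_ms`, `r`,
#'   `n_points`, `phase`.
#' @export
at_ari_slope <- function(ats, aris, phase = NA_character_) {
  if (length(ats) != length(aris))
    stop("`ats` and `aris` must have equal length", call. = FALSE)
  ok <- is.finite(ats) & is.finite(aris)
  x <- ats[ok]; y <- aris[ok]
  if (length(x) < 3L)
    stop("at least 3 paired electrode values are required", call. = FALSE)
  if (stats::var(x) == 0)
    stop("zero variance in activation times: slope undefined", call. = FALSE)
  fit <- stats::lm(y ~ x)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept_ms = unname(stats::coef(fit)[1L]),
                 r = stats::cor(x, y), n_points = length(x), phase = phase),
            class = "at_ari_fit")
}

#' @export
print.at_ari_fit <- function(x, ...) {
  cat(sprintf("<at_ari_fit%s> slope %.3f, intercept %.1f ms, r = %.3f (n = %d)\n",
              if (is.na(x$phase)) "" else paste0(": ", x$phase),
              x$slope, x$intercept_ms, x$r, x$n_points))
  invisible(x)
}

#' Select the measurement window for a phase
#'
#' Baseline measurements are taken from the last clean stretch before the
#' start of dofetilide infusion; dofetilide measurements end at the first
#' ectopic beat or 5 min after the start of infusion, whichever comes first.
#'
#' @param beats A [detect_beats()] annotation table.
#' @param dofetilide_start_s Start of infusion, seconds (may be `NA` for a
#'   baseline-only recording; then the baseline window spans the recording).
#' @param phase `"baseline"` or `"dofetilide"`.
#' @param min_beats Minimum number of clean beats the window must contain.
#' @return List `start_ms`, `end_ms`, `beats` (indices of clean beats in
#'   the window).
#' @export
select_measurement_window <- function(beats, dofetilide_start_s,
                                      phase = c("baseline", "dofetilide"),
                                      min_beats = 6L) {
  phase <- match.arg(phase)
  b <- as.data.frame(beats)
  t_end_rec <- max(b$beat_time_ms) + 1
  t0_dof <- if (is.finite(dofetilide_start_s)) dofetilide_start_s * 1000 else
    t_end_rec
  if (phase == "baseline") {
    ect <- b$beat_time_ms[b$ectopic & b$beat_time_ms < t0_dof]
    start <- if (length(ect)) max(ect) + 1 else 0
    end <- t0_dof
  } else {
    if (!is.finite(dofetilide_start_s))
      stop("no dofetilide phase in this recording", call. = FALSE)
    start <- t0_dof
    ect <- b$beat_time_ms[b$ectopic & b$beat_time_ms > start]
    end <- min(if (length(ect)) min(ect) else Inf, start + 300000, t_end_rec)
  }
  idx <- which(!b$ectopic & b$beat_time_ms >= start & b$beat_time_ms < end)
  if (length(idx) < min_beats)
    stop(sprintf("no qualifying %s window: %d clean beats found, %d needed",
                 phase, length(idx), min_beats), call. = FALSE)
  list(start_ms = start, end_ms = end, beats = idx)
}
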