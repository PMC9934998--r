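#' Full interval table for one phase of a recording
#'
#' Assembles the per-condition interval summary: averaged surface-ECG
#' intervals, RV activation time and MAPD, per-electrode and mean LV AT/ARI,
#' the interventricular deltas and both STVs. STV uses the latest beats of
#' the window (31 beats for 30 successive differences by default); it is NA
#' when the window holds too few beats.
#'
#' @param recording A `cavb_recording`.
#' @param beats A [detect_beats()] table.
#' @param window `c(start_ms, end_ms)` analysis window (e.g. from
#'   [select_measurement_window()]).
#' @param phase Label carried into the output row.
#' @param n_beats Beats to average for ECG intervals.
#' @param stv_diffs Successive differences for STV.
#' @return One-row data.frame with columns `phase`, `PP`, `RR`, `QRS`, `QT`,
#'   `QTc`, `JTc`, `TpTe`, `RV_AT`, `LV_AT`, `dAT`, `RV_MAPD`, `LV_ARI`,
#'   `dMAPD`, `RV_STV`, `LV_STV`, `n_electrodes`; per-electrode means as an
#'   `"electrodes"` attribute.
#' @export
interval_table <- function(recording, beats, window, phase = "baseline",
                           n_beats = 5, stv_diffs = 30) {
  ecg <- measure_intervals(recording, beats, n_beats = n_beats,
                           window = window, phase = phase)
  ms <- map_series(recording, beats, window = window)
  es <- egm_series(recording, beats, window = window)
  agg <- lv_aggregates(es)
  rv_at <- mean(ms$rv_at_ms, na.rm = TRUE)
  rv_mapd <- mean(ms$mapd_ms, na.rm = TRUE)
  mapd_ok <- ms$mapd_ms[is.finite(ms$mapd_ms)]
  ari_ok <- agg$ari_mean_series[is.finite(agg$ari_mean_series)]
  rv_stv <- if (length(mapd_ok) >= stv_diffs + 1L)
    stv(mapd_ok, n_diffs = stv_diffs) else NA_real_
  lv_stv <- if (length(ari_ok) >= stv_diffs + 1L)
    stv(ari_ok, n_diffs = stv_diffs) else NA_real_
  out <- data.frame(phase = phase, PP = ecg$PP, RR = ecg$RR, QRS = ecg$QRS,
                    QT = ecg$QT, QTc = ecg$QTc, JTc = ecg$JTc,
                    TpTe = ecg$TpTe, RV_AT = rv_at, LV_AT = agg$lv_at_ms,
                    dAT = delta_at(agg$lv_at_ms, rv_at),
                    RV_MAPD = rv_mapd, LV_ARI = agg$lv_ari_ms,
                    dMAPD = delta_mapd(agg$lv_ari_ms, rv_mapd),
                    RV_STV = rv_stv, LV_STV = lv_stv,
                    n_electrodes = agg$n_electrodes)
  attr(out, "electrodes") <- list(at = agg$at_by_electrode,
                                  ari = agg$ari_by_electrode,
                                  electrodes = agg$electrodes)
  out
}

# Per-group generator calibration emulating the study arms. The AT-ARI slope
# programmed after full dofetilide effect equals
# slope_base - gain * gw / at_range (electrode delays equally spaced), so
# gain and gw are solved from the target mean ARI prolongation and target
# dofetilide slope.
group_defaults <- function(group) {
  dof_solve <- function(slope_base, slope_dof, at_range, mean_prolong_ms) {
    kappa <- (slope_base - slope_dof) * at_range
    gain <- mean_prolong_ms - kappa / 2
    list(ari_gain_ms = gain, gradient_weight = kappa / gain)
  }
  switch(group,
    SR = list(rate_bpm = 102, electrode_ats = seq(8, 16.6, length.out = 10),
              rv_at_ms = 14.3, ari_base_ms = 214, mapd_base_ms = 193,
              at_ari_slope = -0.4, stv_sigma_ms = 0.75, rv_stv_sigma_ms = 0.5,
              dof = NULL, tdp_lambda = 0,
              strain_fw = list(onset = 10.8, ttp = 263.4, ps = 24.2),
              strain_sep = list(onset = 8.4, ttp = 272.0, ps = 25.7)),
    IVR = list(rate_bpm = 45, electrode_ats = seq(16, 56, length.out = 10),
               rv_at_ms = 25, ari_base_ms = 325, mapd_base_ms = 240,
               at_ari_slope = -0.6, stv_sigma_ms = 4.0, rv_stv_sigma_ms = 1.4,
               dof = dof_solve(-0.6, -3.2, 40, 123), tdp_lambda = 3.5,
               strain_fw = list(onset = 61.8, ttp = 290.5, ps = 47.4),
               strain_sep = list(onset = 8.7, ttp = 269.8, ps = 37.4)),
    RVA = list(rate_bpm = 60, electrode_ats = seq(44.6, 84.6, length.out = 10),
               rv_at_ms = 26.9, ari_base_ms = 271, mapd_base_ms = 242,
               at_ari_slope = -0.5, stv_sigma_ms = 1.4, rv_stv_sigma_ms = 1.4,
               dof = dof_solve(-0.5, -4.5, 40, 203), tdp_lambda = 2.35,
               strain_fw = list(onset = 74.2, ttp = 380.3, ps = 22.9),
               strain_sep = list(onset = 7.3, ttp = 297.6, ps = 28.3)),
    CRT = list(rate_bpm = 60, electrode_ats = seq(28.6, 58.6, length.out = 10),
               rv_at_ms = 46, ari_base_ms = 266, mapd_base_ms = 221.6,
               at_ari_slope = -0.3, stv_sigma_ms = 0.88, rv_stv_sigma_ms = 1.75,
               dof = dof_solve(-0.3, -0.8, 30, 190), tdp_lambda = 1.6,
               strain_fw = list(onset = 37.6, ttp = 307.9, ps = 34.4),
               strain_sep = list(onset = 45.2, ttp = 316.3, ps = 36.0)),
    stop(sprintf("unknown group '%s'", group), call. = FALSE))
}

#' Configuration for a virtual experiment
#'
#' Describes one study arm: rhythm strategy, cohort size, the dofetilide
#' challenge and the per-group generator calibration. RVA and CRT arms are
#' paced at 60 bpm during experiments; the idioventricular arm runs at its
#' (bradycardic) escape rate.
#'
#' @param group `"IVR"`, `"RVA"`, `"CRT"` or `"SR"`.
#' @param n_animals Number of virtual animals.
#' @param duration_s Recording length per animal (seconds).
#' @param dofetilide_start_s Start of the challenge (NA for none, e.g. SR).
#' @param synth Named list of [synth_params()] overrides applied to every
#'   animal.
#' @param master_seed Integer master seed; animal seeds derive from it.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(group = c("IVR", "RVA", "CRT", "SR"),
                              n_animals = 10, duration_s = 1200,
                              dofetilide_start_s = if (group == "SR") NA else 600,
                              synth = list(), master_seed = 1L) {
  group <- match.arg(group)
  if (n_animals < 1) stop("`n_animals` must be >= 1", call. = FALSE)
  gd <- group_defaults(group)
  if (group %in% c("RVA", "CRT") && (gd$rate_bpm != 60) &&
      is.null(synth$rate_bpm))
    stop("RVA/CRT experiments are paced at 60 bpm", call. = FALSE)
  structure(list(group = group, n_animals = as.integer(n_animals),
                 duration_s = duration_s,
                 dofetilide_start_s = dofetilide_start_s,
                 defaults = gd, synth = synth,
                 master_seed = as.integer(master_seed)),
            class = "experiment_config")
}

# Draw the scripted ectopy for one animal: episode count ~ Poisson(lambda),
# placed sequentially in the 10-min window after the challenge starts.
draw_ectopy <- function(lambda, dof_start_s, duration_s, seed) {
  if (lambda <= 0 || !is.finite(dof_start_s)) return(list())
  with_seed(seed, {
    n_ep <- stats::rpois(1L, lambda)
    if (n_ep == 0L) return(list())
    lo <- dof_start_s + 30
    hi <- min(dof_start_s + 540, duration_s - 30)
    if (hi <= lo) return(list())
    onsets <- sort(stats::runif(n_ep, lo, hi))
    eps <- list()
    last_end <- -Inf
    for (i in seq_len(n_ep)) {
      nb <- 5L + stats::rpois(1L, 2.5)
      cyc <- 350
      onset <- max(onsets[i], last_end + 4)     # keep runs separated
      if (onset + nb * cyc / 1000 > duration_s - 10) next
      defib <- if (nb * cyc > 10000) 1L else 0L # cardioverted if > 10 s
      eps[[length(eps) + 1L]] <- episode_spec(onset, nb, polymorphic = TRUE,
                                              cycle_ms = cyc,
                                              defibrillations = defib)
      last_end <- onset + nb * cyc / 1000
    }
    eps
  })
}

#' Run the full analysis chain for one virtual animal
#'
#' Generates the animal's recording (baseline then dofetilide phase),
#' detects beats, measures both phase interval tables, fits the AT-ARI
#' slope per phase on the same electrode set, scores arrhythmic activity and
#' computes strain dyssynchrony. Deterministic per seed.
#'
#' @param config An [experiment_config()].
#' @param animal_seed Integer seed for this animal.
#' @return A list of class `virtual_animal`: `row` (one-row wide data.frame
#'   of headline metrics), `tables` (phase interval tables), `fits`
#'   (per-phase `at_ari_fit`), `events`, `score`, `strain`, `truth`.
#' @export
run_virtual_animal <- function(config, animal_seed) {
  stopifnot(inherits(config, "experiment_config"))
  gd <- config$defaults
  dof <- if (is.finite(config$dofetilide_start_s) && !is.null(gd$dof))
    c(list(start_s = config$dofetilide_start_s), gd$dof) else NULL
  overrides <- config$synth
  ectopy <- if ("ectopy" %in% names(overrides)) {
    e <- overrides$ectopy
    overrides$ectopy <- NULL
    e
  } else {
    draw_ectopy(gd$tdp_lambda, config$dofetilide_start_s, config$duration_s,
                seed = (animal_seed + 104729L) %% .Machine$integer.max)
  }
  args <- utils::modifyList(list(
    rate_bpm = gd$rate_bpm, duration_s = config$duration_s,
    electrode_ats = gd$electrode_ats, ari_base_ms = gd$ari_base_ms,
    at_ari_slope = gd$at_ari_slope, stv_sigma_ms = gd$stv_sigma_ms,
    rv_stv_sigma_ms = gd$rv_stv_sigma_ms, rv_at_ms = gd$rv_at_ms,
    mapd_base_ms = gd$mapd_base_ms, dofetilide = dof, ectopy = ectopy,
    seed = animal_seed), overrides)
  params <- do.call(synth_params, args)

  syn <- synth_recording(params)
  rec <- syn$recording
  beats <- tryCatch(detect_beats(rec),
                    error = function(e) stop("stage detect_beats: ",
                                             conditionMessage(e), call. = FALSE))
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE))
  }

  wb <- run_stage("select_window", select_measurement_window(
    beats, config$dofetilide_start_s, "baseline"))
  tab_b <- run_stage("interval_table",
                     interval_table(rec, beats, c(wb$start_ms, wb$end_ms),
                                    phase = "baseline"))
  eb <- attr(tab_b, "electrodes")
  fit_b <- run_stage("at_ari_slope",
                     at_ari_slope(eb$at, eb$ari, phase = "baseline"))

  tab_d <- NULL; fit_d <- NULL
  if (is.finite(config$dofetilide_start_s)) {
    wd <- run_stage("select_window", select_measurement_window(
      beats, config$dofetilide_start_s, "dofetilide"))
    tab_d <- run_stage("interval_table",
                       interval_table(rec, beats, c(wd$start_ms, wd$end_ms),
                                      phase = "dofetilide"))
    ed <- attr(tab_d, "electrodes")
    shared <- intersect(eb$electrodes, ed$electrodes)
    pos_b <- match(shared, eb$electrodes)
    pos_d <- match(shared, ed$electrodes)
    fit_b <- run_stage("at_ari_slope",
                       at_ari_slope(eb$at[pos_b], eb$ari[pos_b], "baseline"))
    fit_d <- run_stage("at_ari_slope",
                       at_ari_slope(ed$at[pos_d], ed$ari[pos_d], "dofetilide"))
  }

  events <- run_stage("arrhythmia", {
    ev <- classify_tdp(group_episodes(beats), beats)
    if (nrow(ev) && nrow(syn$truth$events)) {
      # defibrillation log: scripted per episode, matched by onset order
      m <- seq_len(min(nrow(ev), nrow(syn$truth$events)))
      ev <- attach_defibrillations(ev, data.frame(
        event = ev$event[m],
        defibrillations = syn$truth$events$defibrillations[m]))
    }
    ev
  })
  score <- if (is.finite(config$dofetilide_start_s))
    run_stage("arrhythmia_score",
              arrhythmia_score(events, config$dofetilide_start_s))
  else structure(list(episode_scores = numeric(), final_as = 0,
                      window_s = c(NA_real_, NA_real_), inducible = FALSE),
                 class = "arrhythmia_score")

  strain <- run_stage("strain", {
    sp <- wall_strain_params(gd$strain_fw, gd$strain_sep,
                             seed = animal_seed + 1L)
    strain_metrics(synth_strain(sp))
  })

  row <- data.frame(group = config$group, seed = animal_seed,
                    slope_baseline = fit_b$slope,
                    slope_dofetilide = if (is.null(fit_d)) NA_real_
                                       else fit_d$slope,
                    inducible = isTRUE(score$inducible),
                    AS = score$final_as, n_events = nrow(events),
                    d_ttp_ms = strain$d_ttp_ms, d_ps_pct = strain$d_ps_pct,
                    d_onset_ms = strain$d_onset_ms)
  for (nm in setdiff(names(tab_b), "phase"))
    row[[paste0(nm, "_baseline")]] <- tab_b[[nm]]
  if (!is.null(tab_d))
    for (nm in setdiff(names(tab_d), "phase"))
      row[[paste0(nm, "_dofetilide")]] <- tab_d[[nm]]

  structure(list(row = row, tables = list(baseline = tab_b,
                                          dofetilide = tab_d),
                 fits = list(baseline = fit_b, dofetilide = fit_d),
                 events = events, score = score, strain = strain,
                 truth = syn$truth),
            class = "virtual_animal")
}

#' Run a cohort of virtual animals
#'
#' @param config An [experiment_config()].
#' @param progress Print per-animal progress to stderr.
#' @return data.frame with one row per animal (the `row` elements of
#'   [run_virtual_animal()] stacked).
#' @export
run_cohort <- function(config, progress = FALSE) {
  seeds <- (config$master_seed + seq_len(config$n_animals) * 1009L) %%
    .Machine$integer.max
  rows <- vector("list", config$n_animals)
  for (i in seq_len(config$n_animals)) {
    if (progress)
      message(sprintf("[%s] animal %d/%d (seed %d)", config$group, i,
                      config$n_animals, seeds[i]))
    rows[[i]] <- run_virtual_animal(config, seeds[i])$row
  }
  out <- do.call(rbind, rows)
  out$animal <- seq_len(nrow(out))
  out
}

#' Summarize a cohort: mean, SD, n per metric; inducibility as count and
#' percent
#'
#' Percentages are rounded half-up to the nearest integer (the presentation
#' convention for inducibility rates).
#'
#' @param rows A data.frame of per-animal rows (see [run_cohort()]); a
#'   logical `inducible` column drives the inducibility summary.
#' @return A list of class `group_summary`: `metrics` (metric/mean/sd/n),
#'   `inducibility` (`n_inducible`, `n`, `percent`), `as` (mean/sd of the
#'   arrhythmia score, when present).
#' @export
summarize_group <- function(rows) {
  if (!is.data.frame(rows) || nrow(rows) == 0L)
    stop("`rows` must contain at least one animal", call. = FALSE)
  num <- vapply(rows, is.numeric, logical(1))
  num[names(num) %in% c("seed", "animal")] <- FALSE
  metrics <- do.call(rbind, lapply(names(rows)[num], function(nm) {
    x <- rows[[nm]]
    x <- x[is.finite(x)]
    data.frame(metric = nm, mean = if (length(x)) mean(x) else NA_real_,
               sd = if (length(x) > 1L) stats::sd(x) else 0,
               n = length(x))
  }))
  ind <- NULL
  if ("inducible" %in% names(rows)) {
    k <- sum(rows$inducible)
    n <- nrow(rows)
    ind <- list(n_inducible = k, n = n,
                percent = round_half_up(100 * k / n))
  }
  asum <- if ("AS" %in% names(rows))
    list(mean = mean(rows$AS), sd = if (nrow(rows) > 1L) stats::sd(rows$AS)
                                    else 0) else NULL
  structure(list(metrics = metrics, inducibility = ind, as = asum,
                 n = nrow(rows)),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary> n = %d animals\n", x$n))
  if (!is.null(x$inducibility))
    cat(sprintf("  inducible: %d/%d (%d%%)\n", x$inducibility$n_inducible,
                x$inducibility$n, x$inducibility$percent))
  if (!is.null(x$as))
    cat(sprintf("  arrhythmia score: %.1f +/- %.1f\n", x$as$mean, x$as$sd))
  invisible(x)
}
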