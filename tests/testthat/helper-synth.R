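# Shared fixture builders: everything is generated in code at test time.

# Noise-free, deterministic recording parameters.
clean_params <- function(duration_s = 40, rate_bpm = 60, slope = -0.4,
                         seed = 7, ...) {
  synth_params(rate_bpm = rate_bpm, duration_s = duration_s,
               at_ari_slope = slope, stv_sigma_ms = 0, noise_sd = 0,
               seed = seed, ...)
}

# A minimal hand-built beat-annotation table (for tests that exercise
# interval/arrhythmia logic without signal synthesis).
fake_beats <- function(times, ectopic = rep(FALSE, length(times)),
                       qrs = 100, qt = 340, tpe = 50,
                       polarity = rep(1, length(times)),
                       amp = rep(1, length(times))) {
  df <- data.frame(beat = seq_along(times), beat_time_ms = times,
                   qrs_on_ms = times, qrs_off_ms = times + qrs,
                   t_peak_ms = ifelse(ectopic, NA_real_, times + qt - tpe),
                   t_end_ms = ifelse(ectopic, NA_real_, times + qt),
                   ectopic = ectopic, polarity_sign = polarity,
                   qrs_amp = amp, template_corr = ifelse(ectopic, 0.2, 1))
  class(df) <- c("beat_annotation", "data.frame")
  df
}
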