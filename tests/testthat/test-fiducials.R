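test_that("beat detection: count, flat-line error, ectopic flags from ground truth", {
  p <- clean_params(duration_s = 60)
  syn <- synth_recording(p)
  b <- detect_beats(syn$recording)
  expect_equal(nrow(b), 60)
  expect_false(any(b$ectopic))

  flat <- syn$recording
  flat$signals[, "ECG"] <- 0
  expect_error(detect_beats(flat), "flat")

  p2 <- synth_params(rate_bpm = 60, duration_s = 60, noise_sd = 0.02,
                     stv_sigma_ms = 1,
                     ectopy = list(episode_spec(30, 5, polymorphic = TRUE)),
                     seed = 5)
  syn2 <- synth_recording(p2)
  b2 <- detect_beats(syn2$recording)
  expect_equal(nrow(b2), nrow(syn2$truth$beats))
  expect_equal(sum(b2$ectopic), 5)
  expect_identical(b2$ectopic, syn2$truth$beats$ectopic)
})

test_that("noise-free fiducials match ground truth within one sample", {
  # off-grid beat times (102 bpm) included to exercise sub-sample placement
  for (rate in c(60, 102)) {
    p <- clean_params(duration_s = 30, rate_bpm = rate, slope = -0.4, seed = 4)
    syn <- synth_recording(p)
    tr <- syn$truth
    b <- detect_beats(syn$recording)
    expect_equal(nrow(b), nrow(tr$beats))
    expect_lt(max(abs(b$qrs_on_ms - tr$beats$qrs_on_ms)), 1.001)
    expect_lt(max(abs(b$qrs_off_ms - tr$beats$qrs_off_ms)), 1.001)
    expect_lt(max(abs(b$t_peak_ms - tr$beats$t_peak_ms)), 1.001)
    expect_lt(max(abs(b$t_end_ms - tr$beats$t_end_ms)), 1.001)

    ms <- map_series(syn$recording, b)
    expect_lt(max(abs(ms$rv_at_ms - p$rv_at_ms)), 1.001)
    expect_lt(max(abs(ms$mapd_ms - tr$beats$mapd_ms[!tr$beats$ectopic])), 1.001)

    es <- egm_series(syn$recording, b)
    expect_lt(max(abs(sweep(es$at, 2, p$electrode_ats))), 1.001)
    expect_lt(max(abs(es$ari - tr$ari[!tr$beats$ectopic, ])), 1.001)
  }
})

test_that("Van de Water correction and JTc arithmetic", {
  expect_equal(qtc_van_der_water(300, 1000), 300)
  expect_equal(qtc_van_der_water(262.3, 587.1), 298.2, tolerance = 0.05)
  expect_equal(qtc_van_der_water(339.1, 1084.0), 331.8, tolerance = 0.05)
  expect_error(qtc_van_der_water(-1, 1000), "positive")

  expect_equal(jtc(300, 100), 200)
  expect_equal(jtc(293.1, 66.5), 226.6, tolerance = 0.05)
  expect_equal(jtc(250, 250), 0)
})

test_that("averaged intervals equal the arithmetic mean of the selected beats", {
  # constant RR 1000 ms, programmed QT varying per beat via direct annotation
  times <- seq(500, 10500, by = 1000)
  b <- fake_beats(times)
  qts <- c(rep(340, 6), 330, 335, 340, 345, 350)
  b$t_end_ms <- b$qrs_on_ms + qts
  b$t_peak_ms <- b$t_end_ms - 50
  iv <- measure_intervals(NULL, b, n_beats = 5)
  expect_equal(iv$RR, 1000)
  expect_equal(iv$PP, 1000)
  expect_equal(iv$QT, mean(c(330, 335, 340, 345, 350)))
  expect_equal(iv$QRS, 100)
  expect_equal(iv$QTc, qtc_van_der_water(iv$QT, iv$RR))
  expect_equal(iv$JTc, iv$QTc - iv$QRS)
})

test_that("interval measurement needs enough consecutive clean beats and names the phase", {
  times <- seq(500, 5500, by = 1000)
  ect <- c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)
  b <- fake_beats(times, ectopic = ect)
  expect_error(measure_intervals(NULL, b, n_beats = 5, phase = "dofetilide"),
               "dofetilide")
})

test_that("MAPD80: square-pulse width, amplitude-scale invariance, flat channel", {
  v <- rep(0, 800)
  v[101:400] <- 1
  m <- mapd80(v, spike_ms = 90, end_ms = 700)
  expect_equal(unname(m["mapd_ms"]), 300, tolerance = 1.001)
  m2 <- mapd80(17 * v, spike_ms = 90, end_ms = 700)
  expect_equal(m2["mapd_ms"], m["mapd_ms"])
  m3 <- mapd80(rep(0, 800), spike_ms = 90, end_ms = 700)
  expect_true(is.na(m3["mapd_ms"]))
})

test_that("EGM activation time: equal deflections resolve to the earlier one", {
  # two identical negative steps at +30 and +42 ms after the spike: the
  # minimum-dV/dt rule with earliest tie-break must report the first
  t <- 0:400
  v <- -tanh((t - 130) / 3) - tanh((t - 142) / 3)
  at <- egm_at(v, spike_ms = 100, window_ms = 160)
  expect_lt(at, 36)
  expect_gt(at, 26)
  # two bitwise-identical notches: the derivative minima tie exactly and
  # which.min must resolve to the first
  v2 <- rep(0, 400)
  v2[131:135] <- -1
  v2[143:147] <- -1
  at2 <- egm_at(v2, spike_ms = 100, window_ms = 160)
  expect_lt(at2, 36)
  expect_gt(at2, 24)
})

test_that("ARI fiducial is invariant under polarity inversion and missing on flat T windows", {
  t <- 0:800
  v <- -(tanh((t - 100) / 2.5) - tanh((t - 350) / 8))
  a1 <- egm_ari(v, at_ms = 100, window = c(200, 600))
  expect_equal(a1, 250, tolerance = 1.001)
  a2 <- egm_ari(-v, at_ms = 100, window = c(200, 600))
  expect_equal(a2, a1, tolerance = 1e-6)
  expect_true(is.na(egm_ari(rep(0, 800), at_ms = 100, window = c(200, 600))))
})

test_that("ARI recovery at chronic-remodelling magnitudes (generator ground truth)", {
  p <- synth_params(rate_bpm = 55, duration_s = 30, ari_base_ms = 278.1,
                    mapd_base_ms = 236.7, at_ari_slope = 0, stv_sigma_ms = 0,
                    noise_sd = 0, seed = 8)
  syn <- synth_recording(p)
  b <- detect_beats(syn$recording)
  es <- egm_series(syn$recording, b)
  expect_equal(mean(es$ari), 278.1, tolerance = 1.001)
  ms <- map_series(syn$recording, b)
  expect_equal(mean(ms$mapd_ms), 236.7, tolerance = 1.001)
})
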