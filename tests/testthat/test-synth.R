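test_that("beat schedule arithmetic: regular spacing, count and determinism", {
  p <- synth_params(rate_bpm = 60, duration_s = 60, seed = 1)
  s <- make_beat_schedule(p)
  expect_equal(nrow(s), 60)
  expect_true(all(abs(diff(s$time_ms) - 1000) < 1e-9))
  expect_false(any(s$ectopic))
  expect_identical(s, make_beat_schedule(p))
})

test_that("ectopic episodes insert exactly n_beats ectopic beats and suspend the rhythm", {
  p <- synth_params(rate_bpm = 60, duration_s = 60,
                    ectopy = list(episode_spec(20, 5, cycle_ms = 350)),
                    seed = 1)
  s <- make_beat_schedule(p)
  expect_equal(sum(s$ectopic), 5)
  ect <- s$time_ms[s$ectopic]
  expect_equal(diff(ect), rep(350, 4))
  # no regular beat during the run or its compensatory cycle
  reg <- s$time_ms[!s$ectopic]
  expect_false(any(reg >= min(ect) - 250 & reg <= max(ect) + 999))
})

test_that("schedule errors: overlapping episodes named, too-short recording", {
  p <- synth_params(rate_bpm = 60, duration_s = 60,
                    ectopy = list(episode_spec(20, 10, cycle_ms = 400),
                                  episode_spec(22, 5, cycle_ms = 400)),
                    seed = 1)
  expect_error(make_beat_schedule(p), "episodes 1 and 2 overlap")
  expect_error(make_beat_schedule(synth_params(rate_bpm = 60, duration_s = 0.6)),
               "too short")
})

test_that("degenerate gradient: zero slope and zero sigma give constant true ARIs", {
  p <- clean_params(duration_s = 20, slope = 0)
  tr <- synth_ground_truth(p)
  expect_true(all(abs(tr$ari - p$ari_base_ms) < 1e-12))
})

test_that("programmed AT-ARI slope is embedded exactly in the ground truth", {
  for (sl in c(-4.5, -0.4, 0, 0.5)) {
    p <- clean_params(duration_s = 20, slope = sl)
    tr <- synth_ground_truth(p)
    fit <- stats::lm(tr$ari[1, ] ~ p$electrode_ats)
    expect_equal(unname(stats::coef(fit)[2]), sl, tolerance = 1e-9)
  }
})

test_that("dofetilide prolongation ramps over 5 min and is largest in early-activated regions", {
  p <- synth_params(rate_bpm = 60, duration_s = 500, stv_sigma_ms = 0,
                    noise_sd = 0, at_ari_slope = 0,
                    dofetilide = list(start_s = 60, ari_gain_ms = 100,
                                      gradient_weight = 1),
                    seed = 2)
  tr <- synth_ground_truth(p)
  tb <- tr$beats$time_ms
  pre <- which(tb < 60000)
  post <- which(tb > 60000 + 300000)
  expect_true(all(abs(tr$ari[pre, ] - p$ari_base_ms) < 1e-9))
  # full effect after the ramp: gain * (1 + gw * earliness)
  prolong <- tr$ari[post[1], ] - p$ari_base_ms
  expect_true(all(diff(prolong) < 0))  # earliness decreases with electrode AT
  expect_equal(max(prolong), 200, tolerance = 1e-6)
  expect_equal(min(prolong), 100, tolerance = 1e-6)
  # mid-ramp beat sits strictly between
  mid <- which(tb > 60000 + 100000 & tb < 60000 + 200000)[1]
  expect_true(all(tr$ari[mid, ] - p$ari_base_ms > 0))
  expect_true(all(tr$ari[mid, ] - p$ari_base_ms < prolong))
})

test_that("true-ARI short-term variability calibrates to sigma * sqrt(2/pi)", {
  sigma <- 2
  p <- synth_params(rate_bpm = 110, duration_s = 1660, stv_sigma_ms = sigma,
                    noise_sd = 0, at_ari_slope = 0, seed = 3)
  tr <- synth_ground_truth(p)
  d <- tr$beats$lv_ari_mean_ms
  expect_gte(length(d), 3001)
  est <- stv(d, n_diffs = 3000)
  expect_equal(est, sigma * sqrt(2 / pi), tolerance = 0.05)
})

test_that("synthetic recordings are bit-identical for identical parameters", {
  p <- synth_params(duration_s = 15, noise_sd = 0.02, seed = 9,
                    ectopy = list(episode_spec(8, 5)))
  s1 <- synth_recording(p)
  s2 <- synth_recording(p)
  expect_identical(s1$recording$signals, s2$recording$signals)
  expect_identical(s1$truth, s2$truth)
})

test_that("strain pulses peak at the programmed time and symmetric walls cancel", {
  sp <- wall_strain_params(list(onset = 30, ttp = 300, ps = 20),
                           list(onset = 30, ttp = 300, ps = 20))
  cs <- synth_strain(sp)
  i <- which.max(cs$strain[, "AL"])
  expect_equal(cs$time_ms[i], 300)
  d <- strain_metrics(cs)
  expect_equal(d$d_ttp_ms, 0, tolerance = 1e-9)
  expect_equal(d$d_ps_pct, 0, tolerance = 1e-9)
})

test_that("programmed wall TTPs reproduce the RV-apex pacing dyssynchrony delta", {
  sp <- wall_strain_params(list(onset = 74.2, ttp = 380.3, ps = 22.9),
                           list(onset = 7.3, ttp = 297.6, ps = 28.3))
  m <- strain_metrics(synth_strain(sp))
  expect_equal(m$d_ttp_ms, 82.7, tolerance = 0.05)
})

test_that("parameter validation rejects malformed inputs", {
  expect_error(synth_params(electrode_ats = 1:5), "10")
  expect_error(synth_params(stv_sigma_ms = -1), "stv_sigma_ms")
  expect_error(synth_params(rate_bpm = 0), "rate_bpm")
  expect_error(episode_spec(10, 0), "n_beats")
  expect_error(strain_synth_params(data.frame(segment = "a", wall = "septum",
                                              onset_ms = 50, ttp_ms = 40,
                                              ps_pct = 10)),
               "six segments")
})
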