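test_that("episode grouping: maximal ectopic runs, conservation, empty input", {
  times <- seq(500, 5500, by = 1000)
  b <- fake_beats(times, ectopic = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE))
  ev <- group_episodes(b)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$n_beats, c(3, 2))
  expect_equal(sum(ev$n_beats), sum(b$ectopic))

  expect_equal(nrow(group_episodes(fake_beats(times))), 0)

  set.seed(17)
  for (i in 1:15) {
    flags <- runif(40) < 0.3
    bb <- fake_beats(seq_along(flags) * 800, ectopic = flags)
    expect_equal(sum(group_episodes(bb)$n_beats), sum(flags))
  }
})

test_that("a scripted 7-beat run detected end-to-end groups into one 7-beat event", {
  p <- synth_params(rate_bpm = 60, duration_s = 60, noise_sd = 0.02,
                    stv_sigma_ms = 1,
                    ectopy = list(episode_spec(25, 7, polymorphic = TRUE)),
                    seed = 21)
  syn <- synth_recording(p)
  b <- detect_beats(syn$recording)
  ev <- group_episodes(b)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$n_beats, 7)
})

test_that("TdP classification: beat-count and polymorphism requirements", {
  mk <- function(n, pol, amp = rep(1, n)) {
    times <- c(500, 1500, 2500 + (seq_len(n) - 1) * 350,
               2500 + n * 350 + 1000)
    ect <- c(FALSE, FALSE, rep(TRUE, n), FALSE)
    fake_beats(times, ectopic = ect,
               polarity = c(1, 1, pol, 1), amp = c(1, 1, amp, 1))
  }
  # 5-beat alternating-polarity run is TdP
  ev <- classify_tdp(group_episodes(mk(5, c(1, -1, 1, -1, 1))),
                     mk(5, c(1, -1, 1, -1, 1)))
  expect_true(ev$is_tdp)
  expect_gte(ev$polymorphism_index, 0.3)
  # 4-beat polymorphic run: below the beat threshold
  ev4 <- classify_tdp(group_episodes(mk(4, c(1, -1, 1, -1))),
                      mk(4, c(1, -1, 1, -1)))
  expect_false(ev4$is_tdp)
  expect_gte(ev4$polymorphism_index, 0.3)
  # 8-beat monomorphic run: fails the polymorphism requirement
  ev8 <- classify_tdp(group_episodes(mk(8, rep(1, 8))), mk(8, rep(1, 8)))
  expect_false(ev8$is_tdp)
  expect_lt(ev8$polymorphism_index, 0.3)
})

test_that("inducibility: >= 3 TdP starting within the 10-min half-open window", {
  mk_ev <- function(starts_s, tdp = rep(TRUE, length(starts_s))) {
    k <- length(starts_s)
    data.frame(event = seq_len(k), start_ms = starts_s * 1000,
               end_ms = starts_s * 1000 + 2000,
               n_beats = rep(6L, k), polymorphism_index = rep(0.6, k),
               is_tdp = tdp, defibrillations = rep(0L, k))
  }
  expect_true(inducibility(mk_ev(c(60, 200, 420) + 100), 100))
  expect_false(inducibility(mk_ev(c(150, 300, 100 + 620)), 100))
  expect_false(inducibility(mk_ev(numeric(0))))
  # non-TdP events never count
  expect_false(inducibility(mk_ev(c(160, 300, 420), tdp = c(TRUE, TRUE, FALSE)),
                            100))
  # boundary: exactly at t0 + 600 s is in; exactly at t0 is out
  expect_true(inducibility(mk_ev(c(200, 300, 700)), 100))
  expect_false(inducibility(mk_ev(c(100, 300, 400)), 100))
})

test_that("arrhythmia score: n+1 rule, defibrillation overrides, top-3 averaging", {
  mk_ev <- function(n_beats, defib = rep(0L, length(n_beats))) {
    k <- length(n_beats)
    data.frame(event = seq_len(k), start_ms = 70000 + seq_len(k) * 20000,
               end_ms = 70000 + seq_len(k) * 20000 + 2000,
               n_beats = n_beats, polymorphism_index = rep(0.6, k),
               is_tdp = n_beats >= 5, defibrillations = defib)
  }
  expect_equal(arrhythmia_score(mk_ev(5), 60)$final_as, 6)
  expect_equal(arrhythmia_score(mk_ev(5, 2L), 60)$final_as, 75)
  expect_equal(arrhythmia_score(mk_ev(5, 1L), 60)$final_as, 50)
  expect_equal(arrhythmia_score(mk_ev(5, 3L), 60)$final_as, 100)
  s <- arrhythmia_score(mk_ev(c(3, 7, 10, 2)), 60)
  expect_equal(s$final_as, (11 + 8 + 4) / 3, tolerance = 1e-9)
  expect_equal(s$episode_scores, c(11, 8, 4, 3))
  # 0 events -> 0 (configurable)
  none <- mk_ev(integer(0))
  expect_equal(arrhythmia_score(none, 60)$final_as, 0)
  expect_equal(arrhythmia_score(none, 60, zero_score = 1)$final_as, 1)
  # events outside the window are ignored
  late <- mk_ev(c(5, 8)); late$start_ms <- c(65000, 60000 + 601000)
  expect_equal(arrhythmia_score(late, 60)$final_as, 6)
  expect_error(arrhythmia_score(transform(mk_ev(5), n_beats = 0L), 60),
               "n_beats")
})

test_that("final score is monotone in episode size and defibrillation count", {
  mk_ev <- function(n_beats, defib) {
    data.frame(event = seq_along(n_beats),
               start_ms = 70000 + seq_along(n_beats) * 20000,
               end_ms = 70000 + seq_along(n_beats) * 20000 + 2000,
               n_beats = n_beats, polymorphism_index = 0.6,
               is_tdp = n_beats >= 5, defibrillations = defib)
  }
  set.seed(9)
  for (i in 1:10) {
    nb <- sample(1:20, 4, replace = TRUE)
    df <- sample(0:3, 4, replace = TRUE)
    base <- arrhythmia_score(mk_ev(nb, df), 60)$final_as
    nb2 <- nb; nb2[1] <- nb2[1] + sample(1:10, 1)
    expect_gte(arrhythmia_score(mk_ev(nb2, df), 60)$final_as, base)
    df2 <- df; df2[1] <- min(3L, df2[1] + 1L)
    expect_gte(arrhythmia_score(mk_ev(nb, df2), 60)$final_as, base)
  }
})

test_that("scripted event logs are reproduced exactly through the signal pipeline", {
  # three polymorphic TdP runs scripted after the challenge: detection,
  # grouping and scoring must recover the scripted final score at default
  # noise
  eps <- list(episode_spec(100, 6, polymorphic = TRUE),
              episode_spec(130, 9, polymorphic = TRUE),
              episode_spec(160, 5, polymorphic = TRUE))
  p <- synth_params(rate_bpm = 60, duration_s = 200, noise_sd = 0.02,
                    stv_sigma_ms = 1,
                    dofetilide = list(start_s = 60, ari_gain_ms = 120,
                                      gradient_weight = 0.5),
                    ectopy = eps, seed = 33)
  syn <- synth_recording(p)
  b <- detect_beats(syn$recording)
  ev <- classify_tdp(group_episodes(b), b)
  expect_equal(nrow(ev), 3)
  expect_equal(ev$n_beats, c(6, 9, 5))
  expect_true(all(ev$is_tdp))
  sc <- arrhythmia_score(ev, 60)
  expect_equal(sc$final_as, mean(c(7, 10, 6)))
  expect_true(sc$inducible)
})
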