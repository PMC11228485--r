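# deterministic hand-built trial: fly rests at (10, 3), startles 5 mm at
# t = 304 s (inside pulse 2 of a train at t = 300), wanders, settles again
# at t = 420 s
startle_fixture <- function() {
  cfg <- cfg_12()
  n <- 900
  x <- rep(10, n); y <- rep(3, n)
  wander <- 305:419
  x[wander + 1] <- 10 + 5 + 2 * sin(wander / 7)
  x[305] <- 15                       # the 5-mm response step at t = 304
  tr <- trajectory(0:(n - 1), x, y, cfg)
  sch <- stimulus_schedule("vibration", train_onset_zt_min = 5)
  list(cfg = cfg, tr = tr, sch = sch)
}

test_that("arousal_trials scores the hand-built startle correctly", {
  fx <- startle_fixture()
  im <- score_immobility(fx$tr)
  bouts <- score_sleep(im)
  trials <- arousal_trials(fx$tr, fx$sch, bouts)
  expect_equal(nrow(trials), 1L)
  expect_true(trials$immobile_at_onset)
  expect_equal(trials$prior_immobility_s, 300)
  expect_true(trials$responded)
  expect_equal(trials$pulse_idx, 2L)          # response at onset + 4 s
  expect_equal(trials$threshold_g, 2)
  # latency: response frame 304 s -> settled rest onset 420 s
  expect_equal(trials$latency_min, (420 - 304) / 60, tolerance = 0.02)
})

test_that("a never-responding fly yields an unresolved trial", {
  cfg <- cfg_12()
  tr <- still_traj(900, jitter = 0.1, seed = 2)
  sch <- stimulus_schedule("vibration", train_onset_zt_min = 5)
  trials <- arousal_trials(tr, sch, score_sleep(score_immobility(tr)))
  expect_true(trials$immobile_at_onset)
  expect_false(trials$responded)
  expect_true(is.na(trials$threshold_g))
  expect_true(is.na(trials$latency_min))
})

test_that("a zero-threshold hard-response fly responds at pulse 1 of every train", {
  cfg <- cfg_12()
  p <- sim_params("warm25",
                  trans_w2r = c(b0 = 30, bH = 0, bC = 0),  # always rest
                  threshold_nodes = cbind(immobility_s = c(1, 10),
                                          threshold_g = c(0, 0)),
                  response_prob_slope = Inf,
                  resleep_latency_mean_min = 0.5)
  sch <- stimulus_schedule("vibration", days = 1)
  f <- simulate_fly(p, cfg, sch, days = 1, seed = 3)
  resp <- f$truth$responses
  expect_true(all(resp$responded))
  expect_true(all(resp$pulse == 1L))
  trials <- arousal_trials(f$trajectory, sch,
                           score_sleep(score_immobility(f$trajectory)))
  expect_true(all(trials$threshold_g[trials$responded] == 1))
})

test_that("overlapping stimulus trains are rejected", {
  fx <- startle_fixture()
  bad <- stimulus_schedule("vibration", train_onset_zt_min = c(5, 5.1))
  expect_error(arousal_trials(fx$tr, bad, data.table()), "overlap")
})

test_that("threshold_vs_immobility handles censoring policies and constants", {
  trials <- data.table(
    fly_id = "f", train_onset_zt_min = seq(60, by = 120, length.out = 8),
    immobile_at_onset = TRUE,
    prior_immobility_s = c(8, 30, 120, 400, 1200, 4000, 6000, 9000),
    responded = c(rep(TRUE, 7), FALSE),
    pulse_idx = 2L, threshold_g = c(rep(2, 7), NA), latency_min = 1)
  setattr(trials, "intensities", 1:5)
  tv <- threshold_vs_immobility(trials)
  expect_equal(tv$mean_threshold_g[1:7], rep(2, 7))
  expect_equal(tv$mean_threshold_g[8], 5)      # censored at max intensity
  expect_equal(tv$n, rep(1L, 8))
  tv2 <- threshold_vs_immobility(trials, censored = "drop")
  expect_equal(tv2$n[8], 0L)
  expect_true(is.na(tv2$mean_threshold_g[8]))
})

test_that("responder_proportion tallies trials by time of day", {
  trials <- data.table(
    fly_id = rep(c("a", "b"), each = 4),
    train_onset_zt_min = rep(c(60, 180, 780, 900), 2),
    immobile_at_onset = TRUE,
    responded = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE))
  rp <- responder_proportion(trials, bin_zt_h = 12)
  expect_equal(rp$prop_responding, c(3 / 4, 1 / 4))
  expect_equal(rp$n_trials, c(4L, 4L))

  all_resp <- copy(trials)[, responded := TRUE]
  expect_true(all(responder_proportion(all_resp)$prop_responding == 1))
  none <- copy(trials)[, responded := FALSE]
  expect_true(all(responder_proportion(none)$prop_responding == 0))
})

test_that("post_stimulus_kinetics recovers a known exponential decay", {
  cfg <- cfg_12()
  tau_s <- 180; base <- 0.12; amp <- 2.0
  n <- 3600
  onset <- 1200
  sp <- rep(base, n)
  post <- onset:(n - 1)
  sp[post + 1] <- base + amp * exp(-(post - onset) / tau_s)
  # fly oscillates so that per-frame |dx| equals the speed profile
  x <- 20 + cumsum(sp * rep_len(c(1, -1), n))
  tr <- trajectory(0:(n - 1), x, rep(3, n), cfg)
  sch <- stimulus_schedule("vibration", train_onset_zt_min = onset / 60)
  kin <- post_stimulus_kinetics(tr, sch, window_min = 30, pre_min = 2)
  expect_equal(unique(kin$phase), "day")
  tau_fit <- startle_decay_constant(kin, "day", fit_window_s = c(20, 600),
                                    baseline = base)
  expect_equal(tau_fit, tau_s / 60, tolerance = 0.1)

  # flat fixture: no transient
  flat <- trajectory(0:(n - 1), 20 + cumsum(rep_len(c(0.1, -0.1), n)),
                     rep(3, n), cfg)
  kf <- post_stimulus_kinetics(flat, sch, window_min = 10)
  expect_lt(diff(range(kf$mean_speed)), 1e-9)

  # normalization of a constant-speed fixture is 1 throughout
  kn <- post_stimulus_kinetics(flat, sch, window_min = 10, normalize = TRUE)
  expect_equal(kn$mean_speed, rep(1, nrow(kn)))
})

test_that("sleep_latency_profile aggregates responders by ZT bin and phase", {
  trials <- data.table(
    fly_id = "f",
    train_onset_zt_min = c(60, 60, 900, 1020),
    immobile_at_onset = TRUE,
    responded = c(TRUE, TRUE, TRUE, FALSE),
    latency_min = c(10, 20, 6, NA))
  prof <- sleep_latency_profile(trials, bin_zt_h = 2)
  expect_equal(prof[zt_h == 0, mean_latency_min], 15)   # bin [ZT 0, 2)
  ph <- sleep_latency_profile(trials, by_phase = TRUE)
  expect_equal(ph[phase == "night", mean_latency_min], 6)
  expect_true(is.na(ph[phase == "night", sem]))   # single responder

  one <- trials[3]
  p1 <- sleep_latency_profile(one)
  expect_equal(p1$mean_latency_min, 6)
  expect_true(is.na(p1$sem))
})

test_that("an instant-resleep fly has a small non-negative latency floor", {
  cfg <- cfg_12()
  p <- sim_params("cold10",
                  trans_w2r = c(b0 = 30, bH = 0, bC = 0),
                  threshold_nodes = cbind(immobility_s = c(1, 10),
                                          threshold_g = c(0, 0)),
                  response_prob_slope = Inf,
                  resleep_latency_mean_min = 0.01)
  sch <- stimulus_schedule("vibration", days = 1)
  f <- simulate_fly(p, cfg, sch, days = 1, seed = 8)
  trials <- arousal_trials(f$trajectory, sch,
                           score_sleep(score_immobility(f$trajectory)))
  lat <- trials[responded == TRUE & !is.na(latency_min), latency_min]
  expect_true(all(lat >= 0))
  expect_lt(mean(lat), 1.5)
})
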