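test_that("a stationary fly is immobile every minute", {
  im <- score_immobility(still_traj(600))
  expect_true(all(im$immobile))
  expect_equal(nrow(im), 10L)
})

test_that("a single above-threshold step marks only its minute mobile", {
  cfg <- cfg_12()
  x <- rep(10, 600)
  x[7 * 60 + 31] <- 14.2          # 4.2 mm excursion inside minute 7
  tr <- trajectory(0:599, x, rep(3, 600), cfg)
  im <- score_immobility(tr)
  expect_false(im$immobile[8])    # minute index 7 (0-based)
  expect_true(all(im$immobile[-8]))
})

test_that("micro-jitter below the threshold stays immobile", {
  tr <- still_traj(1200, jitter = 0.1, seed = 4)
  im <- score_immobility(tr)
  # independent oracle: explicit max-displacement scan per minute
  for (m in 0:19) {
    seg <- tr[tr$t_s >= m * 60 & tr$t_s < (m + 1) * 60, ]
    d <- sqrt((seg$x_mm - seg$x_mm[1])^2 + (seg$y_mm - seg$y_mm[1])^2)
    expect_equal(im$immobile[m + 1], max(d) < 3)
  }
  expect_true(all(im$immobile))
})

test_that("untracked minutes get missing flags", {
  cfg <- cfg_12()
  tr <- trajectory(0:599, rep(10, 600), rep(3, 600), cfg,
                   valid = c(rep(TRUE, 120), rep(FALSE, 60), rep(TRUE, 420)))
  im <- score_immobility(tr)
  expect_true(is.na(im$immobile[3]))
  expect_true(all(im$immobile[-3]))
})

test_that("score_sleep applies the five-minute rule with half-open bounds", {
  im <- data.table(fly_id = "f", zt_min = 0:6,
                   immobile = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  b <- score_sleep(im)
  expect_equal(nrow(b), 1L)
  expect_equal(c(b$start_zt_min, b$end_zt_min, b$duration_min), c(0, 5, 5))

  im2 <- data.table(fly_id = "f", zt_min = 0:10,
                    immobile = c(T, T, T, T, F, T, T, T, T, T, F))
  b2 <- score_sleep(im2)
  expect_equal(nrow(b2), 1L)           # the 4-run is discarded
  expect_equal(c(b2$start_zt_min, b2$end_zt_min), c(5, 10))

  im3 <- copy(im); im3$immobile[3] <- NA   # missing minutes break runs
  expect_equal(nrow(score_sleep(im3)), 0L)
})

test_that("score_sleep equals the brute-force scanner on random flag strings", {
  set.seed(99)
  for (r in 1:25) {
    flags <- runif(200) < 0.6
    flags[runif(200) < 0.03] <- NA
    im <- data.table(fly_id = "f", zt_min = 0:199, immobile = flags)
    b <- score_sleep(im)
    oracle <- brute_sleep_runs(flags)
    expect_equal(b$start_zt_min, oracle$start - 1)
    expect_equal(b$end_zt_min, oracle$end - 1)
  }
})

test_that("sleep scoring is idempotent and additive in bout durations", {
  set.seed(12)
  flags <- runif(1440) < 0.75
  im <- data.table(fly_id = "f", zt_min = 0:1439, immobile = flags)
  b1 <- score_sleep(im)
  expect_identical(b1, score_sleep(im))
  expect_equal(total_sleep(b1)$total_sleep_min, sum(b1$duration_min))
})

test_that("raising the movement threshold never decreases total sleep", {
  tr <- rw_traj(7200, step = 0.8, seed = 21)
  totals <- vapply(c(1, 2, 3, 5, 8), function(thr) {
    b <- score_sleep(score_immobility(tr, move_threshold_mm = thr))
    if (nrow(b)) sum(b$duration_min) else 0
  }, numeric(1))
  expect_true(all(diff(totals) >= 0))
})

test_that("sleep_timecourse bins bout minutes and cohort proportions", {
  b <- data.table(fly_id = "f", start_zt_min = 60, end_zt_min = 90,
                  duration_min = 30)
  tc <- sleep_timecourse(b, bin_min = 30, span_zt_min = c(0, 120))
  expect_equal(tc$per_fly$sleep_min, c(0, 0, 30, 0))

  b2 <- data.table(fly_id = c("a", "b"),
                   start_zt_min = 0, end_zt_min = 120, duration_min = 120)
  tc2 <- sleep_timecourse(b2, bin_min = 30, span_zt_min = c(0, 120))
  expect_true(all(tc2$cohort$prop_asleep == 1))

  set.seed(5)
  starts <- sort(sample(seq(0, 1380, by = 20), 8))
  b3 <- data.table(fly_id = "f", start_zt_min = starts,
                   end_zt_min = starts + 10, duration_min = 10)
  tc3 <- sleep_timecourse(b3, bin_min = 60, span_zt_min = c(0, 1440))
  # naive recount
  naive <- vapply(seq(0, 1380, by = 60), function(s)
    sum(pmax(0, pmin(s + 60, b3$end_zt_min) - pmax(s, b3$start_zt_min))),
    numeric(1))
  expect_equal(tc3$per_fly$sleep_min, naive)
})

test_that("scored sleep tracks ground-truth rest in a cold simulation", {
  cfg <- experiment_config(10, ld_schedule("09:00", 16))
  p <- sim_params("cold10")
  rel_err <- vapply(1:3, function(i) {
    f <- simulate_fly(p, cfg, days = 2, seed = derive_seed(77, i))
    im <- score_immobility(f$trajectory)
    scored <- sum(score_sleep(im)$duration_min)
    st <- f$truth$state
    r <- rle(st)
    truth_min <- sum(r$lengths[r$values == 1 & r$lengths >= 300]) / 60
    abs(scored - truth_min) / truth_min
  }, numeric(1))
  expect_lt(mean(rel_err), 0.02)
})
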