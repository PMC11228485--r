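test_that("assign_zones splits at the boundary with the tie-break", {
  cfg <- cfg_12()    # boundary at 22 mm, labels shade/bright
  tr <- trajectory(0:3, c(10, 22, 22.01, 40), rep(3, 4), cfg)
  z <- assign_zones(tr, cfg)
  expect_equal(z$zone, c("shade", "shade", "bright", "bright"))

  tr2 <- rw_traj(500, seed = 5)
  z2 <- assign_zones(tr2, cfg)
  oracle <- ifelse(!tr2$valid, NA_character_,
                   ifelse(tr2$x_mm <= 22, "shade", "bright"))
  expect_equal(z2$zone, oracle)
})

test_that("shade_pi follows the difference-over-sum definition", {
  cfg <- cfg_12()
  n <- 720
  in_shade <- c(rep(TRUE, 540), rep(FALSE, 180))
  tr <- trajectory(0:(n - 1), ifelse(in_shade, 10, 40), rep(3, n), cfg)
  z <- assign_zones(tr, cfg)
  pi_all <- shade_pi(z, bin_min = n / 60)
  expect_equal(pi_all$pi_value, (540 - 180) / 720)

  all_shade <- trajectory(0:59, rep(5, 60), rep(3, 60), cfg)
  expect_equal(shade_pi(assign_zones(all_shade, cfg), 1)$pi_value, 1)

  split <- trajectory(0:59, rep(c(5, 40), 30), rep(3, 60), cfg)
  expect_equal(shade_pi(assign_zones(split, cfg), 1)$pi_value, 0)
})

test_that("PI is bounded and bins with no tracking are missing", {
  cfg <- cfg_12()
  tr <- rw_traj(1800, seed = 8)
  tr$valid[61:120] <- FALSE
  z <- assign_zones(tr, cfg)
  p <- shade_pi(z, bin_min = 1)
  expect_true(all(abs(p$pi_value) <= 1, na.rm = TRUE))
  expect_true(is.na(p$pi_value[2]))
})

test_that("swapping zone labels negates every PI", {
  cfg <- cfg_12()
  cfg_sw <- experiment_config(25, ld_schedule("09:00", 12),
                              zone_labels = c("bright", "shade"))
  tr <- rw_traj(3600, seed = 13)
  # relabelling the physical sides (filter moved) negates the shade PI
  p1 <- shade_pi(assign_zones(tr, cfg), 10, zone_a = "shade")
  p2 <- shade_pi(assign_zones(tr, cfg_sw), 10, zone_a = "shade")
  expect_equal(p2$pi_value, -p1$pi_value)
})

test_that("sleep_pi handles pure and mixed zone bouts", {
  b <- data.table(fly_id = "f",
                  start_zt_min = c(0, 200, 400),
                  end_zt_min = c(100, 300, 500),
                  duration_min = 100,
                  rest_x_mm = c(5, 8, 40),
                  zone = c("shade", "shade", "bright"))
  expect_equal(sleep_pi(b, c(0, 12), zone_a = "shade")$pi_value,
               (200 - 100) / 300)
  all_shade <- b[zone == "shade"]
  expect_equal(sleep_pi(all_shade, c(0, 12), zone_a = "shade")$pi_value, 1)
  expect_equal(sleep_pi(b, c(0, 12), zone_a = "bright")$pi_value,
               -sleep_pi(b, c(0, 12), zone_a = "shade")$pi_value)
  # equal sleep in both zones
  eq <- b[2:3]
  expect_equal(sleep_pi(eq, c(0, 12), zone_a = "shade")$pi_value, 0)
  # no sleep in the window
  night <- sleep_pi(b, list(night = c(12, 24)), zone_a = "shade")
  expect_true(is.na(night$pi_value))
})

test_that("sleep_pi folds bouts across days", {
  b <- data.table(fly_id = "f",
                  start_zt_min = c(100, 1540),   # same ZT window, two days
                  end_zt_min = c(160, 1600),
                  duration_min = 60,
                  rest_x_mm = c(5, 40),
                  zone = c("shade", "bright"))
  out <- sleep_pi(b, list(day = c(0, 12)), zone_a = "shade")
  expect_equal(out$sleep_a_min, 60)
  expect_equal(out$sleep_b_min, 60)
  expect_equal(out$pi_value, 0)
})

test_that("time_in_zone is frame-weighted and bounded by the window", {
  cfg <- cfg_12()
  day <- trajectory(0:(720 * 60 - 1), rep(40, 720 * 60),
                    rep(3, 720 * 60), cfg)
  z <- assign_zones(day, cfg)
  out <- time_in_zone(z, c(0, 720))
  expect_equal(out$minutes, 720)
  expect_equal(out$zone, "bright")

  alt <- trajectory(0:(720 * 60 - 1),
                    rep(c(5, 40), each = 360 * 60), rep(3, 720 * 60), cfg)
  out2 <- time_in_zone(assign_zones(alt, cfg), c(0, 720))
  expect_equal(sort(out2$minutes), c(360, 360))
})

test_that("shade_movement_correlation recovers constructed extremes", {
  cfg <- cfg_12()
  # anti-monotone by construction: fly k paces faster (larger y
  # oscillation frequency) and spends strictly less time in shade
  flies <- rbindlist(lapply(1:6, function(k) {
    n <- 600
    cut <- round(n * (7 - k) / 8)
    x <- c(rep(5, cut), rep(40, n - cut))
    y <- 3 + 2.5 * sin(2 * pi * k * (0:(n - 1)) / 100)
    trajectory(0:(n - 1), x, y, cfg, fly_id = paste0("f", k))
  }))
  z <- assign_zones(flies, cfg)
  out <- shade_movement_correlation(flies, z, n_perm = 500, seed = 4)
  expect_equal(out$rho, -1)

  expect_error(shade_movement_correlation(flies[fly_id %in% c("f1", "f2")],
                                          z, n_perm = 10), "3 flies")
})

test_that("spearman rho equals the base-R oracle including ties", {
  cfg <- cfg_12()
  set.seed(9)
  flies <- rbindlist(lapply(1:10, function(k)
    rw_traj(400, step = sample(1:3, 1), seed = 300 + k,
            fly_id = paste0("f", k))))
  z <- assign_zones(flies, cfg)
  out <- shade_movement_correlation(flies, z, n_perm = 200, seed = 1)
  oracle <- suppressWarnings(
    cor.test(out$per_fly$distance_mm, out$per_fly$shade_min,
             method = "spearman"))
  expect_equal(out$rho, unname(oracle$estimate))
})

test_that("permutation p-values are roughly uniform under independence", {
  cfg <- cfg_12()
  ps <- vapply(1:24, function(r) {
    flies <- rbindlist(lapply(1:12, function(k)
      rw_traj(150, step = 2, seed = 1000 * r + k, fly_id = paste0("f", k))))
    z <- assign_zones(flies, cfg)
    shade_movement_correlation(flies, z, n_perm = 300, seed = r)$p_perm
  }, numeric(1))
  expect_gt(mean(ps), 0.25)
  expect_lt(mean(ps), 0.75)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("window PI is not the mean of sub-window PIs when denominators differ", {
  cfg <- cfg_12()
  occ <- c(rep(5, 100), rep(40, 20), rep(5, 10), rep(40, 10))
  n <- length(occ) * 60
  # drop tracking for most of the first half so its valid-frame
  # denominator is much smaller
  valid <- rep(TRUE, n)
  valid[1:3000] <- FALSE
  tr <- trajectory(0:(n - 1), rep(occ, each = 60), rep(3, n), cfg,
                   valid = valid)
  z <- assign_zones(tr, cfg)
  whole <- shade_pi(z, bin_min = 140)$pi_value
  halves <- shade_pi(z, bin_min = 70)$pi_value
  expect_false(isTRUE(all.equal(whole, mean(halves))))
})
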