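library(data.table)

# --- small configuration fixtures -------------------------------------------

cfg_12 <- function(temp = 25)
  experiment_config(temp, ld_schedule("09:00", 12))

cfg_16 <- function(temp = 25)
  experiment_config(temp, ld_schedule("09:00", 16))

# random-walk trajectory confined to the arena (reflecting walls)
rw_traj <- function(n, step = 2, seed = 1, config = cfg_12(),
                    fly_id = "rw1", dt_s = 1) {
  set.seed(seed)
  L <- config$arena_length_mm; W <- config$arena_width_mm
  x <- numeric(n); y <- numeric(n)
  x[1] <- runif(1, 0, L); y[1] <- runif(1, 0, W)
  for (i in 2:n) {
    x[i] <- x[i - 1] + rnorm(1, 0, step)
    y[i] <- y[i - 1] + rnorm(1, 0, step / 2)
    while (x[i] < 0 || x[i] > L) x[i] <- ifelse(x[i] < 0, -x[i], 2 * L - x[i])
    while (y[i] < 0 || y[i] > W) y[i] <- ifelse(y[i] < 0, -y[i], 2 * W - y[i])
  }
  trajectory(seq(0, by = dt_s, length.out = n), x, y, config,
             fly_id = fly_id)
}

# a stationary fly with optional positional jitter
still_traj <- function(n, x0 = 10, y0 = 3, jitter = 0, seed = 1,
                       config = cfg_12(), fly_id = "still1") {
  set.seed(seed)
  trajectory(seq_len(n) - 1, x0 + rnorm(n, 0, jitter),
             y0 + rnorm(n, 0, jitter), config, fly_id = fly_id)
}

# long-format activity series from a per-minute value vector
series_from_counts <- function(counts, fly_id = "f1", bin_min = 1) {
  out <- data.table(fly_id = fly_id,
                    zt_min = (seq_along(counts) - 1) * bin_min,
                    counts = as.integer(counts))
  setattr(out, "bin_min", bin_min)
  out
}

# write a synthetic Trikinetics monitor file; counts: bins x channels
write_dam_fixture <- function(counts, path = tempfile(fileext = ".txt"),
                              start = "2024-01-08 09:00:00", bin_s = 60) {
  write_dam(as.matrix(counts), path, start = start, bin_s = bin_s)
  path
}

# --- independent brute-force oracles ----------------------------------------

# midline-crossing count per DAM bin: explicit frame loop with the
# touch-once-on-leaving rule
brute_crossings <- function(traj, config, bin_s = config$dam_bin_s) {
  mid <- config$arena_length_mm / 2
  v <- traj[traj$valid, ]
  t0 <- traj$t_s[1]
  nbin <- floor((traj$t_s[nrow(traj)] - t0) / bin_s) + 1
  counts <- integer(nbin)
  for (i in seq_len(nrow(v))) {
    if (i == 1) next
    s <- sign(v$x_mm[i] - mid)
    s_prev <- sign(v$x_mm[i - 1] - mid)
    # count on the frame leaving the previous side; an exact midline
    # touch counts once, on the leaving frame, whichever side it leaves to
    if (s != 0 && (s_prev == 0 || s != s_prev)) {
      b <- floor((v$t_s[i] - t0) / bin_s) + 1
      counts[b] <- counts[b] + 1L
    }
  }
  counts
}

# maximal-run sleep scanner: explicit loop over minute flags
brute_sleep_runs <- function(flags, min_len = 5) {
  runs <- list()
  start <- NA
  for (i in seq_along(flags)) {
    ok <- !is.na(flags[i]) && flags[i]
    if (ok && is.na(start)) start <- i
    if (!ok && !is.na(start)) {
      if (i - start >= min_len) runs[[length(runs) + 1]] <- c(start, i)
      start <- NA
    }
  }
  if (!is.na(start) && length(flags) + 1 - start >= min_len)
    runs[[length(runs) + 1]] <- c(start, length(flags) + 1)
  if (!length(runs)) return(data.table(start = integer(0), end = integer(0)))
  m <- do.call(rbind, runs)
  data.table(start = m[, 1], end = m[, 2])
}

# naive day-fold-and-average cohort profile with circular moving average
brute_profile <- function(series, smooth_min = 0, bin_min = 1) {
  flies <- unique(series$fly_id)
  nb <- 1440 / bin_min
  mat <- matrix(NA_real_, length(flies), nb)
  for (k in seq_along(flies)) {
    s <- series[series$fly_id == flies[k], ]
    days <- unique(s$zt_min %/% 1440)
    prof <- rep(0, nb); nd <- 0
    for (d in days) {
      sd_ <- s[s$zt_min %/% 1440 == d, ]
      if (nrow(sd_) == nb) {
        prof <- prof + sd_$counts[order(sd_$zt_min %% 1440)]
        nd <- nd + 1
      }
    }
    if (nd > 0) mat[k, ] <- prof / nd
  }
  mu <- colMeans(mat, na.rm = TRUE)
  if (smooth_min > 0) {
    w <- round(smooth_min / bin_min); if (w %% 2 == 0) w <- w + 1
    h <- (w - 1) / 2
    ext <- c(tail(mu, h), mu, head(mu, h))
    mu <- vapply(seq_len(nb), function(i) mean(ext[i:(i + w - 1)]),
                 numeric(1))
  }
  mu
}
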