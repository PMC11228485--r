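# Zone occupancy and preference indices.  PI = (time in zone A - time in
# zone B) / (time in A + time in B), so values > 0 indicate preference
# for zone A (the shaded/red zone by convention) and values < 0 for zone
# B.  The difference-over-sum form is the standard place-preference
# index; it is bounded in [-1, 1] with 0 = indifference.

#' Assign each trajectory frame to a lighting zone
#'
#' Zone membership is determined solely by x relative to
#' `config$zone_boundary_mm`; a frame exactly on the boundary belongs to
#' zone A (documented tie-break).  Invalid frames are missing.
#'
#' @param traj Trajectory `data.table` (one or more flies).
#' @param config An [experiment_config()].
#' @return `data.table` with `fly_id`, `t_s`, `zone` (zone label or NA);
#'   attributes `zone_labels` and `dt_s`.
#' @export
assign_zones <- function(traj, config) {
  dt <- as.data.table(traj)
  zl <- config$zone_labels
  out <- dt[, .(fly_id, t_s,
                zone = ifelse(!valid, NA_character_,
                              ifelse(x_mm <= config$zone_boundary_mm,
                                     zl[1], zl[2])))]
  setattr(out, "zone_labels", zl)
  setattr(out, "dt_s", infer_dt(dt[fly_id == fly_id[1]]))
  out[]
}

#' Zone preference index over time
#'
#' PI per time bin and fly: `(t_A - t_B) / (t_A + t_B)` over the frames
#' in the bin.  Missing frames are excluded from both terms; bins with no
#' tracked frame are missing.
#'
#' @param zones Output of [assign_zones()].
#' @param bin_min Bin width in minutes.
#' @param start_zt_min ZT of the first frame, minutes.
#' @param zone_a Label whose occupancy counts positively (so relabelling
#'   the physical sides negates the index); defaults to the first
#'   configured zone label.
#' @return `data.table` with `fly_id`, `zt_min` (bin start), `pi_value`,
#'   `n_frames`.
#' @export
shade_pi <- function(zones, bin_min = 30, start_zt_min = 0,
                     zone_a = attr(zones, "zone_labels")[1]) {
  if (bin_min < 1) stop("bin_min must be >= 1")
  zl <- attr(zones, "zone_labels")
  zone_b <- setdiff(zl, zone_a)
  dt <- as.data.table(zones)
  dt[, bin := start_zt_min + floor(t_s / 60 / bin_min) * bin_min]
  out <- dt[, {
    a <- sum(zone == zone_a, na.rm = TRUE)
    b <- sum(zone %in% zone_b, na.rm = TRUE)
    .(pi_value = if (a + b == 0) NA_real_ else (a - b) / (a + b),
      n_frames = a + b)
  }, by = .(fly_id, zt_min = bin)]
  setorder(out, fly_id, zt_min)
  out[]
}

#' Sleep preference index per fly and time-of-day window
#'
#' PI over sleep-bout minutes: `(sleep_A - sleep_B) / (sleep_A +
#' sleep_B)`, where a bout contributes its minutes to the zone of its
#' rest location.  Windows are time-of-day intervals (ZT hours) folded
#' across days, e.g. the convention early day `[0, 6)`, late day
#' `[6, 12)`, early night `[12, 18)`, late night `[18, 24)`.  Flies with
#' no zoned sleep in a window are missing.
#'
#' @param bouts Zone-annotated bouts ([score_sleep()] with a trajectory).
#' @param windows_h Named list of `c(start, end)` ZT-hour windows, or a
#'   single `c(start, end)`.
#' @param zone_a Label of zone A (PI > 0 means preference for it);
#'   defaults to the first zone label found.
#' @return `data.table` with `fly_id`, `window`, `pi_value`,
#'   `sleep_a_min`, `sleep_b_min`.
#' @export
sleep_pi <- function(bouts, windows_h = list(day = c(0, 12)),
                     zone_a = NULL) {
  if (!is.list(windows_h)) windows_h <- list(window = windows_h)
  if (is.null(names(windows_h)))
    names(windows_h) <- paste0("w", seq_along(windows_h))
  bdt <- as.data.table(bouts)
  if (!"zone" %in% names(bdt)) stop("bouts must carry a zone column")
  zl <- unique(stats::na.omit(bdt$zone))
  if (is.null(zone_a)) zone_a <- zl[1]
  zone_b <- setdiff(zl, zone_a)
  rbindlist(lapply(names(windows_h), function(wn) {
    w <- windows_h[[wn]] * 60
    ov <- folded_overlap_min(bdt$start_zt_min, bdt$end_zt_min, w[1], w[2])
    bdt2 <- copy(bdt)[, ov_min := ov]
    bdt2[, {
      a <- sum(ov_min[zone == zone_a], na.rm = TRUE)
      b <- if (length(zone_b))
        sum(ov_min[zone %in% zone_b], na.rm = TRUE) else 0
      list(window = wn,
           pi_value = if (a + b == 0) NA_real_ else (a - b) / (a + b),
           sleep_a_min = a, sleep_b_min = b)
    }, by = fly_id]
  }))
}

# minutes of overlap between interval [s, e) (cumulative ZT minutes) and
# the daily window [w1, w2) minutes-of-day, summed across days
folded_overlap_min <- function(s, e, w1, w2) {
  vapply(seq_along(s), function(i) {
    d0 <- floor(s[i] / 1440); d1 <- floor((e[i] - 1e-9) / 1440)
    sum(vapply(d0:d1, function(d)
      max(0, min(e[i], d * 1440 + w2) - max(s[i], d * 1440 + w1)),
      numeric(1)))
  }, numeric(1))
}

#' Time spent in each zone
#'
#' Frame-weighted minutes per zone per fly within a ZT window.
#'
#' @param zones Output of [assign_zones()].
#' @param window_zt_min `c(start, end)` in cumulative ZT minutes.
#' @param start_zt_min ZT of the first frame, minutes.
#' @return `data.table` with `fly_id`, `zone`, `minutes`.
#' @export
time_in_zone <- function(zones, window_zt_min = NULL, start_zt_min = 0) {
  dt_s <- attr(zones, "dt_s")
  dt <- as.data.table(zones)
  dt[, zt := start_zt_min + t_s / 60]
  if (!is.null(window_zt_min))
    dt <- dt[zt >= window_zt_min[1] & zt < window_zt_min[2]]
  dt[!is.na(zone), .(minutes = .N * dt_s / 60), by = .(fly_id, zone)]
}

#' Correlation between movement and shade occupancy across flies
#'
#' Computes, per fly, the total path length and the time spent in the
#' shaded zone within a window, and their Spearman rank correlation with
#' a two-sided permutation p-value (ties handled by average ranks).
#'
#' @param traj Multi-fly trajectory `data.table`.
#' @param zones Output of [assign_zones()] for the same flies.
#' @param window_zt_min Optional `c(start, end)` ZT-minute window.
#' @param n_perm Number of permutations.
#' @param seed RNG seed for the permutation null.
#' @param start_zt_min ZT of the first frame, minutes.
#' @return List with `per_fly` (`fly_id`, `distance_mm`, `shade_min`),
#'   `rho` (Spearman), and `p_perm`.
#' @export
shade_movement_correlation <- function(traj, zones, window_zt_min = NULL,
                                       n_perm = 10000, seed = 1,
                                       start_zt_min = 0) {
  tdt <- as.data.table(traj)
  flies <- unique(tdt$fly_id)
  if (length(flies) < 3) stop("need at least 3 flies")
  zl <- attr(zones, "zone_labels")
  dist_tab <- rbindlist(lapply(split(tdt, by = "fly_id"), function(tr) {
    if (!is.null(window_zt_min)) {
      a <- (window_zt_min[1] - start_zt_min) * 60
      b <- (window_zt_min[2] - start_zt_min) * 60
      tr <- tr[t_s >= a & t_s < b]
    }
    dt_s <- infer_dt(tr)
    i <- valid_pairs(tr, dt_s)
    data.table(fly_id = tr$fly_id[1],
               distance_mm = sum(sqrt((tr$x_mm[i + 1] - tr$x_mm[i])^2 +
                                      (tr$y_mm[i + 1] - tr$y_mm[i])^2)))
  }))
  shade_tab <- time_in_zone(zones, window_zt_min, start_zt_min)
  shade_tab <- shade_tab[zone == zl[1], .(fly_id, shade_min = minutes)]
  per_fly <- shade_tab[dist_tab, on = "fly_id"]
  per_fly[is.na(shade_min), shade_min := 0]
  x <- rank(per_fly$distance_mm); y <- rank(per_fly$shade_min)
  rho <- cor(x, y)
  set.seed(seed)
  null_rho <- replicate(n_perm, cor(x, sample(y)))
  p_perm <- (1 + sum(abs(null_rho) >= abs(rho) - 1e-12)) / (n_perm + 1)
  list(per_fly = per_fly[], rho = rho, p_perm = p_perm)
}
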