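# Sleep scoring by the five-minute rule: a minute is immobile when the
# fly never strays more than the movement threshold (default 3 mm, about
# one body length) from its position at the start of the minute; sleep is
# any maximal run of >= 5 consecutive immobile minutes.

#' Score per-minute immobility from a trajectory
#'
#' A minute `[m, m+1)` is immobile iff the maximum displacement from the
#' minute's first valid position stays below `move_threshold_mm`.
#' Minutes with no valid frame get a missing flag (they later break sleep
#' runs rather than join them).
#'
#' @param traj Trajectory `data.table` (one or more flies).
#' @param move_threshold_mm Movement threshold in mm (default 3).
#' @param start_zt_min ZT of the first frame, minutes.
#' @return `data.table` with `fly_id`, `zt_min` (minute index) and
#'   `immobile` (logical, NA when untracked).
#' @export
score_immobility <- function(traj, move_threshold_mm = 3,
                             start_zt_min = 0) {
  if (move_threshold_mm <= 0) stop("move_threshold_mm must be positive")
  dt <- as.data.table(traj)
  dt[, minute := start_zt_min + floor(t_s / 60)]
  full <- dt[, .(zt_min = seq(min(minute), max(minute))), by = fly_id]
  imm <- dt[valid == TRUE,
            .(immobile = max(sqrt((x_mm - x_mm[1])^2 +
                                  (y_mm - y_mm[1])^2)) < move_threshold_mm),
            by = .(fly_id, minute)]
  out <- imm[full, on = c("fly_id", minute = "zt_min")]
  setnames(out, "minute", "zt_min")
  out[]
}

#' Per-bin immobility from DAM counts
#'
#' For beam-cross data a bin is immobile iff its count is zero.
#'
#' @param series Activity table with a `counts` column.
#' @return `data.table` with `fly_id`, `zt_min`, `immobile`.
#' @export
immobility_from_counts <- function(series) {
  dt <- as.data.table(series)
  dt[, .(fly_id, zt_min, immobile = counts == 0L)]
}

#' Score sleep bouts (five-minute rule)
#'
#' Maximal runs of at least `min_bout_min` consecutive immobile minutes
#' become sleep bouts.  Missing minutes break runs.  Bout boundaries are
#' half-open in minutes: `[start_zt_min, end_zt_min)`.
#'
#' If a trajectory and config are supplied, each bout is annotated with
#' its rest location: `rest_x_mm` (median x over the bout) and `zone`
#' (zone of the median position; the boundary itself belongs to zone A).
#'
#' @param immobility Output of [score_immobility()] or
#'   [immobility_from_counts()].
#' @param min_bout_min Minimum bout length in minutes (default 5).
#' @param traj,config Optional trajectory and [experiment_config()] for
#'   rest-location annotation.
#' @param start_zt_min ZT of the first trajectory frame (must match the
#'   value used for scoring).
#' @return `data.table` with `fly_id`, `start_zt_min`, `end_zt_min`,
#'   `duration_min`, and (when located) `rest_x_mm`, `zone`.
#' @export
score_sleep <- function(immobility, min_bout_min = 5, traj = NULL,
                        config = NULL, start_zt_min = 0) {
  dt <- as.data.table(immobility)
  setorder(dt, fly_id, zt_min)
  bouts <- dt[, {
    flag <- !is.na(immobile) & immobile
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_bout_min
    .(start_zt_min = zt_min[starts[keep]],
      end_zt_min = zt_min[ends[keep]] + 1)
  }, by = fly_id]
  bouts[, duration_min := end_zt_min - start_zt_min]
  if (!is.null(traj)) {
    if (is.null(config)) stop("config needed to assign bout zones")
    tdt <- as.data.table(traj)
    loc <- vapply(seq_len(nrow(bouts)), function(i) {
      f <- bouts$fly_id[i]
      a <- (bouts$start_zt_min[i] - start_zt_min) * 60
      b <- (bouts$end_zt_min[i] - start_zt_min) * 60
      xs <- tdt[fly_id == f & valid == TRUE & t_s >= a & t_s < b, x_mm]
      if (length(xs)) median(xs) else NA_real_
    }, numeric(1))
    bouts[, rest_x_mm := loc]
    bouts[, zone := ifelse(is.na(rest_x_mm), NA_character_,
                           ifelse(rest_x_mm <= config$zone_boundary_mm,
                                  config$zone_labels[1],
                                  config$zone_labels[2]))]
  }
  bouts[]
}

#' Sleep time course
#'
#' Sleep minutes per time bin for each fly, plus the cohort mean and the
#' proportion of flies asleep (any sleep overlap) per bin.
#'
#' @param bouts Output of [score_sleep()].
#' @param bin_min Bin width in minutes.
#' @param span_zt_min `c(first, last)` ZT minute covered; defaults to the
#'   bout range rounded out to whole bins.
#' @param fly_ids Fly universe (flies with no bouts still count toward
#'   cohort proportions); defaults to the flies present in `bouts`.
#' @return List with `per_fly` (`fly_id`, `zt_min`, `sleep_min`) and
#'   `cohort` (`zt_min`, `mean_sleep_min`, `prop_asleep`, `n`).
#' @export
sleep_timecourse <- function(bouts, bin_min = 30, span_zt_min = NULL,
                             fly_ids = NULL) {
  if (bin_min < 1) stop("bin_min must be >= 1")
  bdt <- as.data.table(bouts)
  if (is.null(fly_ids)) fly_ids <- unique(bdt$fly_id)
  if (is.null(span_zt_min)) {
    lo <- floor(min(bdt$start_zt_min) / bin_min) * bin_min
    hi <- ceiling(max(bdt$end_zt_min) / bin_min) * bin_min
  } else {
    lo <- span_zt_min[1]; hi <- span_zt_min[2]
  }
  edges <- seq(lo, hi, by = bin_min)
  starts <- head(edges, -1)
  grid <- data.table(fly_id = rep(fly_ids, each = length(starts)),
                     zt_min = rep(starts, times = length(fly_ids)),
                     sleep_min = 0)
  for (i in seq_len(nrow(bdt))) {
    ov <- pmax(0, pmin(starts + bin_min, bdt$end_zt_min[i]) -
                    pmax(starts, bdt$start_zt_min[i]))
    sel <- grid$fly_id == bdt$fly_id[i]
    grid[sel, sleep_min := sleep_min + ov]
  }
  cohort <- grid[, .(mean_sleep_min = mean(sleep_min),
                     prop_asleep = mean(sleep_min > 0), n = .N),
                 by = zt_min]
  list(per_fly = grid[], cohort = cohort[])
}

#' Total sleep per fly
#'
#' @param bouts Output of [score_sleep()].
#' @return `data.table` with `fly_id` and `total_sleep_min` (the sum of
#'   bout durations).
#' @export
total_sleep <- function(bouts) {
  as.data.table(bouts)[, .(total_sleep_min = sum(duration_min)),
                       by = fly_id]
}
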