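# Circadian activity profiling: day-folded cohort profiles, peak phase,
# morning activity index, day/night totals and temperature-shift
# alignment.

value_column <- function(series) {
  hit <- intersect(c("counts", "speed_mm_s", "value"), names(series))
  if (!length(hit)) stop("series must have a 'counts' or 'speed_mm_s' column")
  hit[1]
}

series_bin_min <- function(series) {
  b <- attr(series, "bin_min")
  if (!is.null(b)) return(b)
  u <- sort(unique(series$zt_min))
  if (length(u) < 2) stop("cannot infer bin size from a single bin")
  median(diff(u))
}

#' Day-folded cohort activity profile
#'
#' Folds each fly's activity onto the 24-h ZT axis (complete days only),
#' averages within fly across days, then reports the cross-fly mean and
#' SEM per bin, in the style of an average actogram.  An optional centered
#' moving average (circular, so ZT 0 and ZT 24 are neighbours) smooths the
#' profile, and `normalize = TRUE` rescales the mean to a maximum of 1
#' (as when speed traces are normalized to peak).
#'
#' @param series Long activity table (`fly_id`, `zt_min`, plus `counts` or
#'   `speed_mm_s`), e.g. rbind-ed outputs of [parse_dam()],
#'   [emulate_dam()] or [speed_series()].
#' @param smooth_min Width of the centered moving average, minutes
#'   (0 = none).
#' @param normalize Rescale the cohort mean to max 1?
#' @return `data.table` with `zt_min` (bin start within the day), `mean`,
#'   `sem`; attributes `n_flies`, `bin_min`, `smooth_min`.
#' @export
daily_profile <- function(series, smooth_min = 0, normalize = FALSE) {
  vc <- value_column(series)
  bin_min <- series_bin_min(series)
  bins_per_day <- as.integer(round(1440 / bin_min))
  dt <- as.data.table(series)[, .(fly_id, zt_min, value = get(vc))]
  dt[, day := zt_min %/% 1440]
  dt[, bin := as.integer(round((zt_min %% 1440) / bin_min))]
  # a day is complete when all of its bins are present
  dt[, n_in_day := .N, by = .(fly_id, day)]
  dt <- dt[n_in_day == bins_per_day]
  if (!nrow(dt)) stop("no complete days in input")
  per_fly <- dt[, .(value = mean(value, na.rm = TRUE)), by = .(fly_id, bin)]
  full <- per_fly[, .N, by = fly_id][N == bins_per_day, fly_id]
  dropped <- setdiff(unique(series$fly_id), full)
  if (length(dropped))
    warning("excluded flies with < 1 complete day: ",
            paste(dropped, collapse = ", "))
  per_fly <- per_fly[fly_id %in% full]
  # a single-fly profile has no cross-fly spread: SEM 0, not undefined
  sem0 <- function(x) if (length(x) < 2) 0 else sd(x) / sqrt(length(x))
  prof <- per_fly[, .(mean = mean(value), sem = sem0(value)), by = bin]
  setorder(prof, bin)
  prof <- prof[data.table(bin = 0:(bins_per_day - 1)), on = "bin"]
  if (smooth_min > 0) {
    w <- max(1L, as.integer(round(smooth_min / bin_min)))
    if (w %% 2 == 0) w <- w + 1L
    prof[, mean := circular_ma(mean, w)]
    prof[, sem := circular_ma(sem, w)]
  }
  if (normalize) {
    peak <- max(prof$mean, na.rm = TRUE)
    if (peak > 0) prof[, `:=`(mean = mean / peak, sem = sem / peak)]
  }
  out <- prof[, .(zt_min = bin * bin_min, mean, sem)]
  setattr(out, "n_flies", length(full))
  setattr(out, "bin_min", bin_min)
  setattr(out, "smooth_min", smooth_min)
  out[]
}

circular_ma <- function(x, w) {
  n <- length(x)
  h <- (w - 1L) / 2L
  xx <- c(tail(x, h), x, head(x, h))
  out <- vapply(seq_len(n), function(i)
    mean(xx[i:(i + w - 1L)], na.rm = TRUE), numeric(1))
  out
}

#' Locate the activity peak within a ZT window
#'
#' Smoothed-argmax peak detection (no curve fitting): the peak is the bin
#' with the highest profile mean inside the window, ties broken toward
#' the earliest ZT.  The conventional evening-peak search window is ZT 2
#' to lights-off + 2 h.
#'
#' @param profile Output of [daily_profile()] (smooth before calling;
#'   `smooth_min >= 15` recommended).
#' @param window_h `c(start, end)` in ZT hours, within `[0, 24)`,
#'   half-open.
#' @param kind Label for the peak (`"evening"`, `"midday"`, `"morning"`).
#' @return List with `peak_zt_h` (decimal hours, bin start), `peak_value`,
#'   `peak_kind`, `window_used`.
#' @export
find_peak <- function(profile, window_h = c(0, 24),
                      kind = c("evening", "midday", "morning")) {
  kind <- match.arg(kind)
  if (window_h[1] < 0 || window_h[2] > 24 || window_h[1] >= window_h[2])
    stop("window_h must be an increasing interval within [0, 24]")
  zt_h <- profile$zt_min / 60
  sel <- which(zt_h >= window_h[1] & zt_h < window_h[2])
  vals <- profile$mean[sel]
  if (!length(sel) || all(is.na(vals)) || max(vals, na.rm = TRUE) <= 0)
    stop("no activity in window")
  i <- sel[which.max(vals)]   # which.max takes the first maximum: earliest ZT
  list(peak_zt_h = zt_h[i], peak_value = profile$mean[i],
       peak_kind = kind, window_used = window_h)
}

#' Morning activity index
#'
#' Proportion of daytime activity occurring in the early-day window
#' (default ZT 0-6, per the index definition "proportion of daytime
#' activity occurring from ZT 0 to 6"; an alternative ZT 0-5 convention
#' exists in the literature and can be selected via `morning_window_h`).
#' Undefined (NA) when a fly has no daytime activity.
#'
#' @param series Long activity table.
#' @param day_window_h Full photoperiod window in ZT hours (e.g. `c(0,
#'   16)` for 16L:8D).
#' @param morning_window_h Early-day window nested in `day_window_h`.
#' @return `data.table` with `fly_id` and `morning_index` in `[0, 1]`.
#' @export
morning_activity_index <- function(series, day_window_h,
                                   morning_window_h = c(0, 6)) {
  if (morning_window_h[1] < day_window_h[1] ||
      morning_window_h[2] > day_window_h[2])
    stop("morning window must be nested in the day window")
  vc <- value_column(series)
  dt <- as.data.table(series)[, .(fly_id, zt = zt_min %% 1440,
                                  value = get(vc))]
  dt[, `:=`(in_day = zt >= day_window_h[1] * 60 & zt < day_window_h[2] * 60,
            in_morning = zt >= morning_window_h[1] * 60 &
              zt < morning_window_h[2] * 60)]
  dt[, .(morning_index = {
    den <- sum(value[in_day], na.rm = TRUE)
    if (is.na(den) || den == 0) NA_real_
    else sum(value[in_morning], na.rm = TRUE) / den
  }), by = fly_id]
}

#' Daytime, nighttime and total activity per fly
#'
#' Totals per 24-h day, averaged across complete days.  The light
#' interval is `[ZT 0, photoperiod)`.
#'
#' @param series Long activity table.
#' @param schedule An [ld_schedule()] supplying the photoperiod.
#' @return `data.table` with `fly_id`, `light`, `dark`, `total`.
#' @export
day_night_totals <- function(series, schedule) {
  vc <- value_column(series)
  bin_min <- series_bin_min(series)
  bins_per_day <- as.integer(round(1440 / bin_min))
  dt <- as.data.table(series)[, .(fly_id, zt_min, value = get(vc))]
  dt[, day := zt_min %/% 1440]
  dt[, n_in_day := .N, by = .(fly_id, day)]
  dt <- dt[n_in_day == bins_per_day]
  if (!nrow(dt)) stop("no complete days in input")
  dt[, light := (zt_min %% 1440) < schedule$photoperiod_h * 60]
  per_day <- dt[, .(light_tot = sum(value[light], na.rm = TRUE),
                    dark_tot = sum(value[!light], na.rm = TRUE)),
                by = .(fly_id, day)]
  per_day[, .(light = mean(light_tot), dark = mean(dark_tot),
              total = mean(light_tot + dark_tot)), by = fly_id]
}

#' Activity profiles aligned to a step change
#'
#' Returns day-folded profiles for the 24 h before a shift (e.g. a rapid
#' temperature change at ZT 6 of a recording day) and for the first and
#' second 24 h after it, with identical binning, so the re-alignment of
#' the activity rhythm can be compared across the shift.
#'
#' @param series Long activity table.
#' @param shift_zt_min The shift instant in cumulative ZT minutes.
#' @return Named list of [daily_profile()] outputs: `before`, `after1`,
#'   and `after2` when a second post-shift day is available.
#' @export
shift_response <- function(series, shift_zt_min) {
  dt <- as.data.table(series)
  lo <- min(dt$zt_min); hi <- max(dt$zt_min)
  if (shift_zt_min - 1440 < lo || shift_zt_min + 1440 > hi + 1e-9)
    stop("recording must span at least one full day on each side of the shift")
  slice <- function(a, b) {
    s <- dt[zt_min >= a & zt_min < b]
    s[, zt_min := zt_min - a]        # re-anchor so the slice folds as one day
    for (at in c("bin_min")) setattr(s, at, attr(series, at))
    daily_profile(s)
  }
  out <- list(before = slice(shift_zt_min - 1440, shift_zt_min),
              after1 = slice(shift_zt_min, shift_zt_min + 1440))
  if (shift_zt_min + 2880 <= hi + series_bin_min(series))
    out$after2 <- slice(shift_zt_min + 1440, shift_zt_min + 2880)
  out
}

sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  sd(x) / sqrt(length(x))
}
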