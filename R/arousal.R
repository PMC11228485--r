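# Arousal-threshold analysis.  A fly enters a trial when it has been
# immobile for at least min_immobility_s at stimulus-train onset; arousal
# is scored as the first pulse whose response window contains a
# displacement of >= move_threshold_mm (default 3 mm, about one body
# length) from the fly's pre-stimulus position.

#' Score arousal trials against a stimulus schedule
#'
#' For each stimulus train, determines whether the fly was immobile at
#' train onset, for how long, whether and at which pulse it responded,
#' and the sleep latency of responders.
#'
#' Immobility is anchored to the fly's position on the last valid frame
#' before train onset: the fly has been immobile since the earliest frame
#' from which it never strayed `move_threshold_mm` from that anchor
#' (backward scan, capped at `lookback_s`; durations at the cap are
#' right-censored).  The response window of pulse k runs from its onset
#' to the onset of pulse k+1 (for the last pulse: onset + pulse length +
#' interpulse gap).  The latency clock starts at the first response frame
#' and stops at the rest onset of the next scored sleep bout; because
#' trajectories carry frame-level resolution, the rest onset is refined
#' from the bout's first minute to the actual frame at which the fly
#' settled (backward scan from the bout start while the fly stays within
#' `move_threshold_mm` of its bout position), which removes the
#' minute-grid quantization from latency estimates.
#'
#' @param traj Trajectory `data.table` (one or more flies).
#' @param schedule A [stimulus_schedule()].
#' @param bouts Scored sleep bouts from [score_sleep()] for the same
#'   trajectory (used for latency).
#' @param move_threshold_mm Movement/response threshold in mm.
#' @param min_immobility_s Minimum immobility at onset for trial
#'   eligibility (default 5 s, the shortest analysis bin).
#' @param start_zt_min ZT of the first frame, minutes.
#' @param lookback_s Cap on the backward immobility scan (s).
#' @return `data.table`, one row per (fly, train): `fly_id`,
#'   `train_onset_zt_min`, `immobile_at_onset`, `prior_immobility_s`,
#'   `responded`, `pulse_idx`, `threshold_g` (intensity of the first
#'   responding pulse, NA for non-responders), `response_zt_min`,
#'   `latency_min` (NA unless the fly responded and slept again).
#'   Attribute `intensities` carries the delivered per-pulse intensities.
#' @export
arousal_trials <- function(traj, schedule, bouts, move_threshold_mm = 3,
                           min_immobility_s = 5, start_zt_min = 0,
                           lookback_s = 14400) {
  stopifnot(inherits(schedule, "stimulus_schedule"))
  tlen <- train_length_s(schedule)
  onsets_min <- schedule$train_onset_zt_min
  if (length(onsets_min) > 1 && any(diff(onsets_min) * 60 < tlen))
    stop("stimulus trains overlap")
  tdt <- as.data.table(traj)
  bdt <- as.data.table(bouts)
  out <- rbindlist(lapply(split(tdt, by = "fly_id"), function(tr) {
    fb <- bdt[fly_id == tr$fly_id[1]]
    arousal_trials_one(tr, fb, schedule, onsets_min, move_threshold_mm,
                       min_immobility_s, start_zt_min, lookback_s)
  }))
  setattr(out, "intensities", schedule$intensities)
  out[]
}

arousal_trials_one <- function(tr, bouts, schedule, onsets_min,
                               thr, min_imm_s, start_zt_min, lookback_s) {
  t0 <- tr$t_s[1]
  t_end <- tr$t_s[nrow(tr)]
  off <- pulse_offsets_s(schedule)
  tlen <- train_length_s(schedule)
  onset_s <- (onsets_min - start_zt_min) * 60
  inside <- onset_s > t0 & (onset_s + tlen) <= t_end
  if (any(!inside & onset_s >= t0 - tlen & onset_s <= t_end))
    warning("trains with incomplete recording coverage dropped")
  onset_s <- onset_s[inside]
  v <- tr[valid == TRUE]
  res <- lapply(onset_s, function(os) {
    pre <- v[t_s < os & t_s >= os - lookback_s]
    if (!nrow(pre)) return(NULL)
    px <- pre$x_mm[nrow(pre)]; py <- pre$y_mm[nrow(pre)]
    d_pre <- sqrt((pre$x_mm - px)^2 + (pre$y_mm - py)^2)
    mobile <- which(d_pre >= thr)
    # no mobile frame within the lookback: censored at the lookback cap
    prior_s <- if (length(mobile)) os - pre$t_s[max(mobile)] else
      min(os - pre$t_s[1], lookback_s)
    eligible <- prior_s >= min_imm_s
    win <- v[t_s >= os & t_s < os + tlen]
    d_win <- sqrt((win$x_mm - px)^2 + (win$y_mm - py)^2)
    hit <- which(d_win >= thr)
    responded <- eligible && length(hit) > 0
    pulse <- resp_t <- thr_g <- lat <- NA_real_
    if (responded) {
      resp_t <- win$t_s[hit[1]]
      pulse <- findInterval(resp_t - os + 1e-9, off)
      thr_g <- schedule$intensities[pulse]
      lat <- latency_to_next_bout(v, bouts, resp_t, thr, start_zt_min)
    }
    data.table(train_onset_zt_min = start_zt_min + os / 60,
               immobile_at_onset = eligible,
               prior_immobility_s = prior_s,
               responded = isTRUE(responded),
               pulse_idx = as.integer(pulse),
               threshold_g = thr_g,
               response_zt_min = start_zt_min + resp_t / 60,
               latency_min = lat)
  })
  out <- rbindlist(res[!vapply(res, is.null, logical(1))])
  if (nrow(out)) {
    out[, fly_id := tr$fly_id[1]]
    setcolorder(out, "fly_id")
  }
  out
}

# frame-resolution latency: time from the response frame to the settled
# rest onset of the next scored bout
latency_to_next_bout <- function(v, bouts, resp_t, thr, start_zt_min) {
  if (!nrow(bouts)) return(NA_real_)
  bstart_s <- (bouts$start_zt_min - start_zt_min) * 60
  nxt <- which(bstart_s >= resp_t)
  if (!length(nxt)) return(NA_real_)
  bs <- bstart_s[nxt[1]]
  seg <- v[t_s >= resp_t & t_s <= bs]
  if (!nrow(seg)) return((bs - resp_t) / 60)
  ax <- seg$x_mm[nrow(seg)]; ay <- seg$y_mm[nrow(seg)]
  d <- sqrt((seg$x_mm - ax)^2 + (seg$y_mm - ay)^2)
  mobile <- which(d >= thr)
  onset <- if (length(mobile) && max(mobile) < nrow(seg))
    seg$t_s[max(mobile) + 1] else if (length(mobile)) bs else resp_t
  max(onset - resp_t, 0) / 60
}

#' Arousal threshold vs. prior immobility
#'
#' Bins eligible trials by immobility duration at train onset and reports
#' the mean delivered intensity of the first responding pulse per bin.
#' Non-responding trials either contribute the maximum delivered
#' intensity as a right-censored value (`censored = "max"`, the default)
#' or are excluded (`censored = "drop"`); the choice matters because how
#' non-responders enter such averages is a reporting convention.
#'
#' Default bins: 5-15 s, 15-60 s, 1-5 min, 5-10 min, 10-60 min,
#' 60-90 min, 90-120 min, > 120 min.
#'
#' @param trials Output of [arousal_trials()].
#' @param breaks_s Left-closed bin edges in seconds (last bin open).
#' @param censored `"max"` or `"drop"`.
#' @param max_intensity Censoring value; defaults to the maximum delivered
#'   intensity recorded on `trials`.
#' @return `data.table` with `bin` (label), `immobility_lo_s`,
#'   `immobility_hi_s`, `mean_threshold_g`, `sem`, `n` (empty bins are
#'   reported with NA mean).
#' @export
threshold_vs_immobility <- function(trials,
                                    breaks_s = c(5, 15, 60, 300, 600,
                                                 3600, 5400, 7200, Inf),
                                    censored = c("max", "drop"),
                                    max_intensity = NULL) {
  censored <- match.arg(censored)
  if (is.unsorted(breaks_s, strictly = TRUE))
    stop("breaks_s must be strictly increasing")
  if (is.null(max_intensity)) {
    ints <- attr(trials, "intensities")
    max_intensity <- if (!is.null(ints)) max(ints) else
      max(trials$threshold_g, na.rm = TRUE)
  }
  dt <- as.data.table(trials)[immobile_at_onset == TRUE]
  dt[, value := ifelse(responded, threshold_g, max_intensity)]
  if (censored == "drop") dt <- dt[responded == TRUE]
  dt <- dt[prior_immobility_s >= breaks_s[1]]
  dt[, bin := cut(prior_immobility_s, breaks_s, right = FALSE)]
  agg <- dt[, .(mean_threshold_g = mean(value), sem = sem(value),
                n = .N), by = bin]
  lo <- head(breaks_s, -1); hi <- tail(breaks_s, -1)
  frame <- data.table(bin = cut(lo, breaks_s, right = FALSE),
                      immobility_lo_s = lo, immobility_hi_s = hi)
  out <- agg[frame, on = "bin"]
  out[is.na(n), n := 0L]
  setcolorder(out, c("bin", "immobility_lo_s", "immobility_hi_s"))
  out[]
}

#' Proportion of flies responding, by time of day
#'
#' @param trials Output of [arousal_trials()] (eligible trials only are
#'   used).
#' @param bin_zt_h ZT bin width in hours.
#' @return `data.table` with `zt_h` (bin start), `prop_responding`,
#'   `ci_lo`, `ci_hi` (exact binomial 95% CI), `n_trials`.
#' @export
responder_proportion <- function(trials, bin_zt_h = 2) {
  dt <- as.data.table(trials)[immobile_at_onset == TRUE]
  dt[, zt_h := (train_onset_zt_min / 60) %% 24]
  dt[, bin := floor(zt_h / bin_zt_h) * bin_zt_h]
  dt[, {
    k <- sum(responded); n <- .N
    ci <- binom.test(k, n)$conf.int
    .(prop_responding = k / n, ci_lo = ci[1], ci_hi = ci[2], n_trials = n)
  }, by = .(zt_h = bin)][order(zt_h)]
}

#' Cohort speed time course around stimulus trains
#'
#' Mean walking speed per second, aligned to train onset, separately for
#' daytime trains (onset in `day_window_h`, default ZT 0-10) and
#' nighttime trains (default ZT 12-22).  With `normalize = TRUE` each
#' phase's time course is divided by its mean pre-stimulus speed.
#'
#' @param traj Trajectory `data.table` (one or more flies).
#' @param schedule A [stimulus_schedule()].
#' @param window_min Minutes after train onset to keep (must cover the
#'   train).
#' @param pre_min Minutes before onset to keep.
#' @param normalize Normalize to the pre-stimulus mean?
#' @param day_window_h,night_window_h ZT windows assigning trains to
#'   phases; trains outside both are ignored.
#' @param start_zt_min ZT of the first frame, minutes.
#' @return `data.table` with `phase` (`"day"`/`"night"`), `rel_s`
#'   (seconds from train onset), `mean_speed`, `n` (fly-train traces
#'   contributing).
#' @export
post_stimulus_kinetics <- function(traj, schedule, window_min = 16,
                                   pre_min = 2, normalize = FALSE,
                                   day_window_h = c(0, 10),
                                   night_window_h = c(12, 22),
                                   start_zt_min = 0) {
  if (window_min * 60 < train_length_s(schedule))
    stop("window_min must cover the stimulus train")
  tdt <- as.data.table(traj)
  pieces <- lapply(split(tdt, by = "fly_id"), function(tr) {
    dt_s <- infer_dt(tr)
    i <- valid_pairs(tr, dt_s)
    sp <- data.table(
      t_s = tr$t_s[i],
      speed = sqrt((tr$x_mm[i + 1] - tr$x_mm[i])^2 +
                   (tr$y_mm[i + 1] - tr$y_mm[i])^2) / dt_s)
    onset_s <- (schedule$train_onset_zt_min - start_zt_min) * 60
    zt_h <- (schedule$train_onset_zt_min / 60) %% 24
    phase <- rep(NA_character_, length(onset_s))
    phase[zt_h >= day_window_h[1] & zt_h < day_window_h[2]] <- "day"
    phase[zt_h >= night_window_h[1] & zt_h < night_window_h[2]] <- "night"
    ok <- !is.na(phase) & onset_s - pre_min * 60 >= tr$t_s[1] &
      onset_s + window_min * 60 <= tr$t_s[nrow(tr)]
    if (any(!is.na(phase) & !ok))
      warning("trains with incomplete windows dropped")
    rbindlist(lapply(which(ok), function(j) {
      seg <- sp[t_s >= onset_s[j] - pre_min * 60 &
                t_s < onset_s[j] + window_min * 60]
      seg[, .(phase = phase[j],
              rel_s = round(t_s - onset_s[j]), speed)]
    }))
  })
  all <- rbindlist(pieces)
  if (!nrow(all)) stop("no usable trains in recording")
  out <- all[, .(mean_speed = mean(speed), n = .N), by = .(phase, rel_s)]
  setorder(out, phase, rel_s)
  if (normalize) {
    out[, mean_speed := mean_speed / mean(mean_speed[rel_s < 0]),
        by = phase]
  }
  out[]
}

#' Exponential decay constant of the post-stimulus speed transient
#'
#' Log-linear regression of the baseline-subtracted mean speed over a
#' post-peak fitting window: `speed(t) = baseline + A * exp(-t / tau)`.
#'
#' @param kinetics Output of [post_stimulus_kinetics()] (unnormalized).
#' @param phase `"day"` or `"night"`.
#' @param fit_window_s `c(from, to)` seconds after onset to fit over
#'   (start after the stimulus train ends).
#' @param baseline Baseline speed; defaults to the pre-stimulus mean.
#' @return Decay constant tau in minutes.
#' @export
startle_decay_constant <- function(kinetics, phase = "day",
                                   fit_window_s = NULL, baseline = NULL) {
  k <- as.data.table(kinetics)
  k <- k[k$phase == phase]
  if (!nrow(k)) stop("phase not present in kinetics")
  if (is.null(baseline)) baseline <- mean(k[rel_s < 0, mean_speed])
  if (is.null(fit_window_s)) {
    pk <- k[rel_s >= 0][which.max(mean_speed), rel_s]
    fit_window_s <- c(pk, max(k$rel_s))
  }
  f <- k[rel_s >= fit_window_s[1] & rel_s <= fit_window_s[2]]
  f <- f[mean_speed - baseline > 0]
  if (nrow(f) < 3) stop("too few points above baseline to fit a decay")
  co <- stats::coef(lm(log(mean_speed - baseline) ~ rel_s, data = f))
  -1 / co[[2]] / 60
}

#' Sleep latency by time of day
#'
#' Mean latency (response to next sleep bout) of responding trials per ZT
#' bin, or aggregated by day/night phase.
#'
#' @param trials Output of [arousal_trials()].
#' @param bin_zt_h ZT bin width in hours.
#' @param by_phase If `TRUE`, aggregate into day `[ZT 0, 12)` vs. night
#'   `[ZT 12, 24)` instead of ZT bins.
#' @return `data.table` with `zt_h` (or `phase`), `mean_latency_min`,
#'   `sem`, `n`.
#' @export
sleep_latency_profile <- function(trials, bin_zt_h = 2, by_phase = FALSE) {
  dt <- as.data.table(trials)[responded == TRUE & !is.na(latency_min)]
  if (!nrow(dt)) stop("no responding trials with defined latency")
  dt[, zt_h := (train_onset_zt_min / 60) %% 24]
  if (by_phase) {
    dt[, phase := ifelse(zt_h < 12, "day", "night")]
    return(dt[, .(mean_latency_min = mean(latency_min),
                  sem = sem(latency_min), n = .N), by = phase][order(phase)])
  }
  dt[, bin := floor(zt_h / bin_zt_h) * bin_zt_h]
  dt[, .(mean_latency_min = mean(latency_min), sem = sem(latency_min),
         n = .N), by = .(zt_h = bin)][order(zt_h)]
}
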