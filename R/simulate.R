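# Synthetic fly generator.  The regime defaults emulate the qualitative
# warm (25 C) vs. diapause (10 C) behavioral signatures: crepuscular
# bimodal activity with a midday siesta vs. a single mid-to-late-day peak;
# an immobility-dependent arousal-threshold curve that at 25 C rises
# ~10-fold between 5 and 10 min of immobility, peaks at 60-90 min and then
# declines, while at 10 C it exceeds the warm peak within 0.25-1 min and
# stays elevated beyond 2 h; short re-sleep latency in the cold; and
# shade-biased resting in the warm that dissipates in the cold.  The node
# values are package defaults chosen for these shapes; they are NOT fitted
# to any real recording.

#' Generative parameters for the synthetic fly
#'
#' @param regime `"warm25"`, `"cold10"`, or `"custom"` (start from warm
#'   defaults and override).
#' @param ... Named overrides of individual fields:
#'   \describe{
#'   \item{circadian_bumps}{3-column matrix `(center_zt_h, width_h,
#'     amplitude)` defining the circadian wake drive C(t) as a sum of
#'     circular Gaussians on the 24-h ZT axis.}
#'   \item{homeostat_rise_per_h, homeostat_decay_per_h}{sleep-pressure
#'     rates while awake / asleep (H is clamped to [0, 1]).}
#'   \item{trans_w2r}{`c(b0, bH, bC)` logistic weights of the per-minute
#'     rest-entry hazard `plogis(b0 + bH*H - bC*C)`.}
#'   \item{trans_r2w_per_min}{baseline spontaneous wake rate (1/min).}
#'   \item{threshold_nodes}{2-column matrix `(immobility_s, threshold_g)`,
#'     increasing in immobility; theta(d) interpolates linearly in log
#'     immobility.}
#'   \item{response_prob_slope}{logistic slope (1/g) of the response
#'     probability around theta; `Inf` gives a hard threshold (a pulse at
#'     exactly theta responds).}
#'   \item{post_startle_peak_mm_s, post_startle_decay_min}{peak speed after
#'     an evoked response and its exponential decay constant.}
#'   \item{resleep_latency_mean_min}{mean of the exponential re-sleep
#'     latency after an evoked response.}
#'   \item{shade_logit}{`c(A, kappa)`: rest episodes settle in the shaded
#'     zone with probability `plogis(A - kappa * H)`.}
#'   \item{step_sd_mm}{random-walk step SD per frame while awake.}
#'   \item{jitter_sd_mm}{micro-jitter SD around the rest position (a
#'     stand-in for unquantified micro-movements; exercises the
#'     immobility-threshold logic).}
#'   \item{H0}{initial sleep pressure.}
#'   \item{seed}{default RNG seed used by [simulate_fly()].}
#'   }
#' @return An object of class `sim_params`.
#' @examples
#' p <- sim_params("cold10")
#' p$resleep_latency_mean_min
#' @export
sim_params <- function(regime = c("warm25", "cold10", "custom"), ...) {
  regime <- match.arg(regime)
  base <- list(
    regime = regime,
    circadian_bumps = rbind(c(0.7, 1.2, 0.9),
                            c(14.5, 1.8, 1.2)),
    homeostat_rise_per_h = 0.12,
    homeostat_decay_per_h = 0.30,
    trans_w2r = c(b0 = -1.0, bH = 3.0, bC = 4.0),
    trans_r2w_per_min = 0.02,
    threshold_nodes = cbind(immobility_s = c(5, 300, 600, 4500, 7200),
                            threshold_g = c(0.35, 0.35, 3.5, 3.8, 2.6)),
    response_prob_slope = 10,
    post_startle_peak_mm_s = 3.5,
    post_startle_decay_min = 4,
    resleep_latency_mean_min = 25,
    shade_logit = c(A = 4.5, kappa = 1.5),
    step_sd_mm = 2.8,
    jitter_sd_mm = 0.1,
    H0 = 0.5,
    seed = 1L)
  if (regime == "cold10") {
    base$circadian_bumps <- rbind(c(9.5, 2.5, 0.9))
    base$trans_w2r <- c(b0 = 1.5, bH = 3.0, bC = 4.0)
    base$trans_r2w_per_min <- 0.004
    base$threshold_nodes <- cbind(
      immobility_s = c(5, 15, 20, 60, 9000),
      threshold_g = c(0.7, 1.2, 5.0, 5.2, 5.4))
    base$post_startle_peak_mm_s <- 3.0
    base$post_startle_decay_min <- 0.5
    base$resleep_latency_mean_min <- 2
    base$shade_logit <- c(A = 0.05, kappa = 0.3)
    base$step_sd_mm <- 2.0
    base$H0 <- 0.3
  }
  over <- list(...)
  unknown <- setdiff(names(over), names(base))
  if (length(unknown))
    stop("unknown sim_params fields: ", paste(unknown, collapse = ", "))
  base[names(over)] <- over
  nodes <- base$threshold_nodes
  if (is.unsorted(nodes[, 1], strictly = TRUE))
    stop("threshold_nodes must be strictly increasing in immobility_s")
  rates <- c(base$homeostat_rise_per_h, base$homeostat_decay_per_h,
             base$trans_r2w_per_min)
  if (any(rates < 0)) stop("rates must be non-negative")
  structure(base, class = "sim_params")
}

#' Generative arousal-threshold curve theta(d)
#'
#' Linear interpolation of the threshold nodes in log immobility, clamped
#' at the end nodes.
#'
#' @param params A [sim_params()] object.
#' @param immobility_s Immobility durations (s).
#' @return Thresholds in g units.
#' @export
threshold_curve <- function(params, immobility_s) {
  nodes <- params$threshold_nodes
  out <- approx(log(nodes[, 1]), nodes[, 2],
                xout = log(pmax(immobility_s, nodes[1, 1])),
                rule = 2)$y
  out
}

# expand a stimulus schedule into per-pulse vectors for the C++ core
build_pulse_table <- function(schedule, total_s) {
  if (is.null(schedule))
    return(list(pulse_t_s = numeric(0), pulse_g = numeric(0),
                pulse_train = integer(0), pulse_idx = integer(0),
                n_trains = 0L))
  onsets_s <- schedule$train_onset_zt_min * 60
  keep <- onsets_s >= 0 & (onsets_s + train_length_s(schedule)) <= total_s
  onsets_s <- onsets_s[keep]
  off <- pulse_offsets_s(schedule)
  k <- schedule$pulses_per_train
  list(pulse_t_s = as.numeric(outer(off, onsets_s, `+`)),
       pulse_g = rep(schedule$intensities, times = length(onsets_s)),
       pulse_train = rep(seq_along(onsets_s), each = k),
       pulse_idx = rep(seq_len(k), times = length(onsets_s)),
       n_trains = length(onsets_s),
       onset_s = onsets_s)
}

#' Simulate one fly
#'
#' Forward-simulates the two-process model at the frame rate in `config`,
#' starting at ZT 0 (lights-on), and returns both the observable
#' trajectory and the generative ground truth.  Identical `(params, seed)`
#' give identical output.
#'
#' @param params A [sim_params()] object.
#' @param config An [experiment_config()].
#' @param schedule Optional [stimulus_schedule()]; `NULL` for undisturbed
#'   recordings.
#' @param days Number of 24-h days to simulate (>= 1).
#' @param seed RNG seed; defaults to `params$seed`.
#' @param fly_id Identifier.
#' @return A list with elements
#'   \describe{
#'   \item{trajectory}{frame-level `data.table` (see [trajectory()]).}
#'   \item{truth}{list with `state` (integer per frame, 0 wake / 1 rest),
#'     `H` (sleep pressure per frame), `episodes` (`data.table`: rest
#'     episode start, zone, settle probability, H at entry) and
#'     `responses` (`data.table`: one row per stimulus train with the
#'     generative trial outcome).}
#'   \item{params, config, schedule, seed, days}{inputs, for provenance.}
#'   }
#' @export
simulate_fly <- function(params, config, schedule = NULL, days = 1,
                         seed = params$seed, fly_id = "fly1") {
  stopifnot(inherits(params, "sim_params"),
            inherits(config, "experiment_config"))
  if (days < 1) stop("days must be >= 1")
  dt_s <- 1 / config$frame_rate_hz
  n_steps <- as.integer(round(days * 86400 / dt_s))
  total_s <- n_steps * dt_s
  pulses <- build_pulse_table(schedule, total_s)

  cpar <- list(
    bump_center = params$circadian_bumps[, 1],
    bump_width = params$circadian_bumps[, 2],
    bump_amp = params$circadian_bumps[, 3],
    rho_w = params$homeostat_rise_per_h,
    rho_s = params$homeostat_decay_per_h,
    b0 = unname(params$trans_w2r[1]),
    bH = unname(params$trans_w2r[2]),
    bC = unname(params$trans_w2r[3]),
    r2w_per_min = params$trans_r2w_per_min,
    theta_d = params$threshold_nodes[, 1],
    theta_g = params$threshold_nodes[, 2],
    response_slope = params$response_prob_slope,
    startle_peak_mm_s = params$post_startle_peak_mm_s,
    startle_decay_min = params$post_startle_decay_min,
    resleep_mean_min = params$resleep_latency_mean_min,
    shade_A = unname(params$shade_logit[1]),
    shade_kappa = unname(params$shade_logit[2]),
    step_sd_mm = params$step_sd_mm,
    jitter_sd_mm = params$jitter_sd_mm,
    H0 = params$H0)
  ccfg <- list(dt_s = dt_s,
               arena_length_mm = config$arena_length_mm,
               arena_width_mm = config$arena_width_mm,
               zone_boundary_mm = config$zone_boundary_mm)

  set.seed(seed)
  raw <- sim_fly_cpp(cpar, ccfg, pulses, n_steps)

  traj <- data.table(fly_id = fly_id,
                     t_s = (seq_len(n_steps) - 1) * dt_s,
                     x_mm = raw$x_mm, y_mm = raw$y_mm, valid = TRUE)
  zl <- config$zone_labels
  episodes <- data.table(
    start_s = raw$ep_start_s,
    zone = zl[raw$ep_zone + 1L],
    p_shade = raw$ep_p_shade,
    H_entry = raw$ep_H)
  responses <- data.table(
    train = seq_len(pulses$n_trains),
    train_onset_s = if (pulses$n_trains) pulses$onset_s else numeric(0),
    resting_at_onset = as.logical(raw$tr_resting),
    prior_immobility_s = raw$tr_prior_immobility_s,
    responded = raw$tr_responded == 1L,
    pulse = raw$tr_pulse,
    response_s = raw$tr_response_s,
    latency_draw_min = raw$tr_latency_min)

  list(trajectory = traj,
       truth = list(state = raw$state, H = raw$H,
                    episodes = episodes, responses = responses),
       params = params, config = config, schedule = schedule,
       seed = seed, days = days)
}

#' Simulate a cohort of flies
#'
#' Derives an independent sub-seed for each fly deterministically from the
#' master seed, so the same master seed reproduces the cohort exactly.
#'
#' @param params_list Named list of [sim_params()] objects, one per group
#'   (e.g. `list(warm25 = sim_params("warm25"), cold10 =
#'   sim_params("cold10"))`).
#' @param config An [experiment_config()].
#' @param schedule Optional [stimulus_schedule()].
#' @param n_per_group Flies per group (>= 1).
#' @param seed Master seed.
#' @param days Days per fly.
#' @return A list with `flies` (list of [simulate_fly()] results, named by
#'   fly id) and `manifest` (`data.table`: fly_id, group, seed, days).
#' @export
make_cohort <- function(params_list, config, schedule = NULL,
                        n_per_group = 1, seed = 1, days = 1) {
  if (n_per_group < 1) stop("n_per_group must be >= 1")
  if (is.null(names(params_list)) || anyDuplicated(names(params_list)))
    stop("params_list must be uniquely named by group")
  grid <- data.table(
    group = rep(names(params_list), each = n_per_group),
    idx = rep(seq_len(n_per_group), times = length(params_list)))
  grid[, fly_id := sprintf("%s_f%02d", group, idx)]
  if (anyDuplicated(grid$fly_id)) stop("duplicate fly ids")
  grid[, seed_used := derive_seed(seed, .I)]
  flies <- vector("list", nrow(grid))
  names(flies) <- grid$fly_id
  for (i in seq_len(nrow(grid))) {
    flies[[i]] <- simulate_fly(params_list[[grid$group[i]]], config,
                               schedule = schedule, days = days,
                               seed = grid$seed_used[i],
                               fly_id = grid$fly_id[i])
  }
  manifest <- grid[, .(fly_id, group, seed = seed_used, days = days)]
  list(flies = flies, manifest = manifest)
}

#' Derive a per-fly sub-seed from a master seed
#'
#' Deterministic 32-bit-safe mixing; distinct indices give distinct seeds.
#'
#' @param master Master seed (integer).
#' @param index Fly index (1-based).
#' @return Integer seed(s) in `[0, 2^31)`.
#' @export
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 1000003 + as.numeric(index) * 7919) %%
               2147483647)
}

#' Write a simulated cohort to disk
#'
#' Emits one trajectory CSV per fly, an emulated DAM monitor file for the
#' cohort, a ground-truth rest-episode CSV and a JSON manifest.
#'
#' @param cohort Result of [make_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts <- NULL
  for (id in names(cohort$flies)) {
    f <- cohort$flies[[id]]
    fwrite(f$trajectory, file.path(dir, paste0(id, "_trajectory.csv")))
    dam <- emulate_dam(f$trajectory, f$config)
    counts <- cbind(counts, dam$counts)
    ep <- copy(f$truth$episodes)[, fly_id := id]
    fwrite(ep, file.path(dir, paste0(id, "_episodes.csv")))
  }
  nch <- min(ncol(counts), N_DAM_CHANNELS)
  write_dam(counts[, seq_len(nch), drop = FALSE],
            file.path(dir, "monitor.txt"))
  manifest <- cohort$manifest
  writeLines(sprintf(
    '{"fly_id":"%s","group":"%s","seed":%d,"days":%d}',
    manifest$fly_id, manifest$group, manifest$seed, manifest$days),
    file.path(dir, "manifest.jsonl"))
  invisible(dir)
}
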