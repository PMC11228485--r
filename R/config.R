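# Experiment configuration: light-dark schedule, arena geometry, recording
# parameters.  ZT (zeitgeber time) 0 is always defined as lights-on.

#' Light-dark schedule
#'
#' Describes the photic environment of a recording.  ZT 0 is lights-on;
#' lights go off at `photoperiod_h`.
#'
#' @param lights_on Wall-clock time of lights-on, `"HH:MM"` or `"HH:MM:SS"`.
#' @param photoperiod_h Hours of light per 24 h cycle, in (0, 24).
#' @param ramping Logical; `TRUE` for ramped (dawn/dusk style) light designs.
#' @param ramp_peak_lux Peak illuminance of a ramping design (lux).
#' @param spectrum One of `"white"`, `"amber_592nm"`, `"red_612nm"`,
#'   `"blue_445nm"`; metadata only.
#'
#' @return An object of class `ld_schedule`.
#' @examples
#' ld_schedule("09:00", photoperiod_h = 8)
#' @export
ld_schedule <- function(lights_on = "09:00", photoperiod_h = 12,
                        ramping = FALSE, ramp_peak_lux = 400,
                        spectrum = c("white", "amber_592nm", "red_612nm",
                                     "blue_445nm")) {
  spectrum <- match.arg(spectrum)
  if (!is.numeric(photoperiod_h) || photoperiod_h <= 0 || photoperiod_h >= 24)
    stop("photoperiod_h must lie strictly between 0 and 24 for LD designs")
  structure(
    list(lights_on = lights_on,
         lights_on_min = parse_clock_min(lights_on),
         photoperiod_h = photoperiod_h,
         ramping = isTRUE(ramping),
         ramp_peak_lux = ramp_peak_lux,
         spectrum = spectrum),
    class = "ld_schedule")
}

# "HH:MM[:SS]" -> minutes past midnight
parse_clock_min <- function(x) {
  parts <- as.numeric(strsplit(x, ":", fixed = TRUE)[[1]])
  if (length(parts) < 2 || length(parts) > 3 || anyNA(parts))
    stop("clock time must be 'HH:MM' or 'HH:MM:SS', got: ", x)
  parts[1] * 60 + parts[2] + if (length(parts) == 3) parts[3] / 60 else 0
}

#' Experiment configuration
#'
#' Bundles the LD schedule with the geometry of the behavioral arena (a
#' 44 mm x 6 mm enclosure split into two lighting zones by a filter at
#' `zone_boundary_mm`) and recording parameters.  Coordinates are in
#' millimeters with the origin at the shaded-end wall and x running along
#' the long axis of the enclosure.
#'
#' @param temperature_c Holding temperature in degrees Celsius (metadata).
#' @param schedule An [ld_schedule()].
#' @param arena_length_mm,arena_width_mm Arena dimensions (mm).
#' @param zone_boundary_mm x coordinate of the filter edge separating zone A
#'   (x <= boundary) from zone B.  Defaults to the arena midline.
#' @param zone_labels Character pair naming zone A and zone B, e.g.
#'   `c("shade", "bright")` or `c("red", "blue")`.
#' @param frame_rate_hz Video tracking frame rate (frames/s).
#' @param dam_bin_s Seconds per DAM count bin.
#'
#' @return An object of class `experiment_config`.
#' @examples
#' experiment_config(25, ld_schedule("09:00", 12))
#' @export
experiment_config <- function(temperature_c = 25,
                              schedule = ld_schedule(),
                              arena_length_mm = 44,
                              arena_width_mm = 6,
                              zone_boundary_mm = arena_length_mm / 2,
                              zone_labels = c("shade", "bright"),
                              frame_rate_hz = 1,
                              dam_bin_s = 60) {
  stopifnot(inherits(schedule, "ld_schedule"))
  if (!(zone_boundary_mm > 0 && zone_boundary_mm < arena_length_mm))
    stop("zone_boundary_mm must lie strictly inside the arena")
  if (frame_rate_hz <= 0) stop("frame_rate_hz must be positive")
  if (length(zone_labels) != 2) stop("zone_labels must have length 2")
  structure(
    list(temperature_c = temperature_c,
         schedule = schedule,
         arena_length_mm = arena_length_mm,
         arena_width_mm = arena_width_mm,
         zone_boundary_mm = zone_boundary_mm,
         zone_labels = as.character(zone_labels),
         frame_rate_hz = frame_rate_hz,
         dam_bin_s = dam_bin_s),
    class = "experiment_config")
}

#' Read an experiment configuration from a YAML file
#'
#' The file mirrors the fields of [experiment_config()] with the schedule
#' nested under a `schedule:` key.
#'
#' @param path Path to a YAML file.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  sch_fields <- y$schedule %||% list()
  sched <- do.call(ld_schedule, sch_fields)
  y$schedule <- NULL
  do.call(experiment_config, c(y, list(schedule = sched)))
}

#' Stimulus-train schedule
#'
#' Describes trains of arousal stimuli delivered during a recording.  The
#' default vibration protocol is five gradually increasing 3-s pulses
#' delivered back-to-back (contiguous ramp steps), once every 2 h; the
#' blue-light protocol is five 3-s pulses with a 10-s interpulse delay at a
#' fixed intensity.
#'
#' @param stim_type `"vibration"` or `"blue_light"`.
#' @param train_onset_zt_min Numeric vector of train onsets in ZT minutes
#'   since the start of the recording (may exceed 1440 for multi-day
#'   schedules).  If `NULL`, onsets are generated every `every_min` minutes
#'   starting at `first_onset_zt_min` for `days` days.
#' @param pulses_per_train Number of pulses per train.
#' @param pulse_s Pulse duration (s).
#' @param interpulse_s Gap between pulses (s); 0 for the contiguous
#'   vibration ramp, 10 for blue light.
#' @param intensities Per-pulse physical intensity.  Vibration intensities
#'   are in g-force units via [drive_level_calibration()] (identity by
#'   default, so drive levels 1..5 map to g values 1..5); light intensity
#'   is in lux (default 85).  Must be non-decreasing for vibration trains.
#' @param days,first_onset_zt_min,every_min Used only when
#'   `train_onset_zt_min` is `NULL`.
#'
#' @return An object of class `stimulus_schedule`.
#' @examples
#' stimulus_schedule("vibration", days = 1)
#' @export
stimulus_schedule <- function(stim_type = c("vibration", "blue_light"),
                              train_onset_zt_min = NULL,
                              pulses_per_train = 5,
                              pulse_s = 3,
                              interpulse_s = NULL,
                              intensities = NULL,
                              days = 1,
                              first_onset_zt_min = 60,
                              every_min = 120) {
  stim_type <- match.arg(stim_type)
  if (is.null(interpulse_s))
    interpulse_s <- if (stim_type == "vibration") 0 else 10
  if (is.null(intensities))
    intensities <- if (stim_type == "vibration") {
      drive_level_calibration()(seq_len(pulses_per_train))
    } else rep(85, pulses_per_train)
  if (length(intensities) != pulses_per_train)
    stop("need one intensity per pulse")
  if (stim_type == "vibration" && is.unsorted(intensities))
    stop("vibration intensities must be non-decreasing within a train")
  if (is.null(train_onset_zt_min))
    train_onset_zt_min <- seq(first_onset_zt_min, by = every_min,
                              length.out = ceiling(days * 1440 / every_min))
  if (is.unsorted(train_onset_zt_min, strictly = TRUE))
    stop("train onsets must be strictly increasing")
  structure(
    list(stim_type = stim_type,
         train_onset_zt_min = train_onset_zt_min,
         pulses_per_train = pulses_per_train,
         pulse_s = pulse_s,
         interpulse_s = interpulse_s,
         intensities = as.numeric(intensities)),
    class = "stimulus_schedule")
}

#' Vibration drive-level to g-force calibration
#'
#' Returns a function mapping integer motor drive levels to measured
#' g-force.  The default is the identity table (levels 1..5 map to g
#' values 1..5 in arbitrary units); a real accelerometer calibration can
#' be supplied as a two-column CSV (`level`, `g`).
#'
#' @param csv Optional path to a calibration CSV.
#' @return A function `level -> g`.
#' @export
drive_level_calibration <- function(csv = NULL) {
  if (is.null(csv)) return(function(level) as.numeric(level))
  tab <- utils::read.csv(csv)
  if (!all(c("level", "g") %in% names(tab)))
    stop("calibration CSV needs columns 'level' and 'g'")
  function(level) {
    g <- tab$g[match(level, tab$level)]
    if (anyNA(g)) stop("drive level outside calibration table")
    g
  }
}

# duration of one stimulus train in seconds, including the terminal
# response window of the last pulse
train_length_s <- function(schedule) {
  schedule$pulses_per_train * (schedule$pulse_s + schedule$interpulse_s)
}

# per-pulse onset offsets within a train, seconds from train onset
pulse_offsets_s <- function(schedule) {
  (seq_len(schedule$pulses_per_train) - 1) *
    (schedule$pulse_s + schedule$interpulse_s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
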