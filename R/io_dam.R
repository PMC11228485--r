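# Trikinetics-style DAM monitor file I/O and trajectory ingestion.
#
# A monitor file is tab-delimited: each row carries >= 10 metadata fields
# (record index, date, time, monitor status, then auxiliary fields)
# followed by 32 integer beam-cross counts, one per channel/tube.

N_DAM_CHANNELS <- 32L
N_DAM_META <- 10L

#' Parse a Trikinetics-style DAM monitor file
#'
#' Reads a tab-delimited monitor file and returns one activity series per
#' non-empty channel, with timestamps converted to zeitgeber minutes using
#' the lights-on time in `config$schedule`.  ZT minutes start in
#' `[0, 1440)` for the first record and increase monotonically from there,
#' so a record taken one hour before lights-on maps to ZT 1380 (the
#' previous cycle's ZT 23:00).
#'
#' Rows whose monitor status field is not `1` are retained and flagged via
#' `status_ok` rather than silently dropped, because dropping bins corrupts
#' actograms.
#'
#' @param path Path to the monitor file.
#' @param config An [experiment_config()]; only the schedule is used.
#' @param keep_empty Keep channels whose counts are all zero?
#' @return A `data.table` with columns `fly_id` (channel, `"ch01"`..),
#'   `zt_min`, `counts`, `status_ok`, and attributes `dam_meta` (character
#'   matrix of the metadata fields), `dam_counts` (bins x 32 integer
#'   matrix), `bin_min`, and `source = "dam"`.
#' @export
parse_dam <- function(path, config, keep_empty = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty DAM file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != nf[1] | nf < N_DAM_META + N_DAM_CHANNELS)
  if (length(bad))
    stop("malformed DAM row at line ", bad[1], ": expected ",
         max(nf[1], N_DAM_META + N_DAM_CHANNELS), " fields, found ",
         nf[bad[1]])
  m <- matrix(unlist(fields), nrow = length(fields), byrow = TRUE)
  nmeta <- ncol(m) - N_DAM_CHANNELS
  meta <- m[, seq_len(nmeta), drop = FALSE]
  cnt <- m[, nmeta + seq_len(N_DAM_CHANNELS), drop = FALSE]
  suppressWarnings(storage.mode(cnt) <- "integer")
  if (anyNA(cnt))
    stop("non-integer channel count at line ",
         which(rowSums(is.na(cnt)) > 0)[1])

  ts <- as.POSIXct(paste(meta[, 2], meta[, 3]),
                   format = "%d %b %y %H:%M:%S", tz = "UTC")
  if (anyNA(ts))
    stop("unparseable timestamp at line ", which(is.na(ts))[1])
  if (is.unsorted(as.numeric(ts), strictly = TRUE))
    stop("timestamps are not strictly increasing")

  clock_min <- as.numeric(ts - as.POSIXct(format(ts[1], "%Y-%m-%d"),
                                          tz = "UTC"), units = "mins")
  zt0 <- (clock_min[1] - config$schedule$lights_on_min) %% 1440
  zt_min <- zt0 + as.numeric(ts - ts[1], units = "mins")
  bin_min <- if (length(zt_min) > 1) median(diff(zt_min)) else 1
  status_ok <- meta[, 4] == "1"

  keep <- if (keep_empty) seq_len(N_DAM_CHANNELS) else
    which(colSums(cnt) > 0)
  out <- rbindlist(lapply(keep, function(k)
    data.table(fly_id = sprintf("ch%02d", k), zt_min = zt_min,
               counts = cnt[, k], status_ok = status_ok)))
  setattr(out, "dam_meta", meta)
  setattr(out, "dam_counts", cnt)
  setattr(out, "bin_min", bin_min)
  setattr(out, "source", "dam")
  out[]
}

#' Write a DAM monitor file
#'
#' Two input forms are accepted: the object returned by [parse_dam()]
#' (the original metadata and full 32-channel count matrix are carried as
#' attributes and reproduced bit-exactly), or a bins x channels integer
#' matrix of counts (up to 32 columns; missing channels are zero-filled)
#' for which metadata rows are synthesized from `start` and `bin_s`.
#'
#' @param x Parsed DAM object or count matrix.
#' @param path Output path.
#' @param start Timestamp of the first bin (`POSIXct` or string,
#'   `"%Y-%m-%d %H:%M:%S"`, UTC) when `x` is a matrix.
#' @param bin_s Bin length in seconds when `x` is a matrix.
#' @return `path`, invisibly.
#' @export
write_dam <- function(x, path, start = "2024-01-01 09:00:00", bin_s = 60) {
  if (is.matrix(x)) {
    n <- nrow(x)
    cnt <- matrix(0L, n, N_DAM_CHANNELS)
    cnt[, seq_len(ncol(x))] <- as.integer(x)
    ts <- as.POSIXct(start, tz = "UTC") + (seq_len(n) - 1) * bin_s
    meta <- cbind(seq_len(n),
                  toupper(format(ts, "%d %b %y")),
                  format(ts, "%H:%M:%S"),
                  "1", "1", "0", "0", "0", "0", "0")
  } else {
    meta <- attr(x, "dam_meta")
    cnt <- attr(x, "dam_counts")
    if (is.null(meta) || is.null(cnt))
      stop("x must be a count matrix or an object returned by parse_dam()")
  }
  lines <- apply(cbind(meta, cnt), 1, paste, collapse = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Build an in-memory trajectory
#'
#' Constructor used by the simulator and by tests.  Frames whose
#' coordinates are missing or fall outside the arena are flagged invalid,
#' not dropped.
#'
#' @param t_s Seconds since recording start, strictly increasing.
#' @param x_mm,y_mm Positions in arena coordinates (origin at the
#'   shaded-end wall).
#' @param config An [experiment_config()] supplying arena bounds.
#' @param fly_id Identifier.
#' @param valid Optional logical vector of a priori frame validity.
#' @return A `data.table` with columns `fly_id`, `t_s`, `x_mm`, `y_mm`,
#'   `valid`.
#' @export
trajectory <- function(t_s, x_mm, y_mm, config, fly_id = "fly1",
                       valid = TRUE) {
  if (is.unsorted(t_s, strictly = TRUE))
    stop("t_s must be strictly increasing")
  valid <- rep_len(valid, length(t_s))
  ok <- valid & !is.na(x_mm) & !is.na(y_mm) &
    x_mm >= 0 & x_mm <= config$arena_length_mm &
    y_mm >= 0 & y_mm <= config$arena_width_mm
  data.table(fly_id = fly_id, t_s = as.numeric(t_s),
             x_mm = as.numeric(x_mm), y_mm = as.numeric(y_mm),
             valid = ok)
}

#' Load a tracking trajectory from a delimited table
#'
#' The table must have a header naming a time column (`t_s`, `time_s`,
#' `t` or `time`), an x column (`x_mm` or `x`) and a y column (`y_mm` or
#' `y`); an optional `valid` column marks tracking dropouts.  The frame
#' interval is inferred from the time column, must be uniform within 1%,
#' and must agree with `config$frame_rate_hz` within 1%.  Frames outside
#' the arena are flagged invalid; if more than 10% of frames are invalid
#' a warning is emitted.
#'
#' @param path CSV/TSV path.
#' @param config An [experiment_config()].
#' @param fly_id Identifier; defaults to the file name without extension.
#' @return A trajectory `data.table` (see [trajectory()]).
#' @export
load_trajectory <- function(path, config, fly_id = NULL) {
  if (is.null(fly_id))
    fly_id <- sub("\\.[^.]*$", "", basename(path))
  tab <- fread(path)
  pick <- function(cands) {
    hit <- intersect(cands, tolower(names(tab)))
    if (!length(hit)) stop("no column matching: ", paste(cands, collapse = "/"))
    names(tab)[match(hit[1], tolower(names(tab)))]
  }
  tcol <- pick(c("t_s", "time_s", "t", "time"))
  xcol <- pick(c("x_mm", "x"))
  ycol <- pick(c("y_mm", "y"))
  t_s <- as.numeric(tab[[tcol]])
  if (is.unsorted(t_s, strictly = TRUE))
    stop("time column must be strictly increasing")
  dts <- diff(t_s)
  dt0 <- median(dts)
  if (length(dts) && any(abs(dts - dt0) > 0.01 * dt0))
    stop("non-uniform sampling: frame intervals deviate by more than 1%")
  if (abs(dt0 - 1 / config$frame_rate_hz) > 0.01 / config$frame_rate_hz)
    stop(sprintf(
      "inferred frame interval %.4g s disagrees with frame_rate_hz = %g",
      dt0, config$frame_rate_hz))
  valid0 <- if ("valid" %in% tolower(names(tab)))
    as.logical(tab[[pick("valid")]]) else TRUE
  traj <- trajectory(t_s, tab[[xcol]], tab[[ycol]], config,
                     fly_id = fly_id, valid = valid0)
  frac_bad <- mean(!traj$valid)
  if (frac_bad > 0.10)
    warning(sprintf("%.1f%% of frames invalid in %s", 100 * frac_bad, fly_id))
  traj
}

# valid consecutive frame pairs of a single-fly trajectory: both frames
# valid and exactly one frame interval apart
valid_pairs <- function(traj, dt_s) {
  n <- nrow(traj)
  if (n < 2) return(integer(0))
  i <- seq_len(n - 1)
  i[traj$valid[i] & traj$valid[i + 1] &
      abs(diff(traj$t_s) - dt_s) < 0.01 * dt_s]
}

infer_dt <- function(traj) {
  if (nrow(traj) < 2) stop("trajectory has fewer than 2 frames")
  median(diff(traj$t_s))
}

#' Per-bin mean speed from a trajectory
#'
#' Speed per bin is the sum of Euclidean frame-to-frame displacements over
#' valid consecutive frame pairs, divided by the elapsed valid time in the
#' bin.  Bins containing no valid pair are reported as missing, not zero.
#'
#' @param traj A single-fly trajectory.
#' @param bin_s Bin length in seconds (a multiple of the frame interval).
#' @param start_zt_min ZT of the first frame, minutes (recordings made in
#'   this package start at lights-on, ZT 0).
#' @return A `data.table` with `fly_id`, `zt_min` (bin start) and
#'   `speed_mm_s`; attribute `source = "tracking"`.
#' @export
speed_series <- function(traj, bin_s = 60, start_zt_min = 0) {
  if (!nrow(traj)) stop("empty trajectory")
  dt_s <- infer_dt(traj)
  if (abs(bin_s / dt_s - round(bin_s / dt_s)) > 1e-6)
    stop("bin_s must be a multiple of the frame interval")
  i <- valid_pairs(traj, dt_s)
  t0 <- traj$t_s[1]
  all_bins <- seq(0, floor((traj$t_s[nrow(traj)] - t0) / bin_s))
  disp <- sqrt((traj$x_mm[i + 1] - traj$x_mm[i])^2 +
               (traj$y_mm[i + 1] - traj$y_mm[i])^2)
  b <- floor((traj$t_s[i] - t0) / bin_s)
  agg <- data.table(bin = b, disp = disp)[
    , .(speed_mm_s = sum(disp) / (.N * dt_s)), by = bin]
  out <- agg[data.table(bin = all_bins), on = "bin"]
  out <- data.table(fly_id = traj$fly_id[1],
                    zt_min = start_zt_min + out$bin * bin_s / 60,
                    speed_mm_s = out$speed_mm_s)
  setattr(out, "source", "tracking")
  setattr(out, "bin_min", bin_s / 60)
  out[]
}

#' Emulate a DAM beam from a trajectory
#'
#' Counts, per DAM bin, the number of times the fly crosses the virtual
#' infrared beam at the arena midline (x = arena_length_mm / 2).  A
#' crossing is a sign change of x - midline between consecutive valid
#' frames; a frame that touches the midline exactly counts once, on the
#' frame at which the fly leaves the midline (regardless of the side it
#' leaves to), which makes the count deterministic.
#'
#' @param traj A single-fly trajectory.
#' @param config An [experiment_config()] (`dam_bin_s`, arena length).
#' @param start_zt_min ZT of the first frame, minutes.
#' @return A `data.table` with `fly_id`, `zt_min`, `counts`; attribute
#'   `source = "dam_emulated"`.
#' @export
emulate_dam <- function(traj, config, start_zt_min = 0) {
  if (!nrow(traj)) stop("empty trajectory")
  mid <- config$arena_length_mm / 2
  v <- traj[valid == TRUE]
  t0 <- traj$t_s[1]
  bin_s <- config$dam_bin_s
  all_bins <- seq(0, floor((traj$t_s[nrow(traj)] - t0) / bin_s))
  counts <- rep(0L, length(all_bins))
  if (nrow(v) >= 2) {
    s <- sign(v$x_mm - mid)
    # a crossing registers on the frame that leaves the previous side:
    # either a strict sign change, or leaving the midline after an exact
    # touch (counted once, whichever side the fly leaves to)
    prev <- c(s[1], s[-length(s)])
    cross <- which(s != 0 & (prev == 0 | s != prev))
    if (length(cross)) {
      b <- floor((v$t_s[cross] - t0) / bin_s)
      tab <- table(b)
      idx <- as.integer(names(tab)) + 1L
      counts[idx] <- counts[idx] + as.integer(tab)
    }
  }
  out <- data.table(fly_id = traj$fly_id[1],
                    zt_min = start_zt_min + all_bins * bin_s / 60,
                    counts = counts)
  setattr(out, "source", "dam_emulated")
  setattr(out, "bin_min", bin_s / 60)
  out[]
}

#' Write activity series to a tidy CSV
#'
#' @param series Activity `data.table` (from [parse_dam()],
#'   [speed_series()] or [emulate_dam()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_activity_csv <- function(series, path) {
  fwrite(series, path)
  invisible(path)
}
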