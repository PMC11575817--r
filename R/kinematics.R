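#' Zero-phase Butterworth low-pass filter
#'
#' Applies a Butterworth low-pass filter forward and backward (phase-shift
#' correction) to every coordinate of a trajectory, the standard smoothing
#' step for optical motion-capture marker data. The effective two-pass
#' magnitude response at frequency f is `1 / (1 + (f/cutoff)^(2*order))`.
#' Edges are handled by odd (point-reflected) extension of three filter
#' warm-up lengths; attempts are expected to include a quiet margin of at
#' least 0.5 s before and after the movement.
#'
#' @param traj A `vbt_trajectory` (or any data frame with `time_s` and
#'   coordinate columns `x_m`, `y_m`, `z_m`).
#' @param order Filter order of each pass (even; default 4).
#' @param cutoff Cutoff frequency in Hz (default 10); must be below the
#'   Nyquist frequency.
#' @return The trajectory with filtered coordinates; attributes preserved.
#' @export
lowpass_filter <- function(traj, order = 4, cutoff = 10) {
  fs <- trajectory_fs(traj)
  stop_if_not(cutoff > 0 && cutoff < fs / 2,
              "cutoff must lie below the Nyquist frequency")
  stop_if_not(order >= 2 && order %% 2 == 0, "order must be an even integer >= 2")
  pad <- 3L * ceiling(fs / cutoff)
  stop_if_not(nrow(traj) > pad + 1L,
              sprintf("trajectory too short for filter warm-up (need > %d samples)",
                      pad + 1L))
  bf <- signal::butter(order, cutoff / (fs / 2))
  for (col in c("x_m", "y_m", "z_m")) {
    if (col %in% names(traj)) traj[[col]] <- filtfilt_odd(bf, traj[[col]], pad)
  }
  traj
}

# Forward-backward IIR filtering with odd extension at both ends. The
# extended signal is mean-centred before filtering so the zero-initial-state
# transient is driven only by deviations from the mean, not by the absolute
# coordinate level.
filtfilt_odd <- function(bf, z, pad) {
  n <- length(z)
  ext <- c(2 * z[1] - z[(pad + 1):2], z, 2 * z[n] - z[(n - 1):(n - pad)])
  m <- mean(ext)
  ext <- ext - m
  f1 <- signal::filter(bf, ext)
  f2 <- rev(signal::filter(bf, rev(f1)))
  f2[(pad + 1):(pad + n)] + m
}

trajectory_fs <- function(traj) {
  fs <- attr(traj, "sampling_rate")
  if (!is.null(fs)) return(fs)
  stop_if_not(nrow(traj) >= 2, "trajectory needs at least 2 samples")
  dts <- diff(traj$time_s)
  stop_if_not(max(dts) - min(dts) < 1e-6, "sampling must be uniform")
  1 / stats::median(dts)
}

#' Differentiate a trajectory
#'
#' First derivative of vertical position with respect to time: central
#' differences at interior samples, one-sided differences at the ends.
#'
#' @param traj A `vbt_trajectory`, or a numeric position vector (then `dt`
#'   must be given).
#' @param dt Sampling interval in seconds when `traj` is a plain vector.
#' @return Numeric vector of vertical velocity (m/s), same length as input.
#' @export
differentiate <- function(traj, dt = NULL) {
  if (is.numeric(traj)) {
    z <- traj
    stop_if_not(!is.null(dt) && dt > 0, "dt must be supplied for numeric input")
  } else {
    z <- traj$z_m
    dt <- 1 / trajectory_fs(traj)
  }
  n <- length(z)
  stop_if_not(n >= 2, "need at least 2 samples")
  v <- numeric(n)
  v[2:(n - 1)] <- (z[3:n] - z[1:(n - 2)]) / (2 * dt)
  v[1] <- (z[2] - z[1]) / dt
  v[n] <- (z[n] - z[n - 1]) / dt
  v
}

#' Detect concentric repetitions by velocity and displacement thresholds
#'
#' Candidate segments are maximal contiguous runs of samples whose vertical
#' velocity exceeds `v_thresh` (strictly); a segment is kept if its net
#' vertical displacement is at least `d_thresh`, which filters out unracking,
#' re-racking and other small upward movements. Mean velocity is displacement
#' divided by duration. Only upward segments are repetitions; eccentric
#' phases are never counted.
#'
#' @param velocity Vertical velocity series (m/s).
#' @param position Vertical position series (m), aligned with `velocity`.
#' @param time Time stamps in seconds, aligned with `velocity`.
#' @param v_thresh Instantaneous velocity threshold (m/s), default 0.02.
#' @param d_thresh Minimum net displacement (m), default 0.10.
#' @return A data frame of class `vbt_segments` with one row per kept segment
#'   (ordered by start time): `start_time`, `end_time`, `duration`,
#'   `displacement`, `mean_velocity`. Zero rows is a valid result.
#' @export
detect_reps <- function(velocity, position, time,
                        v_thresh = 0.02, d_thresh = 0.10) {
  stop_if_not(length(velocity) == length(position) &&
                length(velocity) == length(time),
              "velocity, position and time must be aligned")
  above <- velocity > v_thresh
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values
  segs <- data.frame(start = starts[keep], end = ends[keep])
  if (nrow(segs) > 0) {
    segs$displacement <- position[segs$end] - position[segs$start]
    segs <- segs[segs$displacement >= d_thresh, , drop = FALSE]
  }
  out <- data.frame(
    start_time = time[segs$start],
    end_time = time[segs$end],
    duration = time[segs$end] - time[segs$start],
    displacement = segs$displacement
  )
  if (nrow(out) > 0) {
    out$mean_velocity <- out$displacement / out$duration
    out <- out[order(out$start_time), , drop = FALSE]
    rownames(out) <- NULL
  } else {
    out$mean_velocity <- numeric(0)
  }
  class(out) <- c("vbt_segments", "data.frame")
  out
}

#' Resolve multiple detections within one attempt
#'
#' When more segments survive thresholding than repetitions were performed
#' (e.g. walkout or re-rack movements above 10 cm), the `expected_reps`
#' segments with the largest displacement are kept, ties resolved in favour
#' of the earlier segment. This deterministic rule replaces interactive
#' cross-checking of detections against the reconstructed barbell path.
#'
#' @param segments A `vbt_segments` data frame from [detect_reps()].
#' @param expected_reps Number of repetitions performed (>= 1).
#' @return The selected segments, ordered by start time. If fewer segments
#'   than expected were found they are returned as-is with attribute
#'   `shortfall = TRUE` and a warning.
#' @export
resolve_reps <- function(segments, expected_reps = 1L) {
  stop_if_not(expected_reps >= 1, "expected_reps must be >= 1")
  if (nrow(segments) < expected_reps) {
    warning(sprintf("found %d segment(s) but expected %d",
                    nrow(segments), expected_reps))
    attr(segments, "shortfall") <- TRUE
    return(segments)
  }
  if (nrow(segments) > expected_reps) {
    ord <- order(-segments$displacement, segments$start_time)
    segments <- segments[sort(ord[seq_len(expected_reps)]), , drop = FALSE]
    rownames(segments) <- NULL
  }
  attr(segments, "shortfall") <- FALSE
  segments
}

#' Process one lift attempt into criterion repetition observations
#'
#' Criterion pipeline: zero-phase Butterworth filtering, differentiation,
#' threshold-based repetition detection, and resolution of multiple
#' detections.
#'
#' @param traj A `vbt_trajectory`.
#' @param expected_reps Repetitions performed in the attempt.
#' @param v_thresh,d_thresh Detection thresholds, see [detect_reps()].
#' @param cutoff,order Filter settings, see [lowpass_filter()].
#' @param device_id Device label for the emitted observations.
#' @return A data frame in the repetition-observation schema (one row per
#'   kept segment, `status = "ok"`), carrying the trajectory's metadata.
#' @export
process_attempt <- function(traj, expected_reps = 1L,
                            v_thresh = 0.02, d_thresh = 0.10,
                            cutoff = 10, order = 4,
                            device_id = "vicon") {
  filtered <- lowpass_filter(traj, order = order, cutoff = cutoff)
  vel <- differentiate(filtered)
  segs <- detect_reps(vel, filtered$z_m, filtered$time_s,
                      v_thresh = v_thresh, d_thresh = d_thresh)
  segs <- resolve_reps(segs, expected_reps)
  n <- nrow(segs)
  meta <- function(name, default) attr(traj, name) %||% default
  out <- data.frame(
    subject_id = rep(meta("subject_id", NA_character_), length.out = max(n, 0)),
    exercise = rep(meta("exercise", NA_character_), length.out = max(n, 0)),
    load_pct = rep(round(100 * (meta("load_fraction", NA_real_))),
                   length.out = max(n, 0)),
    set_index = rep(meta("set_index", 1L), length.out = max(n, 0)),
    rep_index = seq_len(n),
    device_id = rep(device_id, length.out = max(n, 0)),
    mean_velocity = segs$mean_velocity,
    status = rep("ok", length.out = max(n, 0)),
    stringsAsFactors = FALSE
  )
  attr(out, "segments") <- segs
  out
}
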