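#' Angular velocities from a pose time series
#'
#' Forward differences of the position angle (period 360) and orientation
#' angle (period 180), scaled by the frame rate and assigned to the earlier
#' frame. The last frame has no velocity; any difference touching an invalid
#' pose is missing. Optionally applies a centered moving-median (window 5)
#' to each velocity channel.
#'
#' @param poses Data frame from [track_frames()] (columns
#'   `position_angle_deg`, `orientation_angle_deg`, `valid`).
#' @param frame_rate Frames per second.
#' @param smooth If `TRUE`, apply a centered moving median of window 5 to
#'   both velocity series (off by default).
#' @return The input with columns `position_velocity_degps` and
#'   `orientation_velocity_degps` appended (clockwise positive, degrees/s).
#' @export
velocities <- function(poses, frame_rate, smooth = FALSE) {
  if (!is.numeric(frame_rate) || frame_rate <= 0)
    stop("frame_rate must be positive", call. = FALSE)
  n <- nrow(poses)
  vp <- vo <- rep(NA_real_, n)
  if (n >= 2L) {
    i <- seq_len(n - 1L)
    pa <- poses$position_angle_deg
    oa <- poses$orientation_angle_deg
    vp[i] <- angular_difference(pa[i], pa[i + 1L], 360) * frame_rate
    vo[i] <- angular_difference(oa[i], oa[i + 1L], 180) * frame_rate
    bad <- !poses$valid[i] | !poses$valid[i + 1L]
    vp[i][bad] <- NA_real_
    vo[i][bad] <- NA_real_
  }
  if (smooth) {
    vp <- moving_median(vp, 5)
    vo <- moving_median(vo, 5)
  }
  poses$position_velocity_degps <- vp
  poses$orientation_velocity_degps <- vo
  poses
}

# Centered moving median; windows containing a missing value yield NA so
# gaps are never interpolated over.
moving_median <- function(x, w) {
  n <- length(x)
  h <- floor(w / 2)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    win <- x[max(1, i - h):min(n, i + h)]
    if (!anyNA(win)) out[i] <- stats::median(win)
  }
  out
}

#' Flag frames where the mouse moves with the stimulus
#'
#' Joins the per-frame stimulus direction onto the kinematic table and flags,
#' independently for the position and orientation channels, the frames whose
#' velocity sign agrees with the drum direction (clockwise positive). A frame
#' is never matched when the velocity is missing, slower than the dead band,
#' or the stimulus direction is unknown.
#'
#' @param samples Data frame from [velocities()].
#' @param stimulus Data frame from [detect_directions()], frame-aligned with
#'   `samples` (equal row count).
#' @param dead_band Minimum speed, degrees/s, below which movement is treated
#'   as jitter and excluded from matching.
#' @return `samples` with columns `stim_direction`, `stim_phase_shift_px`,
#'   `stim_confidence`, `position_matched`, `orientation_matched` appended.
#' @export
direction_match <- function(samples, stimulus, dead_band = 2) {
  if (nrow(samples) != nrow(stimulus))
    stop(sprintf("samples (%d rows) and stimulus (%d rows) must be frame-aligned",
                 nrow(samples), nrow(stimulus)), call. = FALSE)
  s <- dir_sign(stimulus$direction)
  matched <- function(v) {
    ok <- !is.na(v) & s != 0 & abs(v) >= dead_band & sign(v) == s
    ok & !is.na(ok)
  }
  samples$stim_direction <- stimulus$direction
  samples$stim_phase_shift_px <- stimulus$phase_shift_px
  samples$stim_confidence <- stimulus$confidence
  samples$position_matched <- matched(samples$position_velocity_degps)
  samples$orientation_matched <- matched(samples$orientation_velocity_degps)
  samples
}

#' Summarize a trial into the two optomotor endpoints
#'
#' Computes the assay endpoints over the direction-matched frames:
#' the angular orientation speed (mean absolute orientation velocity of the
#' snout-tail axis) and the angular running speed (mean absolute angular
#' velocity of the body center around the arena center). Each endpoint is
#' missing - never zero - when no frame matched its channel: "no tracking
#' behavior observed" is distinct from "tracked at speed 0".
#'
#' @param samples Data frame from [direction_match()].
#' @return An object of class `optomotor_trial`: a list with `samples` (the
#'   per-frame table), `angular_orientation_speed` and
#'   `angular_running_speed` (degrees/s or `NA`), `matched_frame_counts`
#'   (named: orientation, position) and `qc` counters.
#' @export
summarize_trial <- function(samples) {
  if (nrow(samples) < 1L) stop("at least one sample is required", call. = FALSE)
  pm <- samples$position_matched
  om <- samples$orientation_matched
  running <- if (any(pm)) mean(abs(samples$position_velocity_degps[pm])) else NA_real_
  orient <- if (any(om)) mean(abs(samples$orientation_velocity_degps[om])) else NA_real_
  res <- list(
    samples = samples,
    angular_orientation_speed = orient,
    angular_running_speed = running,
    matched_frame_counts = c(orientation = sum(om), position = sum(pm)),
    qc = list(
      frames_total = nrow(samples),
      frames_valid = sum(samples$valid),
      frames_unknown_stimulus = sum(samples$stim_direction == "UNKNOWN")
    )
  )
  class(res) <- "optomotor_trial"
  res
}

#' @export
print.optomotor_trial <- function(x, ...) {
  cat("Optomotor trial\n")
  fmt <- function(v) if (is.na(v)) "not observed" else sprintf("%.2f deg/s", v)
  cat(sprintf("  angular orientation speed: %s (%d matched frames)\n",
              fmt(x$angular_orientation_speed), x$matched_frame_counts["orientation"]))
  cat(sprintf("  angular running speed:     %s (%d matched frames)\n",
              fmt(x$angular_running_speed), x$matched_frame_counts["position"]))
  cat(sprintf("  frames: %d total, %d valid pose, %d unknown stimulus\n",
              x$qc$frames_total, x$qc$frames_valid, x$qc$frames_unknown_stimulus))
  invisible(x)
}

#' @export
summary.optomotor_trial <- function(object, ...) {
  s <- object$samples
  known <- s$stim_direction %in% c("CW", "CCW")
  out <- list(
    endpoints = c(angular_orientation_speed = object$angular_orientation_speed,
                  angular_running_speed = object$angular_running_speed),
    matched_frame_counts = object$matched_frame_counts,
    qc = object$qc,
    stim_bouts = if (any(known)) table(s$stim_direction[known]) else table(character(0)),
    velocity_quartiles = list(
      position = stats::quantile(s$position_velocity_degps, na.rm = TRUE),
      orientation = stats::quantile(s$orientation_velocity_degps, na.rm = TRUE)
    )
  )
  class(out) <- "summary.optomotor_trial"
  out
}

#' @export
print.summary.optomotor_trial <- function(x, ...) {
  cat("Optomotor trial summary\n")
  cat(sprintf("  angular orientation speed: %s deg/s\n",
              format(x$endpoints[1], digits = 4)))
  cat(sprintf("  angular running speed:     %s deg/s\n",
              format(x$endpoints[2], digits = 4)))
  cat(sprintf("  matched frames: %d orientation, %d position of %d total (%d valid)\n",
              x$matched_frame_counts["orientation"], x$matched_frame_counts["position"],
              x$qc$frames_total, x$qc$frames_valid))
  cat("  position velocity quartiles (deg/s):\n")
  print(round(x$velocity_quartiles$position, 2))
  invisible(x)
}

#' @export
as.data.frame.optomotor_trial <- function(x, ...) x$samples

#' Plot an optomotor trial
#'
#' Two base-graphics panels: the mouse position angle over time with the
#' detected stimulus direction shaded, and the position angular velocity with
#' direction-matched frames highlighted.
#'
#' @param x An `optomotor_trial`.
#' @param ... Passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.optomotor_trial <- function(x, ...) {
  s <- x$samples
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  shade <- function() {
    known <- s$stim_direction
    r <- rle(known)
    ends <- cumsum(r$lengths); starts <- c(1, utils::head(ends, -1) + 1)
    usr <- graphics::par("usr")
    for (j in seq_along(r$values)) {
      if (r$values[j] == "UNKNOWN") next
      col <- if (r$values[j] == "CW") grDevices::rgb(0, 0, 1, 0.08)
             else grDevices::rgb(1, 0, 0, 0.08)
      graphics::rect(s$time_s[starts[j]], usr[3], s$time_s[ends[j]], usr[4],
                     col = col, border = NA)
    }
  }
  plot(s$time_s, s$position_angle_deg, type = "l", xlab = "time (s)",
       ylab = "position angle (deg)", main = "position angle / stimulus direction", ...)
  shade()
  vr <- range(s$position_velocity_degps, na.rm = TRUE, finite = TRUE)
  if (!all(is.finite(vr))) vr <- c(-1, 1)
  plot(s$time_s, s$position_velocity_degps, type = "l", col = "grey50",
       ylim = vr + c(-1, 1), xlab = "time (s)",
       ylab = "angular velocity (deg/s)",
       main = "position velocity (matched frames in black)")
  m <- s$position_matched
  graphics::points(s$time_s[m], s$position_velocity_degps[m], pch = 16, cex = 0.3)
  invisible(x)
}
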