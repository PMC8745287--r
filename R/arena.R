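#' Apparatus and stimulus configuration for the optomotor drum
#'
#' Bundles the geometry, stimulus and acquisition parameters of the optomotor
#' apparatus. Defaults mirror the standard small-drum design: a 22 cm drum
#' lined with vertical black/white stripes at 0.2 cycles/degree, rotating at
#' 50 degrees/s and reversing direction every 20 s, recorded at 30 frames/s
#' for 480 s, with a 15 cm transparent cylinder on the central platform.
#' Every value is overridable so the package can serve other arenas.
#'
#' @param drum_diameter Drum diameter, cm.
#' @param drum_height Drum height, cm.
#' @param cylinder_diameter Diameter of the transparent mouse cylinder, cm;
#'   must be smaller than the drum diameter.
#' @param stripe_spatial_frequency Stripe spatial frequency, cycles per degree
#'   of visual angle. Multiplied by 360 this gives the number of full
#'   black/white cycles around the drum; the synthetic renderer requires that
#'   product to be a whole number (72 at the default).
#' @param drum_speed Drum rotation speed, degrees/s (positive magnitude).
#' @param alternation_period Duration of each constant-direction bout, s.
#' @param initial_direction `"CW"` or `"CCW"`: direction of the first bout.
#' @param frame_rate Acquisition frame rate, frames/s.
#' @param recording_length Nominal recording duration, s.
#' @param luminance_range Length-2 numeric, 8-bit display intensities
#'   `c(background, mouse)`: bright background, dark mouse.
#' @return An object of class `arena_config`.
#' @examples
#' cfg <- arena_config()
#' cfg$drum_speed
#' @export
arena_config <- function(drum_diameter = 22,
                         drum_height = 30,
                         cylinder_diameter = 15,
                         stripe_spatial_frequency = 0.2,
                         drum_speed = 50,
                         alternation_period = 20,
                         initial_direction = c("CW", "CCW"),
                         frame_rate = 30,
                         recording_length = 480,
                         luminance_range = c(220, 30)) {
  initial_direction <- match.arg(initial_direction)
  cfg <- list(
    drum_diameter = drum_diameter,
    drum_height = drum_height,
    cylinder_diameter = cylinder_diameter,
    stripe_spatial_frequency = stripe_spatial_frequency,
    drum_speed = drum_speed,
    alternation_period = alternation_period,
    initial_direction = initial_direction,
    frame_rate = frame_rate,
    recording_length = recording_length,
    luminance_range = luminance_range
  )
  class(cfg) <- "arena_config"
  validate_arena_config(cfg)
  cfg
}

validate_arena_config <- function(cfg) {
  problems <- character(0)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  chk(num1(cfg$drum_speed) && cfg$drum_speed > 0,
      "drum_speed: must be a positive number")
  chk(num1(cfg$alternation_period) && cfg$alternation_period > 0,
      "alternation_period: must be a positive number")
  chk(num1(cfg$frame_rate) && cfg$frame_rate > 0,
      "frame_rate: must be a positive number")
  chk(num1(cfg$stripe_spatial_frequency) && cfg$stripe_spatial_frequency > 0,
      "stripe_spatial_frequency: must be a positive number")
  chk(num1(cfg$recording_length) && cfg$recording_length > 0,
      "recording_length: must be a positive number")
  chk(num1(cfg$drum_diameter) && cfg$drum_diameter > 0,
      "drum_diameter: must be a positive number")
  chk(num1(cfg$cylinder_diameter) && cfg$cylinder_diameter > 0,
      "cylinder_diameter: must be a positive number")
  if (num1(cfg$cylinder_diameter) && num1(cfg$drum_diameter))
    chk(cfg$cylinder_diameter < cfg$drum_diameter,
        "cylinder_diameter: must be smaller than drum_diameter")
  chk(cfg$initial_direction %in% c("CW", "CCW"),
      "initial_direction: must be \"CW\" or \"CCW\"")
  chk(is.numeric(cfg$luminance_range) && length(cfg$luminance_range) == 2L &&
        all(cfg$luminance_range >= 0) && all(cfg$luminance_range <= 255) &&
        cfg$luminance_range[1] > cfg$luminance_range[2],
      "luminance_range: must be two 8-bit values c(background, mouse) with background > mouse")
  if (length(problems))
    stop("invalid arena configuration:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  invisible(cfg)
}

#' @export
print.arena_config <- function(x, ...) {
  cat("Optomotor arena configuration\n")
  cat(sprintf("  drum %.1f cm (h %.1f cm), cylinder %.1f cm\n",
              x$drum_diameter, x$drum_height, x$cylinder_diameter))
  cat(sprintf("  stripes %.3g cycles/degree (%d cycles/circumference)\n",
              x$stripe_spatial_frequency, n_stripe_cycles(x)))
  cat(sprintf("  drum speed %.1f deg/s, reversing every %.1f s (first bout %s)\n",
              x$drum_speed, x$alternation_period, x$initial_direction))
  cat(sprintf("  %.0f frames/s, %.0f s recording\n",
              x$frame_rate, x$recording_length))
  invisible(x)
}

# Number of full black/white cycles around the drum.
n_stripe_cycles <- function(config) {
  nc <- config$stripe_spatial_frequency * 360
  round(nc)
}

# Renderer precondition: whole number of cycles around the circumference.
check_integral_cycles <- function(config) {
  nc <- config$stripe_spatial_frequency * 360
  if (abs(nc - round(nc)) > 1e-9)
    stop(sprintf(
      "stripe_spatial_frequency: %g cycles/degree gives %g cycles around the drum; the renderer requires a whole number of cycles",
      config$stripe_spatial_frequency, nc), call. = FALSE)
  invisible(round(nc))
}

#' Image-space geometry of the monitored arena
#'
#' Locates the circular region in which the mouse is tracked and the
#' rectangular stripe band ("strip") directly above the arena center from
#' which the stimulus direction is read. The strip must lie fully inside the
#' frame and fully outside the mask circle.
#'
#' @param width,height Frame size in pixels.
#' @param center Numeric length-2, pixel coordinates `c(x, y)` of the
#'   monitored-area center (x = column, y = row; row 1 is the top of the
#'   image).
#' @param mask_radius Radius in pixels of the circular tracking region.
#' @param stripe_roi List with integer ranges `rows = c(first, last)` and
#'   `cols = c(first, last)` delimiting the stripe strip, or `NULL` to place
#'   a strip of `roi_width` pixels directly above the center covering the
#'   annulus between the mask circle and the frame edge.
#' @param roi_width Width in pixels of the auto-placed strip (ignored when
#'   `stripe_roi` is given). 48 px shows roughly two and a half stripe
#'   cycles of the default stimulus at the default geometry.
#' @return An object of class `arena_geometry`.
#' @examples
#' geo <- arena_geometry()
#' geo$mask_radius
#' @export
arena_geometry <- function(width = 480, height = 480,
                           center = c((width + 1) / 2, (height + 1) / 2),
                           mask_radius = 200,
                           stripe_roi = NULL,
                           roi_width = 48) {
  if (is.null(stripe_roi)) {
    cx <- center[1]; cy <- center[2]
    top_gap <- cy - 1                      # distance from center to top edge
    r_in <- mask_radius + 4
    r_out <- top_gap - 4
    if (r_out - r_in < 8)
      stop("arena_geometry: no room for a stripe strip between the mask circle and the top edge",
           call. = FALSE)
    rows <- c(ceiling(cy - r_out), floor(cy - r_in))
    cols <- c(floor(cx - roi_width / 2), floor(cx - roi_width / 2) + roi_width - 1L)
    stripe_roi <- list(rows = as.integer(rows), cols = as.integer(cols))
  }
  geo <- list(width = as.integer(width), height = as.integer(height),
              center = as.numeric(center), mask_radius = as.numeric(mask_radius),
              stripe_roi = lapply(stripe_roi, as.integer))
  class(geo) <- "arena_geometry"
  validate_arena_geometry(geo)
  geo
}

validate_arena_geometry <- function(geo) {
  problems <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  chk(geo$width > 0 && geo$height > 0, "width/height: must be positive")
  chk(is.numeric(geo$mask_radius) && geo$mask_radius > 0,
      "mask_radius: must be positive")
  chk(length(geo$center) == 2L && all(is.finite(geo$center)),
      "center: must be two finite pixel coordinates c(x, y)")
  roi <- geo$stripe_roi
  ok_roi <- is.list(roi) && all(c("rows", "cols") %in% names(roi)) &&
    length(roi$rows) == 2L && length(roi$cols) == 2L
  chk(ok_roi, "stripe_roi: must have integer ranges rows = c(a, b), cols = c(a, b)")
  if (ok_roi) {
    chk(roi$rows[1] >= 1 && roi$rows[2] <= geo$height &&
          roi$cols[1] >= 1 && roi$cols[2] <= geo$width &&
          roi$rows[1] <= roi$rows[2] && roi$cols[1] <= roi$cols[2],
        "stripe_roi: must lie fully inside the frame")
    # every ROI pixel must be outside the mask circle
    yy <- roi$rows[1]:roi$rows[2]; xx <- roi$cols[1]:roi$cols[2]
    d2 <- outer((yy - geo$center[2])^2, (xx - geo$center[1])^2, `+`)
    chk(all(d2 > geo$mask_radius^2),
        "stripe_roi: must lie fully outside the mask circle")
  }
  if (length(problems))
    stop("invalid arena geometry:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  invisible(geo)
}

#' @export
print.arena_geometry <- function(x, ...) {
  cat(sprintf("Arena geometry: %dx%d px, center (%.1f, %.1f), mask radius %.1f px\n",
              x$width, x$height, x$center[1], x$center[2], x$mask_radius))
  cat(sprintf("  stripe strip rows %d:%d, cols %d:%d\n",
              x$stripe_roi$rows[1], x$stripe_roi$rows[2],
              x$stripe_roi$cols[1], x$stripe_roi$cols[2]))
  invisible(x)
}

# Mean distance (px) from the arena center to the stripe-strip rows; the
# pixel scale used to convert drum rotation (degrees) into lateral strip
# displacement (px).
stripe_roi_radius <- function(geometry) {
  geometry$center[2] - mean(geometry$stripe_roi$rows[1]:geometry$stripe_roi$rows[2])
}

#' Package-wide angle and rotation conventions
#'
#' All angles are measured in image (overhead-camera) coordinates. The
#' position angle of the mouse is the clockwise angle from the upward
#' vertical through the arena center to the center-to-centroid ray: 0 deg is
#' directly above the center, 90 deg to the right, 180 deg below, 270 deg to
#' the left. The body-orientation angle is axial (modulo 180 deg), measured
#' clockwise from the image vertical: 0 deg is a vertical body axis, 90 deg
#' horizontal. Clockwise angular velocity is positive; "CW"/"CCW" refer to
#' rotation as seen by the overhead camera.
#'
#' @return A named list stating the conventions (ranges, zero directions,
#'   sign of clockwise motion).
#' @export
angle_conventions <- function() {
  list(
    position_angle = list(range = c(0, 360), zero = "up (12 o'clock)",
                          positive = "clockwise", right = 90),
    orientation_angle = list(range = c(0, 180), zero = "vertical body axis",
                             positive = "clockwise", horizontal = 90),
    angular_velocity = list(units = "degrees/s", positive = "clockwise"),
    frame_coordinates = "x = column (rightward), y = row (downward), row 1 at the top"
  )
}

dir_sign <- function(direction) {
  ifelse(direction == "CW", 1, ifelse(direction == "CCW", -1, 0))
}

opposite_direction <- function(direction) {
  ifelse(direction == "CW", "CCW", ifelse(direction == "CCW", "CW", direction))
}

#' Programmed drum direction at a given time
#'
#' Pure ground-truth schedule of the motor: the drum holds its direction for
#' `alternation_period` seconds, then reverses, starting from
#' `initial_direction` at t = 0. Bouts are half-open: a boundary instant
#' belongs to the later bout. The analysis pipeline never reads this; it is
#' used by the simulator and for validation.
#'
#' @param config An [arena_config()].
#' @param t Time(s) in seconds, non-negative; vectorized.
#' @return Character vector of `"CW"`/`"CCW"`.
#' @examples
#' cfg <- arena_config()
#' stimulus_direction_schedule(cfg, c(5, 25))
#' @export
stimulus_direction_schedule <- function(config, t) {
  stopifnot(inherits(config, "arena_config"))
  if (!is.numeric(t) || any(!is.finite(t)))
    stop("t must be finite and numeric", call. = FALSE)
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  bout <- floor(t / config$alternation_period)
  ifelse(bout %% 2 == 0, config$initial_direction,
         opposite_direction(config$initial_direction))
}

# Net signed drum rotation (degrees, CW positive) accumulated from time 0 to
# t under the alternation schedule. Closed form: complete bouts alternate
# +/- speed*P and cancel pairwise.
stimulus_phase <- function(config, t) {
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  P <- config$alternation_period
  s0 <- dir_sign(config$initial_direction)
  n <- floor(t / P)
  r <- t - n * P
  s0 * config$drum_speed * (P * (n %% 2) + (-1)^n * r)
}

# Mouse heading schedule: the drum schedule delayed by `latency` seconds
# after each reversal (the pre-start direction is the initial direction).
delayed_phase <- function(config, t, latency) {
  if (latency <= 0) return(stimulus_phase(config, t))
  s0 <- dir_sign(config$initial_direction)
  ifelse(t <= latency,
         s0 * config$drum_speed * t,
         s0 * config$drum_speed * latency +
           stimulus_phase(config, pmax(t - latency, 0)))
}
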