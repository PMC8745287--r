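#' Behavior parameters for the simulated mouse
#'
#' Controls the synthetic animal: how strongly it follows the drum
#' (`following_gain`, as a fraction of the drum's angular speed), how long
#' after each stimulus reversal it reverses (`response_latency`), per-frame
#' Gaussian jitter on both angles, and the ellipse used to render its body.
#' The animal sits at a fixed radius of 0.6 x mask_radius, a simulator
#' simplification of the real animal's varying radial position.
#'
#' @param following_gain Fraction of the drum speed tracked, in \[0, 1\].
#' @param response_latency Seconds after each reversal before the simulated
#'   animal reverses; non-negative.
#' @param angle_noise_sd Per-frame Gaussian jitter (degrees) added to the
#'   position and orientation angles.
#' @param body_length,body_width Ellipse axes in pixels; length > width > 0
#'   so the rendered orientation is unambiguous.
#' @param seed Integer seed; trajectories are fully reproducible given
#'   (config, behavior, seed).
#' @return An object of class `behavior_params`.
#' @export
behavior_params <- function(following_gain = 1, response_latency = 0,
                            angle_noise_sd = 0, body_length = 60,
                            body_width = 24, seed = 1L) {
  if (!is.numeric(following_gain) || following_gain < 0 || following_gain > 1)
    stop("following_gain must lie in [0, 1]", call. = FALSE)
  if (response_latency < 0) stop("response_latency must be >= 0", call. = FALSE)
  if (angle_noise_sd < 0) stop("angle_noise_sd must be >= 0", call. = FALSE)
  if (!(body_length > body_width && body_width > 0))
    stop("need body_length > body_width > 0", call. = FALSE)
  structure(list(following_gain = following_gain,
                 response_latency = response_latency,
                 angle_noise_sd = angle_noise_sd,
                 body_length = body_length, body_width = body_width,
                 seed = as.integer(seed)),
            class = "behavior_params")
}

# Precomputed per-geometry lookup for the stimulus renderer: linear indices
# and position angles (deg) of the annulus outside the mask circle, plus the
# inside-mask index.
stimulus_canvas <- function(geometry) {
  h <- geometry$height; w <- geometry$width
  cx <- geometry$center[1]; cy <- geometry$center[2]
  dx <- matrix(rep(seq_len(w) - cx, each = h), h, w)
  dy <- matrix(rep(seq_len(h) - cy, times = w), h, w)
  outside <- which(dx^2 + dy^2 > geometry$mask_radius^2)
  theta <- atan2(dx[outside], -dy[outside]) * 180 / pi
  list(h = h, w = w, outside = outside, theta = theta)
}

#' Render one frame of the rotating stripe stimulus
#'
#' Draws the stripe band as the annulus outside the circular tracking region:
#' `round(360 * stripe_spatial_frequency)` full black/white cycles span the
#' circumference (72 at the defaults), rotated by the net drum rotation
#' accumulated up to time `t` under the alternation schedule. The region
#' inside the mask circle is the bright platform. In the strip directly above
#' the center the pattern appears as vertical stripes, and clockwise drum
#' rotation moves it to the right.
#'
#' @param config An [arena_config()]; the cycle count must be integral.
#' @param geometry An [arena_geometry()].
#' @param t Time in seconds.
#' @param canvas Optional precomputed canvas (internal; reused across frames
#'   for speed).
#' @return Grayscale matrix (0-255) of size `height` x `width`.
#' @export
render_stimulus_frame <- function(config, geometry, t, canvas = NULL) {
  ncyc <- check_integral_cycles(config)
  if (is.null(canvas)) canvas <- stimulus_canvas(geometry)
  phase <- stimulus_phase(config, t)
  img <- matrix(config$luminance_range[1], canvas$h, canvas$w)
  frac <- ((canvas$theta - phase) * ncyc / 360) %% 1
  img[canvas$outside] <- ifelse(frac < 0.5, 0, 255)
  img
}

# Paint the mouse as a filled dark ellipse: center (mx, my) px, major
# semi-axis a along the axial direction `orient_deg` (clockwise from the
# image vertical), minor semi-axis b.
draw_mouse <- function(img, mx, my, orient_deg, a, b, intensity) {
  h <- nrow(img); w <- ncol(img)
  x0 <- max(1L, floor(mx - a - 1)); x1 <- min(w, ceiling(mx + a + 1))
  y0 <- max(1L, floor(my - a - 1)); y1 <- min(h, ceiling(my + a + 1))
  if (x0 > x1 || y0 > y1) return(img)
  xs <- x0:x1; ys <- y0:y1
  th <- orient_deg * pi / 180
  ux <- sin(th); uy <- -cos(th)          # unit vector along the body axis
  dx <- matrix(rep(xs - mx, each = length(ys)), length(ys), length(xs))
  dy <- matrix(rep(ys - my, times = length(xs)), length(ys), length(xs))
  t1 <- dx * ux + dy * uy
  t2 <- -dx * uy + dy * ux
  inside <- (t1 / a)^2 + (t2 / b)^2 <= 1
  sub <- img[ys, xs, drop = FALSE]
  sub[inside] <- intensity
  img[ys, xs] <- sub
  img
}

#' Simulate a ground-truth mouse trajectory
#'
#' The position angle integrates `following_gain` x drum speed in the drum
#' direction delayed by `response_latency`, with per-frame Gaussian jitter;
#' the body orientation is tangential to the motion (perpendicular to the
#' center ray) with the same jitter model. The radial distance is fixed at
#' 0.6 x mask_radius.
#'
#' @param config An [arena_config()].
#' @param behavior A [behavior_params()].
#' @param duration Trajectory length in seconds (> 0).
#' @param geometry An [arena_geometry()] (sets the stripe-strip radius used
#'   to express the ground-truth stripe shift in pixels).
#' @return Data frame with one row per frame: `frame`, `time_s`,
#'   `true_position_angle`, `true_orientation_angle`, `true_stim_direction`,
#'   `true_stim_phase_shift_px` (`NA` on frame 0).
#' @export
simulate_mouse <- function(config, behavior, duration,
                           geometry = arena_geometry()) {
  if (!is.numeric(duration) || duration <= 0)
    stop("duration must be positive", call. = FALSE)
  n <- round(duration * config$frame_rate)
  t <- (seq_len(n) - 1L) / config$frame_rate
  base_pos <- behavior$following_gain *
    delayed_phase(config, t, behavior$response_latency)
  noise <- with_seed(behavior$seed, list(
    pos = stats::rnorm(n, 0, behavior$angle_noise_sd),
    ori = stats::rnorm(n, 0, behavior$angle_noise_sd)
  ))
  pos <- fold_angle(base_pos + noise$pos, 360)
  ori <- fold_angle(pos + 90 + noise$ori, 180)
  phase <- stimulus_phase(config, t)
  px_per_deg <- stripe_roi_radius(geometry) * pi / 180
  shift_px <- c(NA_real_, diff(phase) * px_per_deg)
  data.frame(frame = seq_len(n) - 1L,
             time_s = t,
             true_position_angle = pos,
             true_orientation_angle = ori,
             true_stim_direction = stimulus_direction_schedule(config, t),
             true_stim_phase_shift_px = shift_px)
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Render a full synthetic optomotor trial
#'
#' Generates a ground-truth trajectory with [simulate_mouse()] and a lazy
#' frame source rendering, per frame, the rotating stripe annulus, the bright
#' central platform and the mouse as a dark ellipse at the true position and
#' orientation. Every mouse pixel is strictly darker than every background
#' pixel inside the mask, so segmentation is well-posed by construction.
#' Optionally writes the frames as numbered PNGs plus the ground-truth CSV.
#'
#' @param config An [arena_config()].
#' @param geometry An [arena_geometry()].
#' @param behavior A [behavior_params()], or `NULL` for a stimulus-only trial
#'   (no mouse; the ground truth then has no pose columns).
#' @param duration Trial length, seconds.
#' @param dir Optional output directory; if given, frames are written as
#'   `frame_000000.png`, ... together with `ground_truth.csv`.
#' @return List with `frames` (a [frame_source]), `truth` (data frame), and,
#'   when `dir` is given, `dir`.
#' @export
render_trial <- function(config, geometry = arena_geometry(),
                         behavior = behavior_params(), duration = 10,
                         dir = NULL) {
  check_integral_cycles(config)
  canvas <- stimulus_canvas(geometry)
  r_mouse <- 0.6 * geometry$mask_radius
  cx <- geometry$center[1]; cy <- geometry$center[2]
  if (is.null(behavior)) {
    n <- round(duration * config$frame_rate)
    t <- (seq_len(n) - 1L) / config$frame_rate
    px_per_deg <- stripe_roi_radius(geometry) * pi / 180
    truth <- data.frame(frame = seq_len(n) - 1L, time_s = t,
                        true_stim_direction = stimulus_direction_schedule(config, t),
                        true_stim_phase_shift_px =
                          c(NA_real_, diff(stimulus_phase(config, t)) * px_per_deg))
  } else {
    truth <- simulate_mouse(config, behavior, duration, geometry)
  }
  mouse_dark <- config$luminance_range[2]
  get_frame <- function(i) {
    tt <- truth$time_s[i]
    img <- render_stimulus_frame(config, geometry, tt, canvas = canvas)
    if (!is.null(behavior)) {
      th <- truth$true_position_angle[i] * pi / 180
      mx <- cx + r_mouse * sin(th)
      my <- cy - r_mouse * cos(th)
      img <- draw_mouse(img, mx, my, truth$true_orientation_angle[i],
                        behavior$body_length / 2, behavior$body_width / 2,
                        mouse_dark)
    }
    img
  }
  frames <- frame_source(n_frames = nrow(truth), frame_rate = config$frame_rate,
                         get_frame = get_frame)
  out <- list(frames = frames, truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (i in seq_len(frames$n_frames)) {
      path <- file.path(dir, sprintf("frame_%06d.png", i - 1L))
      ok <- tryCatch({ png::writePNG(get_frame(i) / 255, path); TRUE },
                     error = function(e) e)
      if (!isTRUE(ok))
        stop(sprintf("failed to write %s: %s", path, conditionMessage(ok)),
             call. = FALSE)
    }
    utils::write.csv(truth, file.path(dir, "ground_truth.csv"),
                     row.names = FALSE)
    out$dir <- dir
  }
  out
}
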