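#' Convert a frame to grayscale
#'
#' Color frames (H x W x 3 arrays) are reduced with the standard luminance
#' weights 0.299 R + 0.587 G + 0.114 B; grayscale matrices pass through
#' unchanged. Frames on the 8-bit scale (values above 1) are rounded to
#' integer intensities after mixing.
#'
#' @param frame Numeric matrix (grayscale) or H x W x 3 array (RGB), either
#'   8-bit (0-255) or float in \[0, 1\].
#' @return Grayscale numeric matrix with the dimensions of the input.
#' @examples
#' red <- array(c(255, 0, 0), dim = c(1, 1, 3))
#' to_grayscale(red)   # 76
#' @export
to_grayscale <- function(frame) {
  if (is.matrix(frame)) return(frame)
  if (is.array(frame) && length(dim(frame)) == 3L) {
    nc <- dim(frame)[3]
    if (nc == 1L) return(frame[, , 1L])
    if (nc != 3L)
      stop(sprintf("unsupported channel count: %d (expected 1 or 3)", nc),
           call. = FALSE)
    g <- 0.299 * frame[, , 1L] + 0.587 * frame[, , 2L] + 0.114 * frame[, , 3L]
    if (max(frame, na.rm = TRUE) > 1) g <- round(g)
    return(g)
  }
  stop("frame must be a matrix or an H x W x 3 array", call. = FALSE)
}

# Linear indices of pixels strictly outside the mask circle (closed disc is
# kept). Precomputed once per geometry in the drivers.
mask_outside_index <- function(geometry, nrow, ncol) {
  cx <- geometry$center[1]; cy <- geometry$center[2]
  d2 <- outer((seq_len(nrow) - cy)^2, (seq_len(ncol) - cx)^2, `+`)
  which(d2 > geometry$mask_radius^2)
}

#' Blank everything outside the circular tracking region
#'
#' Pixels farther than `mask_radius` from the arena center are replaced by
#' `fill` (by default the bright background intensity, so that masked-out
#' pixels can never survive the dark-object segmentation); pixels on or
#' inside the circle are untouched.
#'
#' @param gray Grayscale numeric matrix.
#' @param geometry An [arena_geometry()].
#' @param fill Replacement intensity for masked-out pixels (default 255).
#' @param strict If `TRUE` (default) a mask circle extending beyond the frame
#'   bounds is an error; if `FALSE` it is clipped with a warning.
#' @return Masked grayscale matrix.
#' @export
apply_circular_mask <- function(gray, geometry, fill = 255, strict = TRUE) {
  stopifnot(is.matrix(gray))
  cx <- geometry$center[1]; cy <- geometry$center[2]; r <- geometry$mask_radius
  if (cx - r < 1 - 0.5 || cx + r > ncol(gray) + 0.5 ||
      cy - r < 1 - 0.5 || cy + r > nrow(gray) + 0.5) {
    msg <- sprintf("mask circle (center %.1f, %.1f; radius %.1f) exceeds the %dx%d frame",
                   cx, cy, r, ncol(gray), nrow(gray))
    if (strict) stop(msg, call. = FALSE) else warning(msg, "; clipping", call. = FALSE)
  }
  gray[mask_outside_index(geometry, nrow(gray), ncol(gray))] <- fill
  gray
}

#' Segment the mouse as the dark object on the bright floor
#'
#' Constant-threshold binarization with inversion: pixels strictly darker
#' than `threshold` become foreground (1), everything else background (0).
#' Applied after [apply_circular_mask()] with a bright fill, the masked-out
#' region is always background.
#'
#' @param masked Masked grayscale matrix.
#' @param threshold Intensity cutoff on the frame's scale (default 128 on
#'   the 8-bit scale). A pixel exactly at the threshold is background.
#' @return Integer 0/1 matrix of the same dimensions.
#' @export
segment_mouse <- function(masked, threshold = 128) {
  stopifnot(is.matrix(masked), is.numeric(threshold), length(threshold) == 1L)
  m <- matrix(0L, nrow(masked), ncol(masked))
  m[masked < threshold] <- 1L
  m
}

# Foreground pixel coordinates as a two-column matrix (x = col, y = row).
foreground_xy <- function(mask) {
  idx <- which(mask != 0)
  if (!length(idx)) return(matrix(numeric(0), 0, 2))
  nr <- nrow(mask)
  cbind(x = ((idx - 1) %/% nr) + 1, y = ((idx - 1) %% nr) + 1)
}

#' Position angle of the segmented mouse
#'
#' The clockwise angle from the upward vertical through the arena center to
#' the ray joining the center and the foreground centroid, in \[0, 360):
#' 0 deg directly above the center, 90 deg to the right.
#'
#' @param mask Binary 0/1 matrix (foreground = mouse).
#' @param geometry An [arena_geometry()].
#' @param min_foreground Minimum number of foreground pixels required; below
#'   it the angle is `NA`. The geometric primitive defaults to 1 px; the
#'   tracking pipeline applies its own quality gate (default 50 px).
#' @param eps If the centroid lies within `eps` pixels of the center the
#'   direction is undefined and `NA` is returned.
#' @return Angle in degrees in \[0, 360), or `NA`.
#' @examples
#' geo <- arena_geometry(width = 200, height = 200, mask_radius = 80)
#' m <- matrix(0L, 200, 200); m[100:101, 150:155] <- 1L  # blob to the right
#' position_angle(m, geo)
#' @export
position_angle <- function(mask, geometry, min_foreground = 1, eps = 1) {
  xy <- foreground_xy(mask)
  if (nrow(xy) < min_foreground) return(NA_real_)
  dx <- mean(xy[, 1]) - geometry$center[1]
  dy <- mean(xy[, 2]) - geometry$center[2]
  if (sqrt(dx^2 + dy^2) < eps) return(NA_real_)
  fold_angle(atan2(dx, -dy) * 180 / pi, 360)
}

#' Body-orientation angle of the segmented mouse
#'
#' Fits the major principal axis of the foreground pixel cloud (the line
#' through the centroid minimizing summed squared orthogonal distances) and
#' returns its clockwise angle from the image vertical, folded into
#' \[0, 180): 0 deg vertical, 90 deg horizontal. The axis is undirected, so
#' head and tail are interchangeable.
#'
#' @inheritParams position_angle
#' @param iso_tol Relative tolerance on the principal variances: when
#'   `(var1 - var2) <= iso_tol * var1` the blob is treated as isotropic and
#'   `NA` is returned (the axis is undefined).
#' @return Angle in degrees in \[0, 180), or `NA`.
#' @examples
#' bar <- matrix(0L, 50, 50); bar[25, 10:30] <- 1L  # horizontal bar
#' orientation_angle(bar)   # 90
#' @export
orientation_angle <- function(mask, min_foreground = 1, iso_tol = 0.05) {
  xy <- foreground_xy(mask)
  n <- nrow(xy)
  if (n < min_foreground || n < 2L) return(NA_real_)
  xc <- xy[, 1] - mean(xy[, 1]); yc <- xy[, 2] - mean(xy[, 2])
  sxx <- sum(xc * xc) / n; syy <- sum(yc * yc) / n; sxy <- sum(xc * yc) / n
  ev <- eigen(matrix(c(sxx, sxy, sxy, syy), 2, 2), symmetric = TRUE)
  l1 <- ev$values[1]; l2 <- ev$values[2]
  if (l1 <= 0 || (l1 - l2) <= iso_tol * l1) return(NA_real_)
  v <- ev$vectors[, 1]
  fold_angle(atan2(v[1], -v[2]) * 180 / pi, 180)
}

# Largest 4-connected foreground component (optional cleanup for noisy
# recordings; off by default in the pipeline).
largest_component <- function(mask) {
  idx <- which(mask != 0)
  if (length(idx) <= 1L) return(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- integer(nr * nc)
  best <- integer(0)
  for (seed in idx) {
    if (lab[seed]) next
    comp <- integer(0)
    queue <- seed; lab[seed] <- 1L
    while (length(queue)) {
      p <- queue[length(queue)]; queue <- queue[-length(queue)]
      comp <- c(comp, p)
      r <- ((p - 1) %% nr) + 1
      nb <- c(if (r > 1) p - 1, if (r < nr) p + 1, p - nr, p + nr)
      nb <- nb[nb >= 1 & nb <= nr * nc]
      nb <- nb[mask[nb] != 0 & lab[nb] == 0L]
      lab[nb] <- 1L
      queue <- c(queue, nb)
    }
    if (length(comp) > length(best)) best <- comp
  }
  out <- matrix(0L, nr, nc)
  out[best] <- 1L
  out
}

#' Track the mouse across a sequence of frames
#'
#' Runs the per-frame pose chain — grayscale conversion, circular masking,
#' constant-threshold segmentation, centroid position angle and
#' principal-axis orientation — over a frame sequence. A frame is valid only
#' when both angles are computable; invalid frames carry `NA` for both
#' angles (never zero-filled), and downstream velocities at the gap are
#' missing.
#'
#' @param frames A [frame_source], a list of frames, or an H x W x N array.
#' @param geometry An [arena_geometry()].
#' @param threshold Segmentation intensity cutoff (8-bit scale).
#' @param min_foreground Minimum foreground pixel count for a valid pose.
#' @param eps,iso_tol Degeneracy tolerances, see [position_angle()] and
#'   [orientation_angle()].
#' @param fill Mask fill intensity.
#' @param use_largest_component If `TRUE`, keep only the largest 4-connected
#'   foreground component before measuring angles.
#' @param verbose Emit a QC message with valid/missing counts.
#' @return A data frame with one row per frame: `frame` (0-based),
#'   `time_s`, `position_angle_deg`, `orientation_angle_deg`,
#'   `foreground_px`, `valid`.
#' @export
track_frames <- function(frames, geometry, threshold = 128,
                         min_foreground = 50, eps = 1, iso_tol = 0.05,
                         fill = 255, use_largest_component = FALSE,
                         verbose = FALSE) {
  src <- as_frame_source(frames)
  n <- src$n_frames
  if (n < 1L) stop("at least one frame is required", call. = FALSE)
  out_idx <- NULL   # lazily sized to the first frame
  pos <- ori <- rep(NA_real_, n)
  fg <- integer(n)
  for (i in seq_len(n)) {
    f <- tryCatch(to_grayscale(src$get_frame(i)), error = function(e) NULL)
    if (is.null(f)) next
    if (is.null(out_idx)) out_idx <- mask_outside_index(geometry, nrow(f), ncol(f))
    f[out_idx] <- fill
    m <- segment_mouse(f, threshold)
    if (use_largest_component) m <- largest_component(m)
    fg[i] <- sum(m)
    pos[i] <- position_angle(m, geometry, min_foreground = min_foreground, eps = eps)
    ori[i] <- orientation_angle(m, min_foreground = min_foreground, iso_tol = iso_tol)
  }
  valid <- !is.na(pos) & !is.na(ori)
  pos[!valid] <- NA_real_
  ori[!valid] <- NA_real_
  if (verbose)
    message(sprintf("track_frames: %d/%d frames valid (%d below %d foreground px or degenerate)",
                    sum(valid), n, n - sum(valid), min_foreground))
  data.frame(frame = seq_len(n) - 1L,
             time_s = (seq_len(n) - 1L) / src$frame_rate,
             position_angle_deg = pos,
             orientation_angle_deg = ori,
             foreground_px = fg,
             valid = valid)
}
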