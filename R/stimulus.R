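#' Intensity profile of the stripe strip
#'
#' Cuts the rectangular stripe region directly above the arena center out of
#' a grayscale frame and collapses it to a 1-D profile of column means. In
#' that cut the drum stripes are (near-)vertical, so the 1-D profile retains
#' all direction information while averaging out row noise.
#'
#' @param frame Grayscale matrix or RGB array (converted internally).
#' @param geometry An [arena_geometry()] whose `stripe_roi` lies inside the
#'   frame.
#' @return Numeric vector of length `diff(stripe_roi$cols) + 1`.
#' @export
extract_stripe_strip <- function(frame, geometry) {
  g <- to_grayscale(frame)
  roi <- geometry$stripe_roi
  if (roi$rows[1] < 1 || roi$rows[2] > nrow(g) ||
      roi$cols[1] < 1 || roi$cols[2] > ncol(g))
    stop(sprintf("stripe_roi (rows %d:%d, cols %d:%d) lies outside the %dx%d frame",
                 roi$rows[1], roi$rows[2], roi$cols[1], roi$cols[2],
                 nrow(g), ncol(g)), call. = FALSE)
  colMeans(g[roi$rows[1]:roi$rows[2], roi$cols[1]:roi$cols[2], drop = FALSE])
}

#' Adaptive binarization of a 1-D intensity profile
#'
#' Each sample is compared to the mean of its centered neighborhood of
#' `window` samples (the window shrinks at the profile edges): strictly
#' above the local mean gives 1, otherwise 0. This makes the stripe pattern
#' robust to slow illumination gradients along the strip.
#'
#' @param profile Numeric vector of intensities.
#' @param window Odd integer window length, at least 3 and at most the
#'   profile length.
#' @return Integer 0/1 vector of the same length.
#' @examples
#' binarize_adaptive(rep(c(0, 255), each = 8, times = 4), window = 15)
#' @export
binarize_adaptive <- function(profile, window = 15) {
  n <- length(profile)
  if (!is.numeric(window) || length(window) != 1L || window < 3 ||
      window %% 2 == 0)
    stop("window must be an odd integer >= 3", call. = FALSE)
  if (n < window)
    stop(sprintf("profile length (%d) must be at least the window (%d)", n, window),
         call. = FALSE)
  h <- (window - 1) / 2
  cs <- cumsum(c(0, profile))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  local_mean <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  as.integer(profile > local_mean)
}

# Fraction of agreeing samples between `current` and `previous` displaced
# rightward by s (overlap region only).
shift_agreement <- function(current, previous, s) {
  n <- length(current)
  if (s >= 0) {
    i <- seq.int(1 + s, n)
  } else {
    i <- seq.int(1, n + s)
  }
  mean(current[i] == previous[i - s])
}

#' Infer drum rotation direction from two successive stripe profiles
#'
#' Scans integer lateral shifts of the previous binarized stripe profile and
#' picks the shift maximizing the fraction of agreeing samples (binary
#' cross-correlation). Ties are broken toward the smallest absolute shift,
#' then toward the positive shift. Rightward pattern motion in the strip
#' above the center corresponds to clockwise drum rotation under the package
#' angle conventions; `invert` accommodates mirrored camera mounts.
#'
#' @param current,previous Equal-length binary (0/1) profiles.
#' @param max_shift Largest shift magnitude scanned, px; default one quarter
#'   of the profile length. Must satisfy
#'   `1 <= min_shift <= max_shift < length/2`.
#' @param min_shift Smallest shift magnitude accepted as real motion, px.
#' @param min_confidence Minimum agreement fraction for a direction call.
#' @param invert Flip the sign-to-direction mapping.
#' @return List with `direction` (`"CW"`, `"CCW"` or `"UNKNOWN"`),
#'   `phase_shift` (signed px) and `confidence` (agreement fraction in
#'   \[0, 1\]).
#' @export
infer_direction <- function(current, previous, max_shift = NULL,
                            min_shift = 1, min_confidence = 0.6,
                            invert = FALSE) {
  n <- length(current)
  if (length(previous) != n)
    stop("current and previous profiles must have equal length", call. = FALSE)
  if (is.null(max_shift)) max_shift <- max(1L, floor(n / 4))
  if (min_shift < 1 || min_shift > max_shift || max_shift >= n / 2)
    stop("need 1 <= min_shift <= max_shift < profile length / 2", call. = FALSE)
  # candidate order encodes the tie-break: smallest |s| first, + before -
  cand <- 0L
  for (s in seq_len(max_shift)) cand <- c(cand, s, -s)
  best_s <- 0L; best_a <- -Inf
  for (s in cand) {
    a <- shift_agreement(current, previous, s)
    if (a > best_a) { best_a <- a; best_s <- s }
  }
  direction <- if (abs(best_s) < min_shift || best_a < min_confidence) {
    "UNKNOWN"
  } else if ((best_s > 0) != invert) "CW" else "CCW"
  list(direction = direction, phase_shift = best_s, confidence = best_a)
}

# Majority-vote relabeling of isolated direction flips: each frame with a
# known direction adopts the strict majority of known directions in a
# centered window of `w` frames; ties keep the original label. UNKNOWN
# frames are never relabeled.
smooth_directions <- function(direction, w = 5) {
  if (w <= 1) return(direction)
  n <- length(direction)
  h <- floor(w / 2)
  out <- direction
  for (i in seq_len(n)) {
    if (direction[i] == "UNKNOWN") next
    win <- direction[max(1, i - h):min(n, i + h)]
    ncw <- sum(win == "CW"); nccw <- sum(win == "CCW")
    if (ncw > nccw) out[i] <- "CW" else if (nccw > ncw) out[i] <- "CCW"
  }
  out
}

#' Per-frame drum direction from a frame sequence
#'
#' Driver over [extract_stripe_strip()], [binarize_adaptive()] and
#' [infer_direction()]: extracts and binarizes the stripe strip of every
#' frame, estimates the lateral pattern shift against the previous frame,
#' and calls the rotation direction. The first frame is always `UNKNOWN`.
#' Isolated single-frame flips are removed by centered majority voting.
#'
#' @param frames A [frame_source], list of frames, or H x W x N array (at
#'   least 2 frames).
#' @param geometry An [arena_geometry()].
#' @param window Adaptive-threshold window (odd, px).
#' @param smooth_window Width of the majority-vote window in frames; 1
#'   disables smoothing.
#' @inheritParams infer_direction
#' @return Data frame with one row per frame: `frame` (0-based), `time_s`,
#'   `direction` (smoothed), `phase_shift_px`, `confidence`.
#' @export
detect_directions <- function(frames, geometry, window = 15,
                              max_shift = NULL, min_shift = 1,
                              min_confidence = 0.6, smooth_window = 5,
                              invert = FALSE) {
  src <- as_frame_source(frames)
  n <- src$n_frames
  if (n < 2L) stop("at least two frames are required", call. = FALSE)
  direction <- rep("UNKNOWN", n)
  shift <- rep(NA_real_, n)
  conf <- rep(NA_real_, n)
  prev <- NULL
  for (i in seq_len(n)) {
    prof <- binarize_adaptive(extract_stripe_strip(src$get_frame(i), geometry),
                              window = window)
    if (!is.null(prev)) {
      est <- infer_direction(prof, prev, max_shift = max_shift,
                             min_shift = min_shift,
                             min_confidence = min_confidence, invert = invert)
      direction[i] <- est$direction
      shift[i] <- est$phase_shift
      conf[i] <- est$confidence
    }
    prev <- prof
  }
  data.frame(frame = seq_len(n) - 1L,
             time_s = (seq_len(n) - 1L) / src$frame_rate,
             direction = smooth_directions(direction, smooth_window),
             phase_shift_px = shift,
             confidence = conf)
}

#' Direction-reversal events in a detected direction series
#'
#' A reversal is a frame at which the (smoothed) known direction differs
#' from the last preceding known direction. Leading `UNKNOWN` frames and the
#' first known direction do not count as reversals.
#'
#' @param detections Data frame from [detect_directions()] (columns `frame`,
#'   `time_s`, `direction`).
#' @return Data frame of reversal events with columns `frame` and `time_s`.
#' @export
reversal_events <- function(detections) {
  known <- detections$direction %in% c("CW", "CCW")
  idx <- which(known)
  if (length(idx) < 2L)
    return(detections[integer(0), c("frame", "time_s")])
  d <- detections$direction[idx]
  flips <- idx[-1][d[-1] != d[-length(d)]]
  detections[flips, c("frame", "time_s"), drop = FALSE]
}
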