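#' Minimal signed displacement between circular angles
#'
#' Returns the smallest signed rotation (clockwise positive) taking angle `a`
#' to angle `b` on a circle of the given period: 360 for position angles,
#' 180 for axial (orientation) angles. The result lies in
#' `(-period/2, period/2]`.
#'
#' @param a,b Angles in degrees; vectorized (recycled to a common length).
#' @param period Circle period in degrees: 360 for directed angles, 180 for
#'   axial angles. Must be a single positive finite number.
#' @return Signed displacement(s) in degrees.
#' @examples
#' angular_difference(350, 10)        # +20: wraps across 0
#' angular_difference(10, 350)        # -20
#' angular_difference(175, 5, 180)    # +10 on the axial circle
#' @export
angular_difference <- function(a, b, period = 360) {
  if (!is.numeric(period) || length(period) != 1L || !is.finite(period) ||
      period <= 0)
    stop("period must be a single positive number", call. = FALSE)
  d <- (b - a) %% period
  d[!is.na(d) & d > period / 2] <- d[!is.na(d) & d > period / 2] - period
  d
}

# Fold an angle into [0, period).
fold_angle <- function(a, period = 360) a %% period
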