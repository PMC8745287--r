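# Shared fixtures and independent brute-force oracles.

# Small arena for mask-level tests: 101x101 frame, integer center.
tiny_geometry <- function(size = 101, mask_radius = 40) {
  arena_geometry(width = size, height = size,
                 center = c((size + 1) / 2, (size + 1) / 2),
                 mask_radius = mask_radius,
                 stripe_roi = list(rows = c(2L, 6L), cols = c(31L, 70L)))
}

# Binary mask from explicit (x, y) pixel coordinates.
mask_from_points <- function(xy, size = 101) {
  m <- matrix(0L, size, size)
  m[cbind(xy[, 2], xy[, 1])] <- 1L  # row = y, col = x
  m
}

# Filled disc blob centered at (x, y).
disc_mask <- function(x, y, r, size = 101) {
  g <- expand.grid(px = seq_len(size), py = seq_len(size))
  keep <- (g$px - x)^2 + (g$py - y)^2 <= r^2
  mask_from_points(cbind(g$px[keep], g$py[keep]), size)
}

# Rotate a mask's foreground pixels clockwise by phi degrees about the
# arena center (nearest-neighbor resampling of the pixel list).
rotate_mask <- function(mask, geometry, phi) {
  xy <- which(mask != 0, arr.ind = TRUE)  # row (y), col (x)
  dx <- xy[, 2] - geometry$center[1]
  dy <- xy[, 1] - geometry$center[2]
  th <- atan2(dx, -dy) + phi * pi / 180
  r <- sqrt(dx^2 + dy^2)
  nx <- round(geometry$center[1] + r * sin(th))
  ny <- round(geometry$center[2] - r * cos(th))
  keep <- nx >= 1 & nx <= ncol(mask) & ny >= 1 & ny <= nrow(mask)
  mask_from_points(unique(cbind(nx[keep], ny[keep])), nrow(mask))
}

# Brute-force orientation oracle: scan axis angles on a 0.1 degree grid and
# minimize the summed squared orthogonal distances of the centered pixel
# cloud to the axis.
oracle_orientation <- function(mask) {
  xy <- which(mask != 0, arr.ind = TRUE)
  x <- xy[, 2] - mean(xy[, 2]); y <- xy[, 1] - mean(xy[, 1])
  grid <- seq(0, 179.9, by = 0.1)
  cost <- vapply(grid, function(a) {
    th <- a * pi / 180
    ux <- sin(th); uy <- -cos(th)
    sum(x^2 + y^2) - sum((x * ux + y * uy)^2)
  }, numeric(1))
  grid[which.min(cost)]
}

# Brute-force adaptive-threshold oracle: explicit loop over shrinking
# centered windows.
oracle_binarize <- function(profile, window) {
  h <- (window - 1) / 2
  n <- length(profile)
  vapply(seq_len(n), function(i) {
    win <- profile[max(1, i - h):min(n, i + h)]
    as.integer(profile[i] > mean(win))
  }, integer(1))
}

# Brute-force shift-agreement oracle with the documented tie-break
# (smallest |s|, then positive).
oracle_best_shift <- function(current, previous, max_shift) {
  n <- length(current)
  shifts <- -max_shift:max_shift
  agree <- vapply(shifts, function(s) {
    i <- if (s >= 0) (1 + s):n else 1:(n + s)
    mean(current[i] == previous[i - s])
  }, numeric(1))
  best <- max(agree)
  cand <- shifts[agree == best]
  cand <- cand[order(abs(cand), cand < 0)]
  list(shift = cand[1], agreement = best)
}

# Binary square wave of the given period (half black, half white).
square_wave <- function(n, period) {
  as.integer((seq_len(n) - 1) %% period < period / 2)
}

# Default-style configuration scaled for short desk tests.
test_arena <- function(...) arena_config(...)
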