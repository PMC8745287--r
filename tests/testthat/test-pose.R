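test_that("grayscale conversion uses the standard luminance weights", {
  white <- array(255, dim = c(2, 2, 3))
  expect_equal(to_grayscale(white), matrix(255, 2, 2))
  red <- array(rep(c(255, 0, 0), each = 4), dim = c(2, 2, 3))
  expect_equal(to_grayscale(red), matrix(76, 2, 2))   # round(0.299 * 255)
  g <- matrix(runif(12, 0, 255), 3, 4)
  expect_identical(to_grayscale(g), g)                # grayscale passes through
  expect_error(to_grayscale(array(0, dim = c(2, 2, 4))), "channel count")
})

test_that("circular mask keeps the closed disc and fills the outside", {
  geo <- tiny_geometry(size = 101, mask_radius = 20)
  f <- matrix(0, 101, 101)
  masked <- apply_circular_mask(f, geo, fill = 255)
  # boundary pixel at distance exactly r is kept (closed disc)
  expect_equal(masked[51, 71], 0)   # (x, y) = (71, 51), distance 20
  expect_equal(masked[51, 72], 255) # distance 21: filled
  expect_equal(masked[51, 51], 0)   # center untouched

  # unmasked pixel count close to the disc area; oracle: brute-force scan
  r <- 20
  inside <- sum(masked == 0)
  g <- expand.grid(x = 1:101, y = 1:101)
  brute <- sum((g$x - 51)^2 + (g$y - 51)^2 <= r^2)
  expect_equal(inside, brute)
  expect_lt(abs(inside - pi * r^2), 4 * r)

  # circle exceeding the frame: error in strict mode, warning in lenient
  big <- arena_geometry(width = 101, height = 101, center = c(51, 51),
                        mask_radius = 60,
                        stripe_roi = list(rows = c(1L, 2L), cols = c(1L, 5L)))
  expect_error(apply_circular_mask(f, big), "exceeds")
  expect_warning(apply_circular_mask(f, big, strict = FALSE), "clipping")
})

test_that("segmentation marks pixels strictly darker than the threshold", {
  f <- matrix(230, 50, 50)
  f[20:25, 30:35] <- 20
  m <- segment_mouse(f, 128)
  expect_equal(sum(m), 36)
  expect_true(all(m[20:25, 30:35] == 1L))
  expect_equal(sum(segment_mouse(matrix(200, 10, 10), 128)), 0)
  expect_equal(segment_mouse(matrix(128, 1, 1), 128)[1, 1], 0L)  # at threshold: background
})

test_that("position angle follows the clockwise-from-vertical convention", {
  geo <- tiny_geometry()
  cx <- geo$center[1]; cy <- geo$center[2]
  expect_equal(position_angle(disc_mask(cx, cy - 25, 5), geo), 0)
  expect_equal(position_angle(disc_mask(cx + 25, cy, 5), geo), 90)
  expect_equal(position_angle(disc_mask(cx, cy + 25, 5), geo), 180)
  expect_equal(position_angle(disc_mask(cx - 25, cy, 5), geo), 270)

  # atan2 oracle on random blob placements
  set.seed(11)
  for (k in 1:20) {
    th <- runif(1, 0, 2 * pi); r <- runif(1, 10, 30)
    bx <- round(cx + r * sin(th)); by <- round(cy - r * cos(th))
    m <- disc_mask(bx, by, 4)
    xy <- which(m != 0, arr.ind = TRUE)
    expected <- (atan2(mean(xy[, 2]) - cx, -(mean(xy[, 1]) - cy)) * 180 / pi) %% 360
    expect_equal(position_angle(m, geo), expected)
  }

  # degenerate cases are missing, not zero
  expect_true(is.na(position_angle(matrix(0L, 101, 101), geo)))
  expect_true(is.na(position_angle(disc_mask(cx, cy, 5), geo)))   # centroid at center
  expect_true(is.na(position_angle(disc_mask(cx + 25, cy, 5), geo,
                                   min_foreground = 1e4)))
})

test_that("orientation angle is the principal axis, vertical = 0", {
  bar_h <- mask_from_points(cbind(30:50, rep(51, 21)))   # 1 x 21 horizontal
  expect_equal(orientation_angle(bar_h), 90)
  bar_v <- mask_from_points(cbind(rep(51, 21), 30:50))   # 21 x 1 vertical
  expect_equal(orientation_angle(bar_v), 0)
  diag_up <- mask_from_points(cbind(30:50, 71 - (30:50))) # up-right diagonal
  expect_equal(orientation_angle(diag_up), 45)
  expect_equal(oracle_orientation(diag_up), 45, tolerance = 0.11)

  # axial invariance to head/tail swap: symmetric extension about the centroid
  ext <- mask_from_points(rbind(cbind(30:50, rep(51, 21)),
                                cbind(c(28, 52), c(51, 51))))
  expect_equal(orientation_angle(ext), 90)

  # isotropic blob has no axis
  expect_true(is.na(orientation_angle(disc_mask(51, 51, 8))))
  expect_true(is.na(orientation_angle(mask_from_points(cbind(51, 51)))))
})

test_that("orientation agrees with the brute-force orthogonal-distance fit", {
  set.seed(23)
  for (k in 1:40) {
    n <- sample(3:30, 1)
    xy <- unique(cbind(sample(20:80, n, replace = TRUE),
                       sample(20:80, n, replace = TRUE)))
    m <- mask_from_points(xy)
    got <- orientation_angle(m, iso_tol = 0)
    if (is.na(got)) next   # degenerate cloud: axis undefined
    orc <- oracle_orientation(m)
    d <- abs(angular_difference(got, orc, 180))
    expect_lte(d, 0.2)
  }
})

test_that("pose angles are rotation-equivariant and mirror-symmetric", {
  geo <- tiny_geometry()
  cx <- geo$center[1]; cy <- geo$center[2]
  # anisotropic blob of >= 100 px, tangential orientation
  base <- mask_from_points(as.matrix(expand.grid(x = (cx + 10):(cx + 29),
                                                 y = (cy - 3):(cy + 3))))
  expect_gte(sum(base), 100)
  p0 <- position_angle(base, geo)
  o0 <- orientation_angle(base)

  for (phi in c(17, 60, 121, 203, 311)) {
    rot <- rotate_mask(base, geo, phi)
    expect_lte(abs(angular_difference(position_angle(rot, geo), (p0 + phi) %% 360)),
               1.5)
    expect_lte(abs(angular_difference(orientation_angle(rot), (o0 + phi) %% 180, 180)),
               1.5)
  }

  # mirror about the vertical axis through the center
  mir <- base[, ncol(base):1]
  expect_lte(abs(angular_difference(position_angle(mir, geo), (360 - p0) %% 360)),
             1e-6)
  expect_lte(abs(angular_difference(orientation_angle(mir), (180 - o0) %% 180, 180)),
             1e-6)
})

test_that("frame tracking drives the pose chain and flags invalid frames", {
  geo <- tiny_geometry()
  cx <- geo$center[1]; cy <- geo$center[2]
  bright <- matrix(230, 101, 101)
  blob <- bright
  blob[(cy - 2):(cy + 2), (cx + 20):(cx + 32)] <- 20   # dark bar to the right

  poses <- track_frames(replicate(10, blob, simplify = FALSE), geo,
                        min_foreground = 20)
  expect_equal(nrow(poses), 10)
  expect_true(all(poses$valid))
  expect_true(all(abs(poses$position_angle_deg - 90) < 1))
  expect_true(all(poses$orientation_angle_deg == 90))
  expect_equal(poses$time_s, (0:9) / 30)

  empty <- track_frames(replicate(5, bright, simplify = FALSE), geo)
  expect_true(all(!empty$valid))
  expect_true(all(is.na(empty$position_angle_deg)))
  expect_true(all(is.na(empty$orientation_angle_deg)))
  expect_true(all(empty$foreground_px == 0))
})

test_that("largest-component cleanup drops satellite noise when enabled", {
  geo <- tiny_geometry()
  f <- matrix(230, 101, 101)
  f[48:54, 65:85] <- 20       # mouse bar
  f[20, 40] <- 20             # one dark noise pixel
  src <- list(f)
  with_noise <- track_frames(src, geo, min_foreground = 20)
  cleaned <- track_frames(src, geo, min_foreground = 20,
                          use_largest_component = TRUE)
  expect_equal(cleaned$foreground_px, 7 * 21)
  expect_equal(with_noise$foreground_px, 7 * 21 + 1)
  expect_equal(cleaned$orientation_angle_deg, 90)
})
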