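test_that("angular difference returns the minimal signed displacement", {
  expect_equal(angular_difference(350, 10), 20)
  expect_equal(angular_difference(10, 350), -20)
  expect_equal(angular_difference(175, 5, 180), 10)
  expect_equal(angular_difference(0, 180), 180)     # half turn: +period/2
  expect_error(angular_difference(0, 10, period = -1), "positive")

  # brute-force oracle: the unique d in (-p/2, p/2] with (a + d) mod p = b
  set.seed(3)
  for (k in 1:50) {
    p <- sample(c(180, 360), 1)
    a <- runif(1, 0, p); b <- runif(1, 0, p)
    cand <- seq(-p / 2 + 1e-9, p / 2, by = 1e-4)
    hit <- cand[abs((a + cand) %% p - b) < 5e-5]
    expect_equal(angular_difference(a, b, p), hit[1], tolerance = 1e-3)
  }
})

make_poses <- function(pos, ori = (pos + 90) %% 180, valid = NULL) {
  n <- length(pos)
  if (is.null(valid)) valid <- !is.na(pos)
  data.frame(frame = seq_len(n) - 1L, time_s = (seq_len(n) - 1L) / 30,
             position_angle_deg = pos, orientation_angle_deg = ori %% 180,
             foreground_px = rep(500L, n), valid = valid)
}

test_that("velocities are forward differences scaled by the frame rate", {
  # 1 degree per frame at 30 fps -> +30 deg/s at every interior frame
  k <- velocities(make_poses((0:29) %% 360), 30)
  expect_equal(k$position_velocity_degps[1:29], rep(30, 29))
  expect_equal(k$orientation_velocity_degps[1:29], rep(30, 29))
  expect_true(is.na(k$position_velocity_degps[30]))   # last frame: no difference

  # constant angles -> zero velocity
  k0 <- velocities(make_poses(rep(42, 10)), 30)
  expect_equal(k0$position_velocity_degps[1:9], rep(0, 9))

  # wrap across 0/360 does not produce a spike
  kw <- velocities(make_poses(c(358, 359, 0, 1, 2)), 30)
  expect_equal(kw$position_velocity_degps[1:4], rep(30, 4))

  # a gap at frame k kills the two touching differences
  pos <- (0:9) * 2; pos[5] <- NA
  kg <- velocities(make_poses(pos, valid = !is.na(pos)), 30)
  expect_true(all(is.na(kg$position_velocity_degps[4:5])))
  expect_false(anyNA(kg$position_velocity_degps[c(1:3, 6:9)]))
})

stim_table <- function(dirs) {
  n <- length(dirs)
  data.frame(frame = seq_len(n) - 1L, time_s = (seq_len(n) - 1L) / 30,
             direction = dirs, phase_shift_px = ifelse(dirs == "UNKNOWN", 0, 6),
             confidence = 1)
}

test_that("direction matching gates on sign, dead band and known stimulus", {
  pos <- c(0, 40 / 30, 80 / 30, 80 / 30 - 40 / 30 / 2, NA, 10) %% 360
  poses <- make_poses(pos, valid = !is.na(pos))
  k <- velocities(poses, 30)
  # frames: +40, +40, -20, ..., NA, gap
  st <- stim_table(c("CW", "CCW", "CW", "CW", "CW", "CW"))
  m <- direction_match(k, st, dead_band = 2)
  expect_true(m$position_matched[1])        # +40 vs CW
  expect_false(m$position_matched[2])       # +40 vs CCW
  expect_false(m$position_matched[3])       # -20 vs CW
  expect_false(any(m$position_matched[4:6])) # NA velocity / gap / last frame

  # below the dead band the frame never matches and the metric is unchanged
  slow <- make_poses(cumsum(c(0, rep(0.5 / 30, 9))))  # 0.5 deg/s crawl
  ks <- velocities(slow, 30)
  ms <- direction_match(ks, stim_table(rep("CW", 10)), dead_band = 2)
  expect_false(any(ms$position_matched))
  fast <- velocities(make_poses(cumsum(c(0, rep(40 / 30, 9)))), 30)
  base <- summarize_trial(direction_match(fast, stim_table(rep("CW", 10))))
  joined <- rbind(direction_match(fast, stim_table(rep("CW", 10))),
                  ms)
  expect_equal(summarize_trial(joined)$angular_running_speed,
               base$angular_running_speed)

  expect_error(direction_match(k, stim_table(rep("CW", 3))), "frame-aligned")
})

test_that("trial summary averages absolute velocity over matched frames only", {
  # rigid co-rotation at 50 deg/s
  n <- 60
  pos <- (seq_len(n) - 1) * 50 / 30
  k <- velocities(make_poses(pos %% 360), 30)
  m <- direction_match(k, stim_table(rep("CW", n)))
  tr <- summarize_trial(m)
  expect_s3_class(tr, "optomotor_trial")
  expect_equal(tr$angular_running_speed, 50, tolerance = 1e-9)
  expect_equal(tr$angular_orientation_speed, 50, tolerance = 1e-9)
  expect_equal(unname(tr$matched_frame_counts["position"]), n - 1L)

  # stationary mouse: empty matched set -> missing, never zero
  st <- summarize_trial(direction_match(velocities(make_poses(rep(5, n)), 30),
                                        stim_table(rep("CW", n))))
  expect_true(is.na(st$angular_running_speed))
  expect_true(is.na(st$angular_orientation_speed))
  expect_equal(unname(st$matched_frame_counts["position"]), 0L)

  # counter-rotating mouse: no matched frames either
  ctr <- summarize_trial(direction_match(velocities(make_poses((-pos) %% 360), 30),
                                         stim_table(rep("CW", n))))
  expect_true(is.na(ctr$angular_running_speed))

  # QC counters
  expect_equal(tr$qc$frames_total, n)
  expect_equal(tr$qc$frames_valid, n)
  expect_equal(tr$qc$frames_unknown_stimulus, 0)
})

test_that("metrics are invariant to a global CW/CCW relabeling", {
  n <- 40
  pos <- (seq_len(n) - 1) * 35 / 30
  k_cw <- velocities(make_poses(pos %% 360), 30)
  m_cw <- direction_match(k_cw, stim_table(rep("CW", n)))
  # mirror world: negated angles, CCW stimulus
  k_ccw <- velocities(make_poses((-pos) %% 360), 30)
  m_ccw <- direction_match(k_ccw, stim_table(rep("CCW", n)))
  expect_equal(summarize_trial(m_cw)$angular_running_speed,
               summarize_trial(m_ccw)$angular_running_speed)
  expect_equal(summarize_trial(m_cw)$angular_orientation_speed,
               summarize_trial(m_ccw)$angular_orientation_speed)
})

test_that("removing non-matched frames does not change the metrics", {
  set.seed(9)
  n <- 120
  pos <- cumsum(c(0, rnorm(n - 1, 50 / 30, 1)))
  dirs <- rep(c("CW", "CCW", "UNKNOWN"), length.out = n)
  m <- direction_match(velocities(make_poses(pos %% 360), 30), stim_table(dirs))
  tr_all <- summarize_trial(m)
  kept <- m[m$position_matched | m$orientation_matched, ]
  tr_kept <- summarize_trial(kept)
  expect_equal(tr_all$angular_running_speed, tr_kept$angular_running_speed)
  expect_equal(tr_all$angular_orientation_speed, tr_kept$angular_orientation_speed)
})

test_that("metrics are stable between 30 and 60 fps sampling", {
  # same continuous trajectory sampled at two rates
  traj <- function(t) 50 * t          # deg, rigid following
  for (fr in c(30, 60)) {
    t <- seq(0, 10 - 1 / fr, by = 1 / fr)
    k <- velocities(make_poses(traj(t) %% 360), fr)
    m <- direction_match(k, stim_table(rep("CW", length(t))))
    assign(paste0("v", fr), summarize_trial(m)$angular_running_speed)
  }
  expect_lt(abs(v30 - v60) / v60, 0.02)
})

test_that("trial methods print, summarize, convert and plot", {
  n <- 30
  pos <- (seq_len(n) - 1) * 50 / 30
  tr <- summarize_trial(direction_match(velocities(make_poses(pos %% 360), 30),
                                        stim_table(rep("CW", n))))
  expect_output(print(tr), "angular running speed")
  s <- summary(tr)
  expect_s3_class(s, "summary.optomotor_trial")
  expect_output(print(s), "matched frames")
  expect_equal(nrow(as.data.frame(tr)), n)
  pdf(NULL)
  expect_invisible(plot(tr))
  dev.off()
})
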