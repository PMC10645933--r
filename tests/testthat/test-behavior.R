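# Object at (10, 0) with default footprint; cases place the nose at known
# distances/orientations relative to the object center.
nort_arena_at_10 <- function() {
  arena_nort(object_centers = rbind(old = c(-10, 0), novel = c(10, 0)))
}

test_that("exploration requires the nose within 5 cm AND facing the object", {
  a <- nort_arena_at_10()
  # nose 4 cm from center, heading straight at the object -> exploring
  tr <- make_traj_kp(nose = c(6, 0), head = c(5, 0))
  expect_true(detect_exploration(tr, a)[1, "novel"])
  # nose 6 cm from center, heading straight at it -> too far
  tr <- make_traj_kp(nose = c(4, 0), head = c(3, 0))
  expect_false(detect_exploration(tr, a)[1, "novel"])
  # nose 4 cm but heading 180 degrees away -> not exploring
  tr <- make_traj_kp(nose = c(6, 0), head = c(7, 0))
  expect_false(detect_exploration(tr, a)[1, "novel"])
  # facing cone boundary: at 46 degrees off-axis a 45-degree cone excludes
  th <- 46 * pi / 180
  head_pos <- c(6, 0)
  nose_pos <- head_pos + c(cos(pi - th), sin(pi - th)) * -1 # 1 cm ahead, rotated
  tr <- make_traj_kp(nose = rbind(nose_pos), head = rbind(head_pos))
  expect_false(detect_exploration(tr, a, facing_max_deg = 45)[1, "novel"])
  expect_true(detect_exploration(tr, a, facing_max_deg = 60)[1, "novel"])
})

test_that("discrimination index follows its printed formula and bounds", {
  expect_equal(discrimination_index(30, 30), 0)
  expect_equal(discrimination_index(45, 15), 0.5)
  expect_equal(discrimination_index(0, 20), -1)
  expect_equal(discrimination_index(20, 0), 1)
  di <- discrimination_index(0, 0)
  expect_true(is.na(di))
  expect_true(attr(di, "undefined"))
  # random times always land in [-1, 1]
  set.seed(1)
  for (i in 1:50) {
    di <- discrimination_index(runif(1, 0, 100), runif(1, 0, 100))
    expect_true(di >= -1 && di <= 1)
  }
})

test_that("arm entries need penetration beyond the depth threshold", {
  a <- arena_ymaze() # arms at 90, 210, 330 degrees, length 35
  u <- rbind(c(0, 1), c(cos(210 * pi / 180), sin(210 * pi / 180)))
  # visit arm A (90 deg) to 60% depth, back to center, then arm B to 60%
  body <- rbind(c(0, 0), t(u[1, ] * 21), c(0, 0), t(u[2, ] * 21), c(0, 0))
  tr <- make_traj(body, rep(0, nrow(body)))
  expect_equal(as.character(detect_arm_entries(tr, a)), c("A", "B"))
  # oscillation across the arm mouth below 50% depth: no entry
  body <- rbind(c(0, 0), c(0, 10), c(0, 2), c(0, 12), c(0, 1))
  tr <- make_traj(body, rep(0, 5))
  expect_length(detect_arm_entries(tr, a), 0)
  # dithering around the threshold within one visit yields one entry
  body <- rbind(c(0, 0), c(0, 18), c(0, 16), c(0, 19), c(0, 0))
  tr <- make_traj(body, rep(0, 5))
  expect_equal(as.character(detect_arm_entries(tr, a)), "A")
})

test_that("spontaneous alternation scores distinct triplets over entries minus two", {
  expect_equal(spontaneous_alternation(strsplit("ABCABC", "")[[1]]), 1)
  expect_equal(spontaneous_alternation(strsplit("ABABAB", "")[[1]]), 0)
  expect_equal(spontaneous_alternation(c("A", "B", "C", "B", "A")), 2 / 3)
  expect_equal(spontaneous_alternation(c("A", "B", "C"), as_percent = TRUE), 100)
  out <- spontaneous_alternation(c("A", "B"))
  expect_true(is.na(out) && attr(out, "undefined"))
})

test_that("detected arm sequences equal the generator's latent sequences", {
  a <- arena_ymaze()
  for (seed in 1:25) {
    s <- simulate_trajectory(behavior_sim_params(
      "ymaze", duration_s = 180, frame_rate_hz = 10,
      alternation_bias = runif(1), seed = seed), a)
    expect_identical(as.character(detect_arm_entries(s$trajectory, a)),
                     s$ground_truth$arm_seq, label = paste("seed", seed))
  }
})

test_that("water-maze training metrics follow their definitions", {
  a <- arena_mwm() # platform at (0, 30), radius 5
  # stationary mouse: zero path, latency = timeout
  body <- matrix(rep(c(10, -10), each = 50), ncol = 2)
  m <- mwm_trial_metrics(make_traj(body, rep(0, 50)), a)
  expect_equal(m$path_length_cm, 0)
  expect_equal(m$escape_latency_s, 120)
  expect_false(m$escaped)
  # straight 80 cm swim at 16 cm/s onto the platform: latency 5 s, path 80
  fr <- 10
  y <- seq(-55, by = 16 / fr, length.out = 51) # reaches y = 25 at frame 51
  body <- cbind(0, y)
  m <- mwm_trial_metrics(make_traj(body, rep(pi / 2, length(y)), frame_rate = fr), a)
  expect_true(m$escaped)
  expect_equal(m$escape_latency_s, 5)
  expect_equal(m$path_length_cm, 80)
  expect_equal(m$mean_speed_cm_s, 16)
  # out-of-pool trajectory trips the calibration check
  body_bad <- matrix(rep(c(70, 0), each = 10), ncol = 2)
  expect_error(mwm_trial_metrics(make_traj(body_bad, rep(0, 10)), a), "calibration")
})

test_that("probe metrics partition time into quadrants and average distance", {
  a <- arena_mwm()
  # parked on the former platform center
  body <- matrix(rep(a$platform_center, each = 60), ncol = 2)
  m <- mwm_probe_metrics(make_traj(body, rep(0, 60)), a)
  expect_equal(m$mean_distance_to_platform_cm, 0)
  # parked 30 cm east of the platform: distance 30, all time in that quadrant
  pt <- a$platform_center + c(30, -30) # (30, 0): E quadrant
  body <- matrix(rep(pt, each = 60), ncol = 2)
  m <- mwm_probe_metrics(make_traj(body, rep(0, 60)), a)
  expect_equal(m$mean_distance_to_platform_cm, sqrt(sum((pt - a$platform_center)^2)))
  expect_equal(unname(m$quadrant_time_s["E"]), sum(m$quadrant_time_s))
  # partition property on arbitrary simulated trials
  for (seed in 1:5) {
    s <- simulate_trajectory(behavior_sim_params(
      "mwm_probe", frame_rate_hz = 10, goal_bias = runif(1), seed = seed), a)
    m <- mwm_probe_metrics(s$trajectory, a)
    dur <- diff(range(s$trajectory$time_s))
    expect_lt(abs(sum(m$quadrant_time_s) - dur), 2 * 0.1 + 1e-9)
  }
})

test_that("metrics are invariant under rigid rotation of trajectory and arena", {
  rot <- function(xy, th) xy %*% rbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  th <- 37 * pi / 180
  # NORT
  a <- arena_nort()
  s <- simulate_trajectory(behavior_sim_params(
    "nort", duration_s = 120, frame_rate_hz = 10, novelty_preference = 0.8,
    seed = 31), a)
  tr <- s$trajectory
  tr_rot <- trajectory(tr$time_s,
                       nose = rot(cbind(tr$nose_x, tr$nose_y), th),
                       head = rot(cbind(tr$head_x, tr$head_y), th),
                       body = rot(cbind(tr$body_x, tr$body_y), th))
  a_rot <- arena_nort(object_centers = rot(a$object_centers, th))
  expect_equal(unname(exploration_times(tr_rot, a_rot)),
               unname(exploration_times(tr, a)), tolerance = 1e-10)
  # MWM probe (rotation by a multiple of 90 deg keeps quadrant labels aligned)
  am <- arena_mwm()
  sp <- simulate_trajectory(behavior_sim_params(
    "mwm_probe", frame_rate_hz = 10, seed = 31), am)
  tr <- sp$trajectory
  th2 <- pi / 2
  tr_rot <- trajectory(tr$time_s,
                       nose = rot(cbind(tr$nose_x, tr$nose_y), th2),
                       head = rot(cbind(tr$head_x, tr$head_y), th2),
                       body = rot(cbind(tr$body_x, tr$body_y), th2))
  am_rot <- arena_mwm(platform_center = as.numeric(rot(rbind(am$platform_center), th2)))
  m1 <- mwm_probe_metrics(tr, am)
  m2 <- mwm_probe_metrics(tr_rot, am_rot)
  expect_equal(m2$mean_distance_to_platform_cm, m1$mean_distance_to_platform_cm,
               tolerance = 1e-10)
  expect_equal(unname(m2$quadrant_time_s[m2$target_quadrant]),
               unname(m1$quadrant_time_s[m1$target_quadrant]), tolerance = 1e-10)
})

test_that("short tracking gaps are interpolated, long ones excluded", {
  body <- cbind(seq(0, 10, length.out = 21), 0)
  tr <- make_traj(body, rep(0, 21), frame_rate = 10)
  # 3-frame dropout (0.3 s): interpolated
  tr$nose_likelihood[5:7] <- 0.2
  filled <- fill_gaps(tr)
  expect_false(any(is.na(filled$nose_x)))
  expect_equal(filled$nose_x[6], tr$nose_x[6], tolerance = 1e-9) # linear path
  expect_false(any(attr(filled, "excluded")))
  # 10-frame dropout (1 s): left NA and flagged
  tr2 <- make_traj(body, rep(0, 21), frame_rate = 10)
  tr2$body_likelihood[5:14] <- 0.1
  filled2 <- fill_gaps(tr2)
  expect_true(all(is.na(filled2$body_x[5:14])))
  expect_true(all(attr(filled2, "excluded")[5:14]))
})

test_that("programmed alternation bias maps monotonically to the measured ratio", {
  a <- arena_ymaze()
  mean_ratio <- function(b) {
    mean(vapply(1:30, function(sd) {
      s <- simulate_trajectory(behavior_sim_params(
        "ymaze", duration_s = 240, frame_rate_hz = 10,
        alternation_bias = b, seed = 1000L * b + sd), a)
      spontaneous_alternation(detect_arm_entries(s$trajectory, a))
    }, numeric(1)), na.rm = TRUE)
  }
  ratios <- vapply(c(0, 0.5, 1), mean_ratio, numeric(1))
  expect_true(all(diff(ratios) > 0))
  expect_equal(ratios[3], 1)
  # with no bias the mouse picks uniformly between the two other arms: 1/2
  expect_equal(ratios[1], 0.5, tolerance = 0.07)
})
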