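#' Parameters for the behavioral trajectory simulator
#'
#' Bundles the tunable knobs of the synthetic trajectory generator. The
#' defaults mirror the trial structure of the study being emulated: 10-min
#' object-exploration and Y-maze sessions, 120-s water-maze training trials
#' with escape on reaching the platform, and a 60-s probe trial.
#'
#' @param test_kind one of `"nort"`, `"ymaze"`, `"mwm_training"`,
#'   `"mwm_probe"`.
#' @param duration_s trial duration (s); defaults per `test_kind` (600, 600,
#'   120, 60).
#' @param frame_rate_hz tracking frame rate (frames/s).
#' @param novelty_preference probability that an object-exploration bout
#'   targets the novel object (NORT).
#' @param alternation_bias probability that the next arm entered is the least
#'   recently visited of the two available arms (Y maze); `0` picks uniformly
#'   between them, `1` alternates perfectly.
#' @param goal_bias weight in \[0, 1\] of steering toward the platform versus
#'   heading persistence (water maze).
#' @param speed_mean mean locomotion speed (cm/s); defaults to 8 cm/s walking,
#'   15 cm/s swimming.
#' @param heading_noise s.d. of per-frame heading perturbations (radians).
#' @param seed integer seed; the generator is a pure function of
#'   (params, arena) under a fixed seed.
#' @return a list of class `behavior_sim_params`.
#' @export
behavior_sim_params <- function(test_kind = c("nort", "ymaze", "mwm_training", "mwm_probe"),
                                duration_s = NULL,
                                frame_rate_hz = 30,
                                novelty_preference = 0.5,
                                alternation_bias = 0.5,
                                goal_bias = 0.5,
                                speed_mean = NULL,
                                heading_noise = 0.3,
                                seed = NULL) {
  test_kind <- match.arg(test_kind)
  if (is.null(duration_s)) {
    duration_s <- switch(test_kind, nort = 600, ymaze = 600,
                         mwm_training = 120, mwm_probe = 60)
  }
  if (is.null(speed_mean)) {
    speed_mean <- if (test_kind %in% c("nort", "ymaze")) 8 else 15
  }
  check_pos(duration_s, "duration_s")
  check_pos(frame_rate_hz, "frame_rate_hz")
  check_pos(speed_mean, "speed_mean")
  check_prob(novelty_preference, "novelty_preference")
  check_prob(alternation_bias, "alternation_bias")
  check_prob(goal_bias, "goal_bias")
  if (!is.numeric(heading_noise) || heading_noise < 0 || !is.finite(heading_noise)) {
    stopf("`heading_noise` must be a non-negative finite number")
  }
  structure(list(
    test_kind = test_kind, duration_s = duration_s,
    frame_rate_hz = frame_rate_hz,
    novelty_preference = novelty_preference,
    alternation_bias = alternation_bias, goal_bias = goal_bias,
    speed_mean = speed_mean, heading_noise = heading_noise, seed = seed
  ), class = "behavior_sim_params")
}

# body->head and head->nose distances (cm) used for keypoint placement
.KP_BODY_HEAD <- 1.5
.KP_HEAD_NOSE <- 1.0

# Assemble a trajectory from per-frame body positions and headings (radians).
traj_from_body <- function(time_s, body, heading) {
  u <- cbind(cos(heading), sin(heading))
  head <- body + .KP_BODY_HEAD * u
  nose <- head + .KP_HEAD_NOSE * u
  trajectory(time_s, nose = nose, head = head, body = body)
}

# Heading from velocity; frames with negligible motion inherit the previous
# heading, the first frame inherits forward.
heading_from_velocity <- function(body, min_step = 1e-6) {
  n <- nrow(body)
  v <- diff(body)
  ang <- atan2(v[, 2], v[, 1])
  ang[sqrt(rowSums(v^2)) < min_step] <- NA
  ang <- c(ang, NA)
  # forward then backward fill
  for (i in seq_len(n)[-1]) if (is.na(ang[i])) ang[i] <- ang[i - 1]
  for (i in rev(seq_len(n - 1))) if (is.na(ang[i])) ang[i] <- ang[i + 1]
  ang[is.na(ang)] <- 0
  ang
}

# Smooth AR(1) positional jitter, clipped to +/- 3 sd of the stationary law.
ou_jitter <- function(n, sd_cm, rho = 0.9) {
  if (sd_cm <= 0 || n == 0L) return(numeric(n))
  innov_sd <- sd_cm * sqrt(1 - rho^2)
  z <- numeric(n)
  z[1] <- rnorm(1, 0, sd_cm)
  e <- rnorm(n, 0, innov_sd)
  for (i in seq_len(n)[-1]) z[i] <- rho * z[i - 1] + e[i]
  pmin(pmax(z, -3 * sd_cm), 3 * sd_cm)
}

# Piecewise-linear body path through waypoints at constant speed with dwell
# stops. Returns body matrix plus the frame index at which each waypoint is
# reached. Truncated/padded to n_frames.
path_through_waypoints <- function(waypoints, dwell_s, speed, frame_rate, n_frames) {
  pos <- list()
  arrive <- rep(NA_integer_, nrow(waypoints))
  cur <- waypoints[1, ]
  frames_used <- 0L
  for (i in seq_len(nrow(waypoints))) {
    if (i > 1L) {
      d <- sqrt(sum((waypoints[i, ] - cur)^2))
      nseg <- max(1L, round(d / speed * frame_rate))
      seg <- cbind(seq(cur[1], waypoints[i, 1], length.out = nseg + 1L),
                   seq(cur[2], waypoints[i, 2], length.out = nseg + 1L))[-1L, , drop = FALSE]
      pos[[length(pos) + 1L]] <- seg
      frames_used <- frames_used + nseg
      cur <- waypoints[i, ]
    } else {
      pos[[1L]] <- matrix(cur, 1L)
      frames_used <- 1L
    }
    arrive[i] <- frames_used
    ndw <- round(dwell_s[i] * frame_rate)
    if (ndw > 0L) {
      pos[[length(pos) + 1L]] <- matrix(rep(cur, each = ndw), ndw)
      frames_used <- frames_used + ndw
    }
    if (frames_used >= n_frames) break
  }
  body <- do.call(rbind, pos)
  if (nrow(body) < n_frames) {
    body <- rbind(body, matrix(rep(body[nrow(body), ], each = n_frames - nrow(body)),
                               n_frames - nrow(body)))
  }
  list(body = body[seq_len(n_frames), , drop = FALSE], arrive = arrive)
}

#' Simulate a tracked trajectory with known ground truth
#'
#' Discrete-time correlated-random-walk simulator for the four behavioral
#' paradigms. At each bout onset a target (object, arm, or the platform) is
#' drawn from the programmed preference; the body then moves toward it at
#' `speed_mean` with heading noise, and the nose/head-center/body-center
#' keypoints are placed along the heading at fixed anatomical offsets. The
#' latent targets (exploration bouts, arm-entry sequence, escape event) are
#' exported as ground truth so downstream metric extraction can be validated
#' against them.
#'
#' @param params a [behavior_sim_params()] whose `test_kind` matches the
#'   arena kind.
#' @param arena an [arena_spec][arena] (`arena_nort()`, `arena_ymaze()` or
#'   `arena_mwm()`).
#' @param start optional starting body position (cm); defaults per paradigm.
#' @return a list of class `behavior_sim` with elements `trajectory` (a
#'   [trajectory]) and `ground_truth` (a list; contents depend on the
#'   paradigm: exploration `bouts` for NORT, latent `arm_seq` and
#'   `entry_frames` for the Y maze, `escaped`/`escape_frame` for water-maze
#'   training).
#' @export
simulate_trajectory <- function(params, arena, start = NULL) {
  if (!inherits(params, "behavior_sim_params")) {
    stopf("`params` must be created by behavior_sim_params()")
  }
  needed <- switch(params$test_kind,
                   nort = "nort", ymaze = "ymaze",
                   mwm_training = "mwm", mwm_probe = "mwm")
  check_arena_kind(arena, needed)
  with_seed(params$seed, switch(params$test_kind,
    nort = sim_nort(params, arena),
    ymaze = sim_ymaze(params, arena),
    mwm_training = sim_mwm(params, arena, probe = FALSE, start = start),
    mwm_probe = sim_mwm(params, arena, probe = TRUE, start = start)
  ))
}

sim_nort <- function(params, arena) {
  fr <- params$frame_rate_hz
  n_frames <- round(params$duration_s * fr)
  half <- arena$side_cm / 2
  oc <- arena$object_centers
  novel <- arena$novel_object_id
  old <- setdiff(rownames(oc), novel)
  # body stands off so the nose sits 3.5 cm from the object center
  standoff <- 3.5 + .KP_BODY_HEAD + .KP_HEAD_NOSE

  waypoints <- matrix(c(0, -half * 0.6), 1L)
  dwell <- 0.5
  labels <- "start"
  est_t <- 0.5
  prev <- waypoints[1, ]
  while (est_t < params$duration_s * 1.2) {
    # wander targets stay clear of both objects so non-bout frames do not
    # contaminate the exploration times that identify novelty_preference
    repeat {
      wander <- runif(2, -half + 5, half - 5)
      d_obj <- sqrt(rowSums((oc - matrix(wander, nrow(oc), 2, byrow = TRUE))^2))
      if (all(d_obj >= 10)) break
    }
    obj <- if (runif(1) < params$novelty_preference) novel else old
    u <- (wander - oc[obj, ]) / sqrt(sum((wander - oc[obj, ])^2))
    stand <- oc[obj, ] + u * standoff
    dw_obj <- runif(1, 1.5, 2.5)
    waypoints <- rbind(waypoints, wander, stand)
    dwell <- c(dwell, 1.0, dw_obj)
    labels <- c(labels, "wander", obj)
    est_t <- est_t + (sqrt(sum((wander - prev)^2)) +
                      sqrt(sum((stand - wander)^2))) / params$speed_mean +
      1.0 + dw_obj
    prev <- stand
  }
  pw <- path_through_waypoints(waypoints, dwell, params$speed_mean, fr, n_frames)
  body <- pw$body
  body[, 1] <- body[, 1] + ou_jitter(n_frames, 0.3)
  body[, 2] <- body[, 2] + ou_jitter(n_frames, 0.3)
  margin <- half - .KP_BODY_HEAD - .KP_HEAD_NOSE - 0.1
  body <- pmin(pmax(body, -margin), margin)
  heading <- heading_from_velocity(body)

  # during object dwell, face the object (small residual wobble)
  bouts <- NULL
  dwell_frames <- round(dwell * fr)
  for (i in which(labels %in% rownames(oc))) {
    a <- pw$arrive[i]
    if (is.na(a) || a > n_frames) next
    idx <- a:min(a + dwell_frames[i], n_frames)
    to_obj <- atan2(oc[labels[i], 2] - body[idx, 2],
                    oc[labels[i], 1] - body[idx, 1])
    heading[idx] <- to_obj + rnorm(length(idx), 0, min(params$heading_noise, 0.12))
    bouts <- rbind(bouts, data.frame(
      object = labels[i],
      role = if (labels[i] == novel) "novel" else "old",
      onset_frame = idx[1], offset_frame = idx[length(idx)]
    ))
  }
  time_s <- (seq_len(n_frames) - 1L) / fr
  structure(list(
    trajectory = traj_from_body(time_s, body, heading),
    ground_truth = list(kind = "nort", bouts = bouts)
  ), class = "behavior_sim")
}

sim_ymaze <- function(params, arena) {
  fr <- params$frame_rate_hz
  n_frames <- round(params$duration_s * fr)
  L <- arena$arm_length_cm
  u <- arm_unit_vectors(arena)
  labels <- arena$arm_labels
  depth <- 0.8 * L
  cycle_s <- 2 * depth / params$speed_mean + 1.1

  # latent arm sequence (no consecutive repeats: the mouse returns to the
  # center between entries and never re-enters the arm it just left)
  n_entries <- max(3L, ceiling(params$duration_s / cycle_s) + 2L)
  last_visit <- setNames(rep(-Inf, 3), labels)
  seq_arms <- character(n_entries)
  seq_arms[1] <- sample(labels, 1)
  last_visit[seq_arms[1]] <- 1
  for (k in 2:n_entries) {
    others <- setdiff(labels, seq_arms[k - 1])
    if (runif(1) < params$alternation_bias) {
      lv <- last_visit[others]
      cand <- others[lv == min(lv)]
      seq_arms[k] <- if (length(cand) > 1L) sample(cand, 1) else cand
    } else {
      seq_arms[k] <- sample(others, 1)
    }
    last_visit[seq_arms[k]] <- k
  }

  # assemble waypoints only for entries that complete inside the trial, so
  # the latent sequence is exactly what the trajectory realizes; leftover
  # frames are spent loitering at the final position
  nseg <- max(1L, round(depth / params$speed_mean * fr))
  dwell_arm_f <- round(0.8 * fr)
  dwell_ctr_f <- round(0.3 * fr)
  wp <- list()
  dwell <- numeric(0)
  n_done <- 0L
  frames_used <- 0L
  for (k in seq_len(n_entries)) {
    i <- match(seq_arms[k], labels)
    cost_in <- if (k == 1L) 1L else nseg       # first waypoint is the start
    if (frames_used + cost_in + dwell_arm_f + 5L > n_frames) break
    wp[[length(wp) + 1L]] <- u[i, ] * depth
    dwell <- c(dwell, 0.8)
    frames_used <- frames_used + cost_in + dwell_arm_f
    n_done <- k
    if (frames_used + nseg + dwell_ctr_f >= n_frames) break
    wp[[length(wp) + 1L]] <- c(0, 0)
    dwell <- c(dwell, 0.3)
    frames_used <- frames_used + nseg + dwell_ctr_f
  }
  seq_arms <- seq_arms[seq_len(n_done)]
  pw <- path_through_waypoints(do.call(rbind, wp), dwell, params$speed_mean,
                               fr, n_frames)
  body <- pw$body
  body[, 1] <- body[, 1] + ou_jitter(n_frames, 0.3)
  body[, 2] <- body[, 2] + ou_jitter(n_frames, 0.3)
  heading <- heading_from_velocity(body)
  arm_wp <- which(vapply(wp, function(w) any(w != 0), logical(1)))
  entry_frames <- pw$arrive[arm_wp]
  time_s <- (seq_len(n_frames) - 1L) / fr
  structure(list(
    trajectory = traj_from_body(time_s, body, heading),
    ground_truth = list(kind = "ymaze",
                        arm_seq = seq_arms,
                        entry_frames = entry_frames)
  ), class = "behavior_sim")
}

sim_mwm <- function(params, arena, probe, start = NULL) {
  fr <- params$frame_rate_hz
  n_frames <- round(params$duration_s * fr)
  R <- arena$pool_radius_cm
  plat <- arena$platform_center
  if (is.null(start)) {
    th0 <- runif(1, 0, 2 * pi)
    start <- 0.92 * R * c(cos(th0), sin(th0))
  }
  body <- matrix(NA_real_, n_frames, 2)
  body[1, ] <- start
  heading <- numeric(n_frames)
  heading[1] <- atan2(-start[2], -start[1])
  step0 <- params$speed_mean / fr
  escaped <- FALSE
  escape_frame <- NA_integer_
  target <- plat
  wander_until <- 0L
  for (t in 2:n_frames) {
    p <- body[t - 1, ]
    if (probe && t > wander_until && sqrt(sum((p - target)^2)) < 8) {
      # searching: hover around the former platform location
      ang <- runif(1, 0, 2 * pi)
      rad <- runif(1, 5, 25)
      target <- plat + rad * c(cos(ang), sin(ang))
      wander_until <- t + round(2 * fr)
    }
    to_t <- target - p
    d_t <- sqrt(sum(to_t^2))
    u_goal <- if (d_t > 1e-9) to_t / d_t else c(cos(heading[t - 1]), sin(heading[t - 1]))
    u_prev <- c(cos(heading[t - 1]), sin(heading[t - 1]))
    v <- params$goal_bias * u_goal + (1 - params$goal_bias) * u_prev
    if (sqrt(sum(v^2)) < 1e-9) v <- u_prev
    ang <- atan2(v[2], v[1]) + rnorm(1, 0, params$heading_noise)
    stp <- step0 * runif(1, 0.9, 1.1)
    q <- p + stp * c(cos(ang), sin(ang))
    r <- sqrt(sum(q^2))
    rmax <- R - 2
    if (r > rmax) {
      q <- q * (rmax / r)
      ang <- atan2(-q[2], -q[1]) + rnorm(1, 0, 0.5)
    }
    body[t, ] <- q
    heading[t] <- ang
    if (!probe && sqrt(sum((q - plat)^2)) <= arena$platform_radius_cm) {
      escaped <- TRUE
      escape_frame <- t
      break
    }
  }
  n_use <- if (escaped) escape_frame else n_frames
  body <- body[seq_len(n_use), , drop = FALSE]
  heading <- heading[seq_len(n_use)]
  time_s <- (seq_len(n_use) - 1L) / fr
  structure(list(
    trajectory = traj_from_body(time_s, body, heading),
    ground_truth = list(kind = if (probe) "mwm_probe" else "mwm_training",
                        start = start, escaped = escaped,
                        escape_frame = escape_frame,
                        platform_center = plat)
  ), class = "behavior_sim")
}
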