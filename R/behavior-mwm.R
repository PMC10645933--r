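#' Morris water maze training-trial metrics
#'
#' Computes the training readouts from one swim: escape latency (first time
#' the body center is within the platform radius, or the timeout), path
#' length (sum of consecutive body-center displacements up to escape), and
#' mean swim speed (path length over swim time, post-escape frames excluded).
#'
#' @param traj a [trajectory].
#' @param arena an `arena_mwm()`.
#' @param timeout_s trial timeout (s); default 120.
#' @param boundary_tol_cm allowed excursion beyond the pool wall before a
#'   geometry-calibration error is raised (cm).
#' @return list of class `trial_metrics` with `escape_latency_s`,
#'   `path_length_cm`, `mean_speed_cm_s`, `escaped`.
#' @export
mwm_trial_metrics <- function(traj, arena, timeout_s = 120, boundary_tol_cm = 2) {
  check_arena_kind(arena, "mwm")
  check_pos(timeout_s, "timeout_s")
  body <- keypoint_xy(traj, "body")
  ok <- complete.cases(body)
  r <- sqrt(rowSums(body^2))
  if (any(r[ok] > arena$pool_radius_cm + boundary_tol_cm)) {
    stopf("trajectory leaves the pool by more than %.1f cm: check the pixel-to-cm calibration", boundary_tol_cm)
  }
  d_plat <- sqrt((body[, 1] - arena$platform_center[1])^2 +
                 (body[, 2] - arena$platform_center[2])^2)
  hit <- which(ok & d_plat <= arena$platform_radius_cm)
  if (length(hit) > 0L) {
    esc <- hit[1]
    escaped <- TRUE
    latency <- traj$time_s[esc] - traj$time_s[1]
  } else {
    esc <- nrow(body)
    escaped <- FALSE
    latency <- timeout_s
  }
  idx <- seq_len(esc)
  seg <- diff(body[idx, , drop = FALSE])
  step <- sqrt(rowSums(seg^2))
  path <- sum(step, na.rm = TRUE)
  swim_time <- traj$time_s[esc] - traj$time_s[1]
  structure(list(
    escape_latency_s = latency,
    path_length_cm = path,
    mean_speed_cm_s = if (swim_time > 0) path / swim_time else 0,
    escaped = escaped
  ), class = "trial_metrics")
}

#' Morris water maze probe-trial metrics
#'
#' With the platform removed, memory is read out as time spent in each pool
#' quadrant and the time-averaged distance of the body center to the former
#' platform location.
#'
#' @param traj a [trajectory].
#' @param arena an `arena_mwm()`; the platform fields give the reference
#'   point and target quadrant.
#' @param boundary_tol_cm as in [mwm_trial_metrics()].
#' @return list of class `trial_metrics` with `quadrant_time_s` (named N, E,
#'   S, W; sums to the trial duration within one frame period),
#'   `target_quadrant`, `mean_distance_to_platform_cm`, `path_length_cm`,
#'   `mean_speed_cm_s`.
#' @export
mwm_probe_metrics <- function(traj, arena, boundary_tol_cm = 2) {
  check_arena_kind(arena, "mwm")
  body <- keypoint_xy(traj, "body")
  ok <- complete.cases(body)
  r <- sqrt(rowSums(body^2))
  if (any(r[ok] > arena$pool_radius_cm + boundary_tol_cm)) {
    stopf("trajectory leaves the pool by more than %.1f cm: check the pixel-to-cm calibration", boundary_tol_cm)
  }
  dt <- diff(traj$time_s)
  dt <- c(dt, dt[length(dt)])
  quad <- rep(NA_character_, nrow(body))
  quad[ok] <- quadrant_of(body[ok, 1], body[ok, 2])
  qt <- vapply(c("N", "E", "S", "W"),
               function(q) sum(dt[!is.na(quad) & quad == q]), numeric(1))
  d_plat <- sqrt((body[, 1] - arena$platform_center[1])^2 +
                 (body[, 2] - arena$platform_center[2])^2)
  w <- dt[ok]
  mean_dist <- sum(d_plat[ok] * w) / sum(w)
  seg <- diff(body)
  path <- sum(sqrt(rowSums(seg^2)), na.rm = TRUE)
  total_t <- traj$time_s[nrow(body)] - traj$time_s[1]
  structure(list(
    quadrant_time_s = qt,
    target_quadrant = arena$target_quadrant,
    mean_distance_to_platform_cm = mean_dist,
    path_length_cm = path,
    mean_speed_cm_s = if (total_t > 0) path / total_t else 0
  ), class = "trial_metrics")
}
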