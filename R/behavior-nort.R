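#' Per-frame object-exploration detection
#'
#' A frame counts as exploration of an object when the nose is within
#' `radius_cm` of the object's center and the animal is facing it: the angle
#' between the heading vector (head center to nose) and the vector from the
#' head center to the object center is at most `facing_max_deg`.
#'
#' The 5-cm nose criterion is the study's stated rule; the facing cone is not
#' stated there and defaults to 45 degrees, exposed for sensitivity analysis.
#'
#' @param traj a [trajectory]; run [fill_gaps()] first if the tracking has
#'   dropouts. Frames left `NA` after gap filling are excluded (`NA` in the
#'   output).
#' @param arena an `arena_nort()` specification.
#' @param facing_max_deg half-angle of the facing cone (degrees).
#' @param radius_cm nose-to-object-center distance threshold (cm).
#' @return logical matrix, one row per frame and one column per object id.
#' @export
detect_exploration <- function(traj, arena, facing_max_deg = 45, radius_cm = 5) {
  check_arena_kind(arena, "nort")
  check_pos(radius_cm, "radius_cm")
  if (facing_max_deg <= 0 || facing_max_deg > 180) {
    stopf("`facing_max_deg` must be in (0, 180]")
  }
  nose <- keypoint_xy(traj, "nose")
  head <- keypoint_xy(traj, "head")
  hv <- nose - head
  oc <- arena$object_centers
  out <- matrix(NA, nrow(traj), nrow(oc), dimnames = list(NULL, rownames(oc)))
  cos_max <- cos(facing_max_deg * pi / 180)
  for (k in seq_len(nrow(oc))) {
    dv <- cbind(oc[k, 1] - head[, 1], oc[k, 2] - head[, 2])
    dist_nose <- sqrt((nose[, 1] - oc[k, 1])^2 + (nose[, 2] - oc[k, 2])^2)
    dot <- rowSums(hv * dv)
    den <- sqrt(rowSums(hv^2)) * sqrt(rowSums(dv^2))
    cosang <- ifelse(den > 0, dot / den, 1) # head on the object center: facing
    out[, k] <- dist_nose <= radius_cm & cosang >= cos_max
  }
  out
}

#' Object-exploration times and discrimination index
#'
#' `exploration_times()` integrates the per-frame detection into seconds per
#' object. `discrimination_index()` computes
#' `(t_novel - t_old) / (t_novel + t_old)`, the normalized novelty preference
#' in \[-1, 1\]; 0 means no preference.
#'
#' @param traj a [trajectory].
#' @param arena an `arena_nort()`.
#' @param ... passed on to [detect_exploration()].
#' @return `exploration_times()`: named numeric vector of seconds per object,
#'   with attribute `novel` naming the novel object.
#' @export
exploration_times <- function(traj, arena, ...) {
  expl <- detect_exploration(traj, arena, ...)
  dt <- diff(traj$time_s)
  dt <- c(dt, dt[length(dt)]) # last frame weighted like its predecessor
  times <- colSums(expl * dt, na.rm = TRUE)
  structure(times, novel = arena$novel_object_id)
}

#' @rdname exploration_times
#' @param t_novel_s,t_old_s exploration times (s) of the novel and familiar
#'   object; alternatively pass the result of [exploration_times()] as
#'   `t_novel_s`.
#' @return `discrimination_index()`: a single number in \[-1, 1\], or `NA`
#'   with attribute `undefined = TRUE` when total exploration is zero (such
#'   trials are excluded from group statistics).
#' @export
discrimination_index <- function(t_novel_s, t_old_s = NULL) {
  if (is.null(t_old_s)) {
    novel <- attr(t_novel_s, "novel")
    if (is.null(novel)) stopf("pass two times or an exploration_times() result")
    t_old_s <- sum(t_novel_s[setdiff(names(t_novel_s), novel)])
    t_novel_s <- unname(t_novel_s[novel])
  }
  if (t_novel_s < 0 || t_old_s < 0) stopf("exploration times must be non-negative")
  tot <- t_novel_s + t_old_s
  if (tot <= 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  (t_novel_s - t_old_s) / tot
}
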