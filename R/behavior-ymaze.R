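#' Detect Y-maze arm entries
#'
#' An entry is registered when the body center penetrates an arm beyond
#' `entry_depth_frac` of the arm length (measured along the arm axis from the
#' maze center); consecutive duplicates are collapsed, so oscillating across
#' the threshold within one visit yields a single entry. The depth criterion
#' is a convention of this pipeline (the field does not standardize it) and
#' is exposed for sensitivity analysis.
#'
#' @param traj a [trajectory].
#' @param arena an `arena_ymaze()`.
#' @param entry_depth_frac fraction of the arm length the body center must
#'   reach (default 0.5).
#' @return character vector of arm labels in entry order (possibly empty),
#'   with attribute `entry_frames` giving the frame of each registered entry.
#' @export
detect_arm_entries <- function(traj, arena, entry_depth_frac = 0.5) {
  check_arena_kind(arena, "ymaze")
  check_prob(entry_depth_frac, "entry_depth_frac")
  body <- keypoint_xy(traj, "body")
  u <- arm_unit_vectors(arena)
  L <- arena$arm_length_cm
  halfw <- arena$arm_width_cm / 2
  # per-frame arm membership beyond the depth threshold (0 = none)
  arm_id <- integer(nrow(body))
  depth_min <- entry_depth_frac * L
  for (k in 1:3) {
    s <- body[, 1] * u[k, 1] + body[, 2] * u[k, 2]        # along-axis position
    t_ <- abs(body[, 1] * (-u[k, 2]) + body[, 2] * u[k, 1]) # lateral offset
    inside <- !is.na(s) & s >= depth_min & s <= L & t_ <= halfw
    arm_id[inside] <- k
  }
  keep <- which(arm_id > 0L)
  if (length(keep) == 0L) {
    return(structure(character(0), entry_frames = integer(0)))
  }
  runs <- rle(arm_id[keep])
  firsts <- keep[cumsum(c(1L, head(runs$lengths, -1L)))]
  # collapsing runs of the same arm separated only by out-of-arm frames
  lab <- runs$values
  dedup <- c(TRUE, lab[-1] != lab[-length(lab)])
  structure(arena$arm_labels[lab[dedup]], entry_frames = firsts[dedup])
}

#' Spontaneous alternation ratio
#'
#' The fraction of consecutive overlapping entry triplets that visit three
#' distinct arms, divided by (number of entries minus two) — the classical
#' working-memory readout of the three-arm maze. Under entries drawn
#' independently and uniformly from three arms its expectation is 2/9
#' (about 22 percent), the chance reference used for one-sample tests.
#'
#' @param arm_seq character (or factor) vector of arm labels in entry order.
#' @param as_percent return the ratio times 100.
#' @return the alternation ratio in \[0, 1\] (or percent), or `NA` with
#'   attribute `undefined = TRUE` when fewer than 3 entries were made.
#' @export
spontaneous_alternation <- function(arm_seq, as_percent = FALSE) {
  arm_seq <- as.character(arm_seq)
  n <- length(arm_seq)
  if (n < 3L) {
    return(structure(NA_real_, undefined = TRUE))
  }
  a <- arm_seq[1:(n - 2L)]
  b <- arm_seq[2:(n - 1L)]
  c_ <- arm_seq[3:n]
  distinct <- a != b & b != c_ & a != c_
  ratio <- sum(distinct) / (n - 2L)
  if (as_percent) 100 * ratio else ratio
}
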