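#' Tracked-keypoint trajectory for one trial
#'
#' A `trajectory` holds the pose-estimation output for one behavioral trial:
#' per-frame timestamps and the 2D positions (cm) of three keypoints — nose,
#' head center and body center — each with a tracking confidence in \[0, 1\].
#'
#' @param time_s strictly increasing per-frame timestamps (s).
#' @param nose,head,body two-column matrices of keypoint coordinates (cm).
#' @param likelihood data frame or matrix with columns `nose`, `head`, `body`
#'   of per-frame confidences in \[0, 1\]; defaults to all 1.
#' @return an object of class `trajectory`: a data frame with columns
#'   `time_s`, `<part>_x`, `<part>_y` and `<part>_likelihood` for the three
#'   body parts.
#' @export
trajectory <- function(time_s, nose, head, body, likelihood = NULL) {
  n <- length(time_s)
  if (any(diff(time_s) <= 0)) stopf("`time_s` must be strictly increasing")
  parts <- list(nose = nose, head = head, body = body)
  for (nm in names(parts)) {
    p <- as.matrix(parts[[nm]])
    if (nrow(p) != n || ncol(p) != 2L) {
      stopf("keypoint `%s` must be an n x 2 matrix matching `time_s`", nm)
    }
    parts[[nm]] <- p
  }
  if (is.null(likelihood)) {
    likelihood <- matrix(1, n, 3, dimnames = list(NULL, names(parts)))
  }
  likelihood <- as.matrix(likelihood)
  if (nrow(likelihood) != n || ncol(likelihood) != 3L) {
    stopf("`likelihood` must be n x 3 (nose, head, body)")
  }
  if (any(likelihood < 0 | likelihood > 1, na.rm = TRUE)) {
    stopf("likelihoods must be in [0, 1]")
  }
  df <- data.frame(time_s = as.numeric(time_s))
  for (i in seq_along(parts)) {
    nm <- names(parts)[i]
    df[[paste0(nm, "_x")]] <- parts[[i]][, 1]
    df[[paste0(nm, "_y")]] <- parts[[i]][, 2]
    df[[paste0(nm, "_likelihood")]] <- likelihood[, i]
  }
  class(df) <- c("trajectory", "data.frame")
  df
}

traj_frame_rate <- function(traj) {
  1 / median(diff(traj$time_s))
}

keypoint_xy <- function(traj, part) {
  cbind(traj[[paste0(part, "_x")]], traj[[paste0(part, "_y")]])
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %d frames, %.1f s at ~%.1f Hz>\n",
              nrow(x), diff(range(x$time_s)), traj_frame_rate(x)))
  invisible(x)
}

#' Fill short tracking gaps by interpolation
#'
#' Frames where a keypoint's confidence falls below `min_likelihood` are
#' treated as tracking dropouts. Dropout runs no longer than `max_gap_s` are
#' filled by linear interpolation of that keypoint; longer runs are left as
#' `NA` and flagged in the `excluded` attribute so that time-based
#' denominators can skip them.
#'
#' @param traj a [trajectory].
#' @param min_likelihood confidence threshold below which a frame counts as a
#'   dropout (default 0.6).
#' @param max_gap_s longest dropout run (s) that is interpolated (default 0.5).
#' @return the trajectory with gaps filled; attribute `excluded` is a logical
#'   vector marking frames left unfilled for any keypoint.
#' @export
fill_gaps <- function(traj, min_likelihood = 0.6, max_gap_s = 0.5) {
  excluded <- rep(FALSE, nrow(traj))
  for (part in c("nose", "head", "body")) {
    lik <- traj[[paste0(part, "_likelihood")]]
    bad <- !is.na(lik) & lik < min_likelihood
    bad <- bad | is.na(traj[[paste0(part, "_x")]]) | is.na(traj[[paste0(part, "_y")]])
    if (!any(bad)) next
    r <- rle(bad)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j. in which(r$values)) {
      idx <- starts[j.]:ends[j.]
      gap_s <- traj$time_s[min(ends[j.] + 1L, nrow(traj))] -
        traj$time_s[max(starts[j.] - 1L, 1L)]
      fillable <- gap_s <= max_gap_s &&
        starts[j.] > 1L && ends[j.] < nrow(traj)
      for (ax in c("_x", "_y")) {
        col <- paste0(part, ax)
        if (fillable) {
          ok <- !bad
          traj[[col]][idx] <- approx(traj$time_s[ok], traj[[col]][ok],
                                     xout = traj$time_s[idx])$y
        } else {
          traj[[col]][idx] <- NA_real_
          excluded[idx] <- TRUE
        }
      }
    }
  }
  attr(traj, "excluded") <- excluded
  traj
}

#' Read and write the pose-estimation keypoint CSV dialect
#'
#' The on-disk format is the de facto pose-estimation CSV: three header rows
#' (`scorer`, `bodyparts`, `coords`) followed by one row per frame, with an
#' `x`, `y` and `likelihood` column per body part and the frame index in the
#' first column. Coordinates are stored in cm.
#'
#' @param path file path.
#' @param frame_rate_hz frame rate used to reconstruct timestamps on read.
#' @param traj a [trajectory] to write.
#' @param scorer value of the scorer header row on write.
#' @return `read_keypoint_csv` returns a [trajectory]; `write_keypoint_csv`
#'   returns `path` invisibly.
#' @export
read_keypoint_csv <- function(path, frame_rate_hz = 30) {
  check_pos(frame_rate_hz, "frame_rate_hz")
  hdr <- read.csv(path, header = FALSE, nrows = 3, colClasses = "character")
  body <- read.csv(path, header = FALSE, skip = 3)
  parts <- as.character(hdr[2, -1])
  coords <- as.character(hdr[3, -1])
  get_col <- function(part, coord) {
    j <- which(parts == part & coords == coord)
    if (length(j) != 1L) stopf("column %s/%s not found in %s", part, coord, path)
    as.numeric(body[[j + 1L]])
  }
  frames <- as.numeric(body[[1]])
  part_names <- c(nose = "nose", head = "head_center", body = "body_center")
  lik <- sapply(part_names, function(p) get_col(p, "likelihood"))
  colnames(lik) <- names(part_names)
  trajectory(
    time_s = frames / frame_rate_hz,
    nose = cbind(get_col("nose", "x"), get_col("nose", "y")),
    head = cbind(get_col("head_center", "x"), get_col("head_center", "y")),
    body = cbind(get_col("body_center", "x"), get_col("body_center", "y")),
    likelihood = lik
  )
}

#' @rdname read_keypoint_csv
#' @export
write_keypoint_csv <- function(traj, path, scorer = "pbmstudy") {
  part_names <- c(nose = "nose", head = "head_center", body = "body_center")
  cols <- list()
  for (p in names(part_names)) {
    cols[[paste0(p, "_x")]] <- traj[[paste0(p, "_x")]]
    cols[[paste0(p, "_y")]] <- traj[[paste0(p, "_y")]]
    cols[[paste0(p, "_likelihood")]] <- traj[[paste0(p, "_likelihood")]]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("scorer", rep(scorer, 9)), collapse = ","), con)
  writeLines(paste(c("bodyparts", rep(part_names, each = 3)), collapse = ","), con)
  writeLines(paste(c("coords", rep(c("x", "y", "likelihood"), 3)), collapse = ","), con)
  fr <- round(traj$time_s * traj_frame_rate(traj))
  mat <- cbind(fr, do.call(cbind, cols))
  write.table(mat, con, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}
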