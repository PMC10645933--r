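# Shared fixtures: hand-built trajectories and an independent per-pixel
# annulus oracle. Everything is generated in code; no stored data.

# straight-line trajectory builder: body positions given, heading from the
# supplied unit vectors (nose/head placed at the package's anatomical offsets)
make_traj <- function(body, heading_rad, frame_rate = 10) {
  body <- as.matrix(body)
  u <- cbind(cos(heading_rad), sin(heading_rad))
  head <- body + 1.5 * u
  nose <- head + 1.0 * u
  trajectory((seq_len(nrow(body)) - 1) / frame_rate,
             nose = nose, head = head, body = body)
}

# trajectory with explicit keypoints (for exploration-criterion cases)
make_traj_kp <- function(nose, head, body = NULL, frame_rate = 10) {
  nose <- matrix(nose, ncol = 2)
  head <- matrix(head, ncol = 2)
  if (is.null(body)) body <- head
  trajectory((seq_len(nrow(nose)) - 1) / frame_rate,
             nose = nose, head = head, body = body)
}

# Independent annulus oracle: literal per-pixel enumeration. For each plaque,
# walk every pixel, compute its centroid distance minus the equivalent
# radius, and average intensities in the near/far rings, excluding pixels
# inside any plaque circle and pixels outside the region mask.
brute_force_annulus <- function(img, plaques, mask, px, near = c(0, 12), far = c(18, 60)) {
  nr <- nrow(img); nc <- ncol(img)
  rcol <- if ("equivalent_radius_um" %in% names(plaques)) "equivalent_radius_um" else "radius_um"
  out <- data.frame(plaque_id = plaques$plaque_id, near = NA_real_, far = NA_real_)
  for (j in seq_len(nrow(plaques))) {
    near_vals <- c(); far_vals <- c()
    for (r in seq_len(nr)) {
      for (cc in seq_len(nc)) {
        if (!mask[r, cc]) next
        x <- (cc - 1) * px; y <- (r - 1) * px
        inside_any <- FALSE
        for (k in seq_len(nrow(plaques))) {
          dk <- sqrt((x - plaques$centroid_x_um[k])^2 + (y - plaques$centroid_y_um[k])^2)
          if (dk <= plaques[[rcol]][k]) { inside_any <- TRUE; break }
        }
        if (inside_any) next
        d <- sqrt((x - plaques$centroid_x_um[j])^2 + (y - plaques$centroid_y_um[j])^2) -
          plaques[[rcol]][j]
        if (d > near[1] && d <= near[2]) near_vals <- c(near_vals, img[r, cc])
        if (d >= far[1] && d <= far[2]) far_vals <- c(far_vals, img[r, cc])
      }
    }
    out$near[j] <- mean(near_vals)
    out$far[j] <- mean(far_vals)
  }
  out$ratio <- out$near / out$far
  out
}
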