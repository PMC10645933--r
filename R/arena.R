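#' Arena specifications
#'
#' Constructors for the geometry of the three behavioral apparatuses. All
#' coordinates are in centimeters with the origin at the arena center and the
#' y axis pointing up.
#'
#' @name arena
NULL

new_arena <- function(kind, fields) {
  structure(c(list(kind = kind), fields), class = "arena_spec")
}

#' @describeIn arena Square open-field arena holding two objects for the novel
#'   object recognition test (NORT). Defaults follow a 44 x 44 cm arena with
#'   two objects placed symmetrically about the center.
#'
#' @param side_cm arena side length (cm).
#' @param object_centers two-row matrix of object center coordinates (cm);
#'   row names are the object ids.
#' @param object_radius_cm physical footprint radius of each object (cm).
#' @param novel_object_id which row of `object_centers` is the novel object.
#' @export
arena_nort <- function(side_cm = 44,
                       object_centers = rbind(old = c(-11, 0), novel = c(11, 0)),
                       object_radius_cm = 2,
                       novel_object_id = "novel") {
  check_pos(side_cm, "side_cm")
  check_pos(object_radius_cm, "object_radius_cm")
  object_centers <- as.matrix(object_centers)
  if (nrow(object_centers) != 2L || ncol(object_centers) != 2L) {
    stopf("`object_centers` must be a 2 x 2 matrix (two objects)")
  }
  if (is.null(rownames(object_centers))) {
    rownames(object_centers) <- c("old", "novel")
  }
  if (!novel_object_id %in% rownames(object_centers)) {
    stopf("`novel_object_id` must name a row of `object_centers`")
  }
  if (any(abs(object_centers) > side_cm / 2)) {
    stopf("objects must lie inside the arena")
  }
  new_arena("nort", list(
    side_cm = side_cm,
    object_centers = object_centers,
    object_radius_cm = object_radius_cm,
    novel_object_id = novel_object_id
  ))
}

#' @describeIn arena Three-arm radial (Y) maze. Arms are rectangles of length
#'   `arm_length_cm` and width `arm_width_cm` radiating from the center at
#'   `arm_angles_deg` (measured counter-clockwise from the positive x axis).
#'   Defaults follow a maze with 35 cm long, 5 cm wide arms.
#'
#' @param arm_length_cm arm length (cm).
#' @param arm_width_cm arm width (cm).
#' @param arm_angles_deg angles of the three arm axes (degrees).
#' @param arm_labels labels of the three arms.
#' @export
arena_ymaze <- function(arm_length_cm = 35,
                        arm_width_cm = 5,
                        arm_angles_deg = c(90, 210, 330),
                        arm_labels = c("A", "B", "C")) {
  check_pos(arm_length_cm, "arm_length_cm")
  check_pos(arm_width_cm, "arm_width_cm")
  if (length(arm_angles_deg) != 3L || length(arm_labels) != 3L) {
    stopf("a Y maze has exactly three arms")
  }
  if (anyDuplicated(arm_labels)) stopf("arm labels must be distinct")
  new_arena("ymaze", list(
    arm_length_cm = arm_length_cm,
    arm_width_cm = arm_width_cm,
    arm_angles_deg = as.numeric(arm_angles_deg),
    arm_labels = as.character(arm_labels)
  ))
}

#' @describeIn arena Morris water maze: a circular pool with a (possibly
#'   removed) escape platform and four compass quadrants N/E/S/W. Defaults
#'   follow a 120 cm diameter pool with a 10 cm diameter platform centered in
#'   the target quadrant at half the pool radius.
#'
#' @param pool_radius_cm pool radius (cm).
#' @param platform_center platform center coordinates (cm); also the reference
#'   point of the probe trial after platform removal.
#' @param platform_radius_cm platform radius (cm).
#' @param ... ignored; tolerates extra fields when round-tripping serialized
#'   specifications.
#' @export
arena_mwm <- function(pool_radius_cm = 60,
                      platform_center = c(0, 30),
                      platform_radius_cm = 5,
                      ...) {
  check_pos(pool_radius_cm, "pool_radius_cm")
  check_pos(platform_radius_cm, "platform_radius_cm")
  platform_center <- as.numeric(platform_center)
  if (length(platform_center) != 2L || !all(is.finite(platform_center))) {
    stopf("`platform_center` must be a finite (x, y) pair")
  }
  if (sqrt(sum(platform_center^2)) + platform_radius_cm > pool_radius_cm) {
    stopf("platform must lie entirely inside the pool")
  }
  new_arena("mwm", list(
    pool_radius_cm = pool_radius_cm,
    platform_center = platform_center,
    platform_radius_cm = platform_radius_cm,
    target_quadrant = quadrant_of(platform_center[1], platform_center[2])
  ))
}

#' @export
print.arena_spec <- function(x, ...) {
  cat(sprintf("<arena_spec kind=%s>\n", x$kind))
  for (nm in setdiff(names(x), "kind")) {
    v <- x[[nm]]
    if (is.matrix(v)) {
      cat(sprintf("  %s: %s\n", nm,
                  paste(apply(v, 1L, function(r) paste0("(", paste(r, collapse = ", "), ")")),
                        collapse = " ")))
    } else {
      cat(sprintf("  %s: %s\n", nm, paste(v, collapse = ", ")))
    }
  }
  invisible(x)
}

#' Compass quadrant of pool coordinates
#'
#' Assigns each point to one of the four 90-degree sectors N, E, S, W of the
#' pool, with sector boundaries on the diagonals (N is the sector containing
#' the positive y axis). Ties on a diagonal go to the N/S sector.
#'
#' @param x,y coordinates (cm, pool center at the origin).
#' @return character vector of quadrant labels.
#' @export
quadrant_of <- function(x, y) {
  out <- character(length(x))
  out[y >= abs(x)] <- "N"
  out[y <= -abs(x)] <- "S"
  rest <- out == ""
  out[rest & x > 0] <- "E"
  out[rest & x < 0] <- "W"
  out[out == ""] <- "N" # origin
  out
}

#' Read and write arena specifications as YAML
#'
#' @param path file path.
#' @param arena an [arena_spec][arena] object.
#' @return `read_arena_yaml` returns an `arena_spec`; `write_arena_yaml`
#'   returns `path` invisibly.
#' @export
read_arena_yaml <- function(path) {
  spec <- yaml::read_yaml(path)
  kind <- spec$kind
  spec$kind <- NULL
  switch(kind,
    nort = {
      oc <- do.call(rbind, spec$object_centers)
      spec$object_centers <- oc
      do.call(arena_nort, spec)
    },
    ymaze = do.call(arena_ymaze, spec),
    mwm = {
      spec$target_quadrant <- NULL
      do.call(arena_mwm, spec)
    },
    stopf("unknown arena kind '%s'", kind)
  )
}

#' @rdname read_arena_yaml
#' @export
write_arena_yaml <- function(arena, path) {
  x <- unclass(arena)
  if (arena$kind == "nort") {
    oc <- x$object_centers
    x$object_centers <- setNames(
      lapply(seq_len(nrow(oc)), function(i) as.numeric(oc[i, ])),
      rownames(oc)
    )
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

arm_unit_vectors <- function(arena) {
  th <- arena$arm_angles_deg * pi / 180
  cbind(cos(th), sin(th))
}

check_arena_kind <- function(arena, kind) {
  if (!inherits(arena, "arena_spec")) stopf("`arena` must be an arena_spec")
  if (!arena$kind %in% kind) {
    stopf("arena kind '%s' does not match required kind '%s'",
          arena$kind, paste(kind, collapse = "/"))
  }
  invisible(arena)
}
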