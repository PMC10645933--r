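#' Annotated analysis region of a stained section
#'
#' A region annotation carries the inclusion geometry of one brain region
#' (prefrontal cortex or hippocampus) on a section's pixel grid, with
#' optional exclusion polygons for damaged or artifact-bearing areas.
#' Exclusions are subtracted before any area or intensity computation.
#'
#' Geometry may be given either as polygons (pixel coordinates of vertices,
#' 0-based, x right / y down, matching the on-disk polygon JSON) or directly
#' as a logical mask.
#'
#' @param region_label `"prefrontal_cortex"` or `"hippocampus"` (free-form
#'   labels are allowed but these are the study's regions).
#' @param image_shape section dimensions in pixels (rows, cols).
#' @param pixel_size_um isotropic pixel size (um).
#' @param include list of polygons (each an n x 2 matrix of (x, y) vertices)
#'   or a logical matrix; `NULL` includes the whole image.
#' @param exclude list of polygons or a logical matrix of excluded pixels.
#' @return object of class `region_annotation` with the resolved logical
#'   `mask` (TRUE = analyzed).
#' @export
region_annotation <- function(region_label, image_shape, pixel_size_um = 0.6,
                              include = NULL, exclude = NULL) {
  check_pos(pixel_size_um, "pixel_size_um")
  image_shape <- as.integer(image_shape)
  resolve <- function(geom, default) {
    if (is.null(geom)) return(default)
    if (is.matrix(geom) && is.logical(geom)) {
      if (!all(dim(geom) == image_shape)) stopf("mask dimensions must match `image_shape`")
      return(geom)
    }
    if (is.matrix(geom)) geom <- list(geom)
    m <- matrix(FALSE, image_shape[1], image_shape[2])
    for (p in geom) m <- m | rasterize_polygon(p, image_shape)
    m
  }
  inc <- resolve(include, matrix(TRUE, image_shape[1], image_shape[2]))
  exc <- resolve(exclude, matrix(FALSE, image_shape[1], image_shape[2]))
  structure(list(
    region_label = region_label,
    image_shape = image_shape,
    pixel_size_um = pixel_size_um,
    mask = inc & !exc
  ), class = "region_annotation")
}

#' @export
print.region_annotation <- function(x, ...) {
  cat(sprintf("<region_annotation %s: %d x %d px, %.0f um^2 included>\n",
              x$region_label, x$image_shape[1], x$image_shape[2],
              region_area_um2(x)))
  invisible(x)
}

#' Included area of a region (um^2)
#' @param region a [region_annotation()].
#' @export
region_area_um2 <- function(region) {
  sum(region$mask) * region$pixel_size_um^2
}

# Even-odd rasterization of one polygon onto the pixel grid. Vertices are
# 0-based pixel coordinates (x right, y down); a pixel is inside when its
# center is inside the polygon.
rasterize_polygon <- function(poly, image_shape) {
  poly <- as.matrix(poly)
  if (ncol(poly) != 2L || nrow(poly) < 3L) stopf("polygons need >= 3 (x, y) vertices")
  nr <- image_shape[1]; nc <- image_shape[2]
  xs <- rep(seq_len(nc) - 1, each = nr)
  ys <- rep(seq_len(nr) - 1, nc)
  n <- nrow(poly)
  inside <- rep(FALSE, nr * nc)
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > ys) != (yj > ys)) &
      (xs < (xj - xi) * (ys - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  matrix(inside, nr, nc)
}

#' Read a region annotation from polygon JSON
#'
#' The JSON layout is `{"region_label": ..., "image_shape": [rows, cols],
#' "pixel_size_um": ..., "include": [[[x, y], ...], ...],
#' "exclude": [...]}` with 0-based pixel coordinates, y down.
#'
#' @param path JSON file path.
#' @return a [region_annotation()].
#' @export
read_region_json <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  to_polys <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.matrix(x)) return(list(x))
    # equal-length polygons simplify to one [polygon, vertex, coord] array
    if (is.array(x) && length(dim(x)) == 3L) {
      return(lapply(seq_len(dim(x)[1]), function(i) x[i, , ]))
    }
    lapply(x, as.matrix)
  }
  region_annotation(
    region_label = spec$region_label,
    image_shape = spec$image_shape,
    pixel_size_um = if (is.null(spec$pixel_size_um)) 0.6 else spec$pixel_size_um,
    include = to_polys(spec$include),
    exclude = to_polys(spec$exclude)
  )
}
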