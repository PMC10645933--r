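#' Segment amyloid plaques by global thresholding
#'
#' Stand-in for an interactively trained pixel classifier: pixels of the
#' plaque (congophilic) channel above an intensity threshold inside the
#' included region are grouped into connected components, and components
#' smaller than `min_area_um2` are discarded. The default threshold is Otsu's
#' method computed on the included pixels; a numeric threshold may be given
#' instead. Method and threshold are recorded in the result so runs are
#' auditable.
#'
#' @param plaque_channel numeric intensity matrix (row = y, col = x).
#' @param region a [region_annotation()] on the same pixel grid.
#' @param min_area_um2 minimum plaque area (um^2), default 20.
#' @param threshold_method `"otsu"` or a single numeric intensity threshold.
#' @return list of class `plaque_segmentation`: `mask` (integer label
#'   matrix, 0 = background), `plaques` (the plaque table: one row per
#'   plaque with centroid in pixels and um, `area_um2`,
#'   `equivalent_radius_um = sqrt(area/pi)`, `region_label`), and
#'   `threshold` (the intensity cut actually used).
#' @export
segment_plaques <- function(plaque_channel, region, min_area_um2 = 20,
                            threshold_method = "otsu") {
  if (!inherits(region, "region_annotation")) stopf("`region` must be a region_annotation")
  if (!all(dim(plaque_channel) == region$image_shape)) {
    stopf("image and region annotation must share the pixel grid")
  }
  px <- region$pixel_size_um
  vals <- plaque_channel[region$mask]
  if (length(vals) == 0L) {
    warning("region empty after exclusions; returning an empty plaque table")
    thr <- Inf
  } else if (is.numeric(threshold_method)) {
    thr <- threshold_method
  } else if (identical(threshold_method, "otsu")) {
    rng <- range(vals)
    if (diff(rng) == 0) {
      thr <- rng[1] # flat image: nothing above threshold
    } else {
      scaled <- matrix((plaque_channel - rng[1]) / diff(rng),
                       nrow(plaque_channel))
      thr <- rng[1] + diff(rng) *
        EBImage::otsu(scaled, range = c(0, 1), levels = 256)
    }
  } else {
    stopf("`threshold_method` must be \"otsu\" or a numeric threshold")
  }
  bw <- (plaque_channel > thr) & region$mask
  lab <- EBImage::bwlabel(EBImage::Image(t(bw)))
  lab <- t(EBImage::imageData(lab)) # back to row = y orientation
  ids <- sort(unique(lab[lab > 0]))
  min_px <- min_area_um2 / px^2
  rows <- list()
  out_lab <- matrix(0L, nrow(lab), ncol(lab))
  next_id <- 0L
  for (id in ids) {
    sel <- which(lab == id)
    if (length(sel) < min_px) next
    next_id <- next_id + 1L
    out_lab[sel] <- next_id
    rc <- arrayInd(sel, dim(lab))
    cy <- mean(rc[, 1]) - 1 # 0-based pixel-center coordinates
    cx <- mean(rc[, 2]) - 1
    area <- length(sel) * px^2
    rows[[next_id]] <- data.frame(
      plaque_id = next_id,
      centroid_x_px = cx, centroid_y_px = cy,
      centroid_x_um = cx * px, centroid_y_um = cy * px,
      area_um2 = area,
      equivalent_radius_um = sqrt(area / pi),
      region_label = region$region_label
    )
  }
  plaques <- if (length(rows)) do.call(rbind, rows) else data.frame(
    plaque_id = integer(0), centroid_x_px = numeric(0), centroid_y_px = numeric(0),
    centroid_x_um = numeric(0), centroid_y_um = numeric(0), area_um2 = numeric(0),
    equivalent_radius_um = numeric(0), region_label = character(0)
  )
  structure(list(mask = out_lab, plaques = plaques, threshold = thr),
            class = "plaque_segmentation")
}

#' Plaque load of a region
#'
#' Fraction of the included region area occupied by plaque pixels.
#'
#' @param mask integer or logical plaque mask (non-zero = plaque).
#' @param region a [region_annotation()].
#' @return a number in \[0, 1\].
#' @export
plaque_load <- function(mask, region) {
  if (!all(dim(mask) == region$image_shape)) {
    stopf("mask and region annotation must share the pixel grid")
  }
  denom <- sum(region$mask)
  if (denom == 0L) stopf("region has zero included area")
  sum(mask > 0 & region$mask) / denom
}

#' Peri-plaque microglial response (annulus intensity ratio)
#'
#' For each plaque, the microglial-marker intensity is averaged in a near
#' annulus (plaque edge to `near_um[2]`, default 12 um) and a far annulus
#' (`far_um[1]` to `far_um[2]`, default 18 to 60 um), and their ratio is
#' reported. A spatially uniform microglial density gives a ratio of 1;
#' elevated density around plaques gives ratios above 1.
#'
#' The plaque edge is the circle of the plaque's equivalent radius around its
#' centroid, so the annulus distance of a pixel is its centroid distance (um)
#' minus the equivalent radius. Pixels inside any plaque (per `plaque_mask`,
#' or per the equivalent circles when no mask is given) and pixels outside
#' the included region are excluded from both annuli. In `strict` mode,
#' pixels falling in the annuli of more than one plaque are also dropped;
#' by default such contested pixels contribute to every plaque that claims
#' them.
#'
#' @param microglia_channel numeric intensity matrix.
#' @param plaques plaque table from [segment_plaques()] (or a ground-truth
#'   table with `centroid_x_um`, `centroid_y_um` and `equivalent_radius_um`
#'   or `radius_um` columns).
#' @param region a [region_annotation()].
#' @param near_um,far_um annulus bounds as distances from the plaque edge
#'   (um).
#' @param plaque_mask optional label/logical mask of plaque interiors.
#' @param strict drop pixels contested between plaques.
#' @param summary_fun how per-plaque ratios are aggregated into the region
#'   summary (default mean; median also reported).
#' @return list of class `microglia_response`: `per_plaque` data frame
#'   (`plaque_id`, `mean_intensity_near`, `mean_intensity_far`, `ratio`,
#'   `n_near_px`, `n_far_px`), `summary` (mean, median, n of usable
#'   plaques), and `dropped` (ids of plaques with an empty annulus, e.g. at
#'   the region border).
#' @export
microglia_response <- function(microglia_channel, plaques, region,
                               near_um = c(0, 12), far_um = c(18, 60),
                               plaque_mask = NULL, strict = FALSE,
                               summary_fun = mean) {
  if (!all(dim(microglia_channel) == region$image_shape)) {
    stopf("image and region annotation must share the pixel grid")
  }
  px <- region$pixel_size_um
  nr <- nrow(microglia_channel); nc <- ncol(microglia_channel)
  radius_col <- if ("equivalent_radius_um" %in% names(plaques)) {
    "equivalent_radius_um"
  } else if ("radius_um" %in% names(plaques)) {
    "radius_um"
  } else {
    stopf("`plaques` needs an equivalent_radius_um or radius_um column")
  }
  n_pl <- nrow(plaques)

  # pixels unusable everywhere: outside the region or inside any plaque
  usable <- region$mask
  if (!is.null(plaque_mask)) {
    usable <- usable & !(plaque_mask > 0)
  }
  X <- matrix(rep((seq_len(nc) - 1) * px, each = nr), nr, nc)
  Y <- matrix(rep((seq_len(nr) - 1) * px, nc), nr, nc)
  if (is.null(plaque_mask)) {
    for (j in seq_len(n_pl)) {
      dj <- sqrt((X - plaques$centroid_x_um[j])^2 + (Y - plaques$centroid_y_um[j])^2)
      usable <- usable & (dj > plaques[[radius_col]][j])
    }
  }
  edge_dist <- vector("list", n_pl)
  claim <- matrix(0L, nr, nc) # how many plaques' annuli claim a pixel
  for (j in seq_len(n_pl)) {
    dj <- sqrt((X - plaques$centroid_x_um[j])^2 +
               (Y - plaques$centroid_y_um[j])^2) - plaques[[radius_col]][j]
    edge_dist[[j]] <- dj
    in_ann <- (dj > near_um[1] & dj <= near_um[2]) |
      (dj >= far_um[1] & dj <= far_um[2])
    claim <- claim + in_ann
  }
  if (strict) usable <- usable & (claim <= 1L)

  rows <- list()
  dropped <- integer(0)
  for (j in seq_len(n_pl)) {
    dj <- edge_dist[[j]]
    near_sel <- usable & dj > near_um[1] & dj <= near_um[2]
    far_sel <- usable & dj >= far_um[1] & dj <= far_um[2]
    n_near <- sum(near_sel); n_far <- sum(far_sel)
    if (n_near == 0L || n_far == 0L) {
      dropped <- c(dropped, plaques$plaque_id[j])
      next
    }
    m_near <- mean(microglia_channel[near_sel])
    m_far <- mean(microglia_channel[far_sel])
    rows[[length(rows) + 1L]] <- data.frame(
      plaque_id = plaques$plaque_id[j],
      mean_intensity_near = m_near, mean_intensity_far = m_far,
      ratio = m_near / m_far, n_near_px = n_near, n_far_px = n_far
    )
  }
  per_plaque <- if (length(rows)) do.call(rbind, rows) else data.frame(
    plaque_id = integer(0), mean_intensity_near = numeric(0),
    mean_intensity_far = numeric(0), ratio = numeric(0),
    n_near_px = integer(0), n_far_px = integer(0)
  )
  if (length(dropped)) {
    message(sprintf("microglia_response: dropped %d plaque(s) with an empty annulus (ids: %s)",
                    length(dropped), paste(dropped, collapse = ", ")))
  }
  structure(list(
    per_plaque = per_plaque,
    summary = list(
      region_label = region$region_label,
      ratio_mean = if (nrow(per_plaque)) summary_fun(per_plaque$ratio) else NA_real_,
      ratio_median = if (nrow(per_plaque)) median(per_plaque$ratio) else NA_real_,
      n_plaques = nrow(per_plaque)
    ),
    dropped = dropped,
    near_um = near_um, far_um = far_um
  ), class = "microglia_response")
}

#' Count neurons from an instance label mask
#'
#' Counts nucleus instances whose centroid lies inside the included region,
#' and reports the density per square micrometer. The mask must be an
#' instance segmentation (distinct positive integer per nucleus); a plain
#' binary mask is rejected with a pointer to connected-component labeling.
#'
#' @param label_mask integer instance mask (0 = background).
#' @param region a [region_annotation()].
#' @return list with `count`, `density_per_um2`, and `centroids` (data frame
#'   of counted instances, 0-based pixel coordinates).
#' @export
count_neurons <- function(label_mask, region) {
  if (!all(dim(label_mask) == region$image_shape)) {
    stopf("mask and region annotation must share the pixel grid")
  }
  ids <- unique(label_mask[label_mask > 0])
  if (length(ids) == 1L && all(label_mask %in% c(0, 1)) && sum(label_mask == 1) > 0) {
    stopf(paste("`label_mask` looks binary, not an instance segmentation;",
                "label connected components first (e.g. EBImage::bwlabel)"))
  }
  area <- region_area_um2(region)
  if (area <= 0) stopf("region has zero included area")
  rows <- list()
  for (id in sort(ids)) {
    rc <- arrayInd(which(label_mask == id), dim(label_mask))
    cy <- mean(rc[, 1]) - 1
    cx <- mean(rc[, 2]) - 1
    ri <- round(cy) + 1L; ci <- round(cx) + 1L
    if (region$mask[ri, ci]) {
      rows[[length(rows) + 1L]] <- data.frame(
        nucleus_id = id, centroid_x_px = cx, centroid_y_px = cy
      )
    }
  }
  centroids <- if (length(rows)) do.call(rbind, rows) else data.frame(
    nucleus_id = integer(0), centroid_x_px = numeric(0), centroid_y_px = numeric(0)
  )
  list(count = nrow(centroids),
       density_per_um2 = nrow(centroids) / area,
       centroids = centroids)
}
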