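#' Parameters for the synthetic stained-section generator
#'
#' Describes a synthetic three-channel fluorescence section: disk-like amyloid
#' plaques (congophilic channel), a microglial marker channel whose intensity
#' is radially enriched around each plaque, and nucleus-like blobs (neuronal
#' marker channel). The default pixel size of 0.6 um matches the acquisition
#' geometry the pipeline is designed for.
#'
#' The microglial enrichment profile is a multiplicative plateau: intensity is
#' `microglia_baseline * enrichment_factor` from the plaque edge out to
#' `enrichment_decay_um`, then falls off linearly to baseline over
#' `enrichment_falloff_um`. With the defaults (12 um plateau, 6 um falloff)
#' the near annulus (edge to 12 um) is fully enriched and the far annulus
#' (18 to 60 um) is pure baseline, so the expected annulus ratio equals
#' `enrichment_factor` exactly.
#'
#' @param image_shape image dimensions in pixels (rows, cols).
#' @param pixel_size_um isotropic pixel size (um).
#' @param plaque_count number of plaques.
#' @param plaque_radius_um_range range of plaque radii (um).
#' @param plaque_intensity peak intensity of the plaque channel.
#' @param background background intensity of the plaque and nucleus channels.
#' @param microglia_baseline baseline intensity of the microglial channel.
#' @param enrichment_factor multiplicative intensity elevation inside the
#'   peri-plaque enrichment zone (must be > 0; 1 means no enrichment).
#' @param enrichment_decay_um width of the enrichment plateau outside the
#'   plaque edge (um).
#' @param enrichment_falloff_um width of the linear return to baseline (um).
#' @param nucleus_count number of nucleus-like blobs.
#' @param nucleus_radius_um nucleus radius (um).
#' @param noise_sd s.d. of additive Gaussian noise (clipped at zero);
#'   `noise_model = "poisson"` instead draws each pixel from a Poisson law
#'   with the noise-free value as mean.
#' @param noise_model `"gaussian"` or `"poisson"`.
#' @param min_separation_um minimum edge-to-edge distance between plaques.
#' @param border_margin_um minimum distance from any plaque edge to the image
#'   border; the default (66 um) keeps the full far annulus inside the image.
#' @param seed integer seed.
#' @return a list of class `histo_sim_params`.
#' @export
histo_sim_params <- function(image_shape = c(512, 512),
                             pixel_size_um = 0.6,
                             plaque_count = 5,
                             plaque_radius_um_range = c(8, 15),
                             plaque_intensity = 1000,
                             background = 20,
                             microglia_baseline = 200,
                             enrichment_factor = 1.8,
                             enrichment_decay_um = 12,
                             enrichment_falloff_um = 6,
                             nucleus_count = 50,
                             nucleus_radius_um = 4,
                             noise_sd = 0,
                             noise_model = c("gaussian", "poisson"),
                             min_separation_um = 4,
                             border_margin_um = 66,
                             seed = NULL) {
  noise_model <- match.arg(noise_model)
  check_pos(pixel_size_um, "pixel_size_um")
  check_pos(enrichment_factor, "enrichment_factor")
  if (length(image_shape) != 2L || any(image_shape < 8)) {
    stopf("`image_shape` must be (rows, cols), each >= 8 pixels")
  }
  if (length(plaque_radius_um_range) != 2L || any(plaque_radius_um_range <= 0) ||
      diff(plaque_radius_um_range) < 0) {
    stopf("`plaque_radius_um_range` must be a positive (min, max) pair")
  }
  if (plaque_count < 0 || nucleus_count < 0) stopf("counts must be non-negative")
  if (noise_sd < 0) stopf("`noise_sd` must be non-negative")
  structure(list(
    image_shape = as.integer(image_shape), pixel_size_um = pixel_size_um,
    plaque_count = as.integer(plaque_count),
    plaque_radius_um_range = plaque_radius_um_range,
    plaque_intensity = plaque_intensity, background = background,
    microglia_baseline = microglia_baseline,
    enrichment_factor = enrichment_factor,
    enrichment_decay_um = enrichment_decay_um,
    enrichment_falloff_um = enrichment_falloff_um,
    nucleus_count = as.integer(nucleus_count),
    nucleus_radius_um = nucleus_radius_um,
    noise_sd = noise_sd, noise_model = noise_model,
    min_separation_um = min_separation_um,
    border_margin_um = border_margin_um, seed = seed
  ), class = "histo_sim_params")
}

# Rejection-sample non-overlapping disk centers (um, 0-based pixel frame).
place_disks <- function(n, radii_um, extent_um, margin_um, sep_um, max_tries = 5000L) {
  centers <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    lo <- radii_um[i] + margin_um
    hi_x <- extent_um[1] - lo
    hi_y <- extent_um[2] - lo
    if (hi_x <= lo || hi_y <= lo) {
      stopf("impossible packing: disk %d (radius %.1f um + margin %.1f um) does not fit the image",
            i, radii_um[i], margin_um)
    }
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- c(runif(1, lo, hi_x), runif(1, lo, hi_y))
      if (i == 1L) { ok <- TRUE } else {
        d <- sqrt(rowSums((centers[seq_len(i - 1L), , drop = FALSE] -
                             matrix(cand, i - 1L, 2, byrow = TRUE))^2))
        ok <- all(d >= radii_um[i] + radii_um[seq_len(i - 1L)] + sep_um)
      }
      if (ok) { centers[i, ] <- cand; break }
    }
    if (!ok) stopf("impossible packing: could not place %d non-overlapping disks", n)
  }
  centers
}

#' Simulate a stained section with known ground truth
#'
#' Generates the three channels described in [histo_sim_params()] as numeric
#' intensity matrices (row = y, increasing downward; column = x), plus an
#' instance label mask for the nuclei, and exports the exact ground truth
#' (plaque centers/radii, enrichment factor, nucleus centers).
#'
#' Pixel coordinates in the ground truth are 0-based, (x, y) with y down, and
#' refer to pixel centers; micrometer coordinates are pixels times
#' `pixel_size_um`.
#'
#' @param params a [histo_sim_params()].
#' @return list of class `histo_sim` with elements `images` (list
#'   `plaque`, `microglia`, `nucleus`, `nucleus_label`) and `ground_truth`
#'   (list with `plaques` data frame, `enrichment_factor`, `nuclei` data
#'   frame, `pixel_size_um`).
#' @export
simulate_histology_image <- function(params) {
  if (!inherits(params, "histo_sim_params")) {
    stopf("`params` must be created by histo_sim_params()")
  }
  with_seed(params$seed, {
    nr <- params$image_shape[1]
    nc <- params$image_shape[2]
    px <- params$pixel_size_um
    extent <- c(nc, nr) * px
    X <- matrix(rep((seq_len(nc) - 1) * px, each = nr), nr, nc)
    Y <- matrix(rep((seq_len(nr) - 1) * px, nc), nr, nc)

    radii <- runif(params$plaque_count, params$plaque_radius_um_range[1],
                   params$plaque_radius_um_range[2])
    centers <- place_disks(params$plaque_count, radii, extent,
                           params$border_margin_um, params$min_separation_um)

    # distance (um) from each pixel center to the nearest plaque edge
    d_edge <- matrix(Inf, nr, nc)
    plaque_mask <- matrix(FALSE, nr, nc)
    for (j in seq_len(params$plaque_count)) {
      dj <- sqrt((X - centers[j, 1])^2 + (Y - centers[j, 2])^2) - radii[j]
      d_edge <- pmin(d_edge, dj)
      plaque_mask <- plaque_mask | (dj <= 0)
    }

    f <- params$enrichment_factor
    dec <- params$enrichment_decay_um
    fall <- params$enrichment_falloff_um
    profile <- matrix(1, nr, nc)
    if (is.finite(dec)) {
      in_plateau <- d_edge <= dec
      in_fall <- d_edge > dec & d_edge < dec + fall
      profile[in_plateau] <- f
      profile[in_fall] <- f + (1 - f) * (d_edge[in_fall] - dec) / fall
    }
    microglia <- params$microglia_baseline * profile
    plaque_ch <- matrix(params$background, nr, nc)
    plaque_ch[plaque_mask] <- params$plaque_intensity

    nuc_r <- params$nucleus_radius_um
    nuc_centers <- place_disks(params$nucleus_count,
                               rep(nuc_r, params$nucleus_count), extent,
                               margin_um = 1, sep_um = 1)
    nucleus <- matrix(params$background, nr, nc)
    nucleus_label <- matrix(0L, nr, nc)
    for (j in seq_len(params$nucleus_count)) {
      inside <- (X - nuc_centers[j, 1])^2 + (Y - nuc_centers[j, 2])^2 <= nuc_r^2
      nucleus[inside] <- 500
      nucleus_label[inside] <- j
    }

    add_noise <- function(img) {
      if (params$noise_model == "poisson") {
        matrix(stats::rpois(length(img), lambda = pmax(img, 0)), nrow(img))
      } else if (params$noise_sd > 0) {
        pmax(img + rnorm(length(img), 0, params$noise_sd), 0)
      } else {
        img
      }
    }
    images <- list(
      plaque = add_noise(plaque_ch),
      microglia = add_noise(microglia),
      nucleus = add_noise(nucleus),
      nucleus_label = nucleus_label
    )
    plaques <- data.frame(
      plaque_id = seq_len(params$plaque_count),
      centroid_x_px = centers[, 1] / px, centroid_y_px = centers[, 2] / px,
      centroid_x_um = centers[, 1], centroid_y_um = centers[, 2],
      radius_um = radii
    )[seq_len(params$plaque_count), , drop = FALSE]
    nuclei <- data.frame(
      nucleus_id = seq_len(params$nucleus_count),
      centroid_x_px = nuc_centers[, 1] / px,
      centroid_y_px = nuc_centers[, 2] / px
    )[seq_len(params$nucleus_count), , drop = FALSE]
    structure(list(
      images = images,
      ground_truth = list(kind = "histology", plaques = plaques,
                          enrichment_factor = f, nuclei = nuclei,
                          pixel_size_um = px)
    ), class = "histo_sim")
  })
}

#' Write and read synthetic channels as 16-bit TIFF
#'
#' Intensities are stored as 16-bit grayscale; values are divided by
#' `scale` (default 65535) on write and multiplied back on read, so integer
#' intensities up to 65535 round-trip exactly.
#'
#' @param images named list of numeric matrices (as produced by
#'   [simulate_histology_image()]).
#' @param dir output directory; one `<name>.tif` per channel.
#' @param scale full-scale intensity mapped to the 16-bit maximum.
#' @return `write_histology_tiff` returns the written paths invisibly;
#'   `read_histology_tiff` returns a named list of matrices.
#' @export
write_histology_tiff <- function(images, dir, scale = 65535) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(images)) {
    p <- file.path(dir, paste0(nm, ".tif"))
    img <- pmin(pmax(images[[nm]] / scale, 0), 1)
    tiff::writeTIFF(img, p, bits.per.sample = 16L)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname write_histology_tiff
#' @export
read_histology_tiff <- function(dir, scale = 65535) {
  files <- list.files(dir, pattern = "\\.tif$", full.names = TRUE)
  out <- lapply(files, function(p) tiff::readTIFF(p) * scale)
  names(out) <- sub("\\.tif$", "", basename(files))
  out
}

#' Serialize ground truth as JSON
#'
#' @param gt a `ground_truth` list from a simulator.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(gt, path) {
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}
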