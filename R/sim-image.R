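#' Parameters for the synthetic embryo image simulator
#'
#' A stated world for two-channel 3D in situ hybridization volumes of the
#' heart field: channel 1 contains Gaussian nuclei (the Hoechst
#' counterstain), channel 2 contains diffraction-limited transcript spots
#' placed uniformly at Poisson-distributed counts inside two box-shaped
#' region halves mirrored across a planar midline. The true left/right spot
#' density ratio is `lr_fold`; `side_intensity_bias` multiplies voxel
#' intensities on one side of the midline in both channels, emulating
#' one-sided lightsheet attenuation (the effect the Hoechst normalization
#' is designed to cancel).
#'
#' Defaults: a 56 x 56 x 28 micrometer field of view at 0.5 micrometer
#' isotropic voxels; 120 nuclei per side (sigma 2 micrometers) placed with
#' a hard-core exclusion of one nuclear diameter, as real nuclei cannot
#' overlap; transcript spots of sigma 0.4 micrometers at 0.005 spots per
#' cubic micrometer on the right (optically resolvable, the regime in which
#' single-molecule spot counting is quantitative); Poisson shot noise on
#' the rendered intensity.
#'
#' @param shape_voxels integer triple, volume shape in voxels.
#' @param voxel_size_um positive triple, voxel size in micrometers.
#' @param n_nuclei_per_side integer pair (left, right).
#' @param spot_density_right expected transcript spots per cubic micrometer
#'   on the right side.
#' @param lr_fold true left/right spot-density ratio (>= 0).
#' @param side_intensity_bias multiplicative intensity factor applied to
#'   `bias_side` only, both channels (> 0).
#' @param bias_side "left" or "right".
#' @param psf_sigma_um point-spread-function sigma triple (micrometers),
#'   added in quadrature to object sizes.
#' @param noise_model "poisson" or "gaussian".
#' @param gaussian_sd read-noise sd when `noise_model = "gaussian"`.
#' @param nucleus_sigma_um,spot_sigma_um object sizes (micrometers).
#' @param nucleus_amp,spot_amp,background rendered intensities (counts).
#' @param seed integer seed.
#' @return an `image_sim_params` list.
#' @export
image_sim_params <- function(shape_voxels = c(112, 112, 56),
                             voxel_size_um = c(0.5, 0.5, 0.5),
                             n_nuclei_per_side = c(120, 120),
                             spot_density_right = 0.005,
                             lr_fold = 1,
                             side_intensity_bias = 1,
                             bias_side = "right",
                             psf_sigma_um = c(0.25, 0.25, 0.5),
                             noise_model = "poisson",
                             gaussian_sd = 3,
                             nucleus_sigma_um = 2,
                             spot_sigma_um = 0.4,
                             nucleus_amp = 120,
                             spot_amp = 150,
                             background = 5,
                             seed = 1) {
  check_triple(shape_voxels, "shape_voxels", positive = TRUE,
               integerish = TRUE)
  check_triple(voxel_size_um, "voxel_size_um", positive = TRUE)
  if (!is.numeric(n_nuclei_per_side) || length(n_nuclei_per_side) != 2L ||
      any(n_nuclei_per_side <= 0) ||
      any(n_nuclei_per_side != round(n_nuclei_per_side)))
    stop_field("n_nuclei_per_side", "must be a positive integer pair")
  check_scalar(spot_density_right, "spot_density_right", nonneg = TRUE)
  check_scalar(lr_fold, "lr_fold", nonneg = TRUE)
  check_scalar(side_intensity_bias, "side_intensity_bias", positive = TRUE)
  bias_side <- match.arg(bias_side, c("left", "right"))
  check_triple(psf_sigma_um, "psf_sigma_um", positive = TRUE)
  noise_model <- match.arg(noise_model, c("poisson", "gaussian"))
  check_scalar(gaussian_sd, "gaussian_sd", nonneg = TRUE)
  check_scalar(nucleus_sigma_um, "nucleus_sigma_um", positive = TRUE)
  check_scalar(spot_sigma_um, "spot_sigma_um", positive = TRUE)
  check_scalar(background, "background", nonneg = TRUE)
  check_scalar(seed, "seed", integerish = TRUE)
  structure(list(shape_voxels = as.integer(shape_voxels),
                 voxel_size_um = voxel_size_um,
                 n_nuclei_per_side = as.integer(n_nuclei_per_side),
                 spot_density_right = spot_density_right,
                 lr_fold = lr_fold,
                 side_intensity_bias = side_intensity_bias,
                 bias_side = bias_side,
                 psf_sigma_um = psf_sigma_um,
                 noise_model = noise_model, gaussian_sd = gaussian_sd,
                 nucleus_sigma_um = nucleus_sigma_um,
                 spot_sigma_um = spot_sigma_um,
                 nucleus_amp = nucleus_amp, spot_amp = spot_amp,
                 background = background, seed = seed),
            class = "image_sim_params")
}

#' Named presets for the image simulator
#'
#' `"E8.5d"` fixes the generator's true left/right transcript-density ratio
#' to 4.5, the peak heart-field enrichment of the left-sided marker at
#' stage E8.5d; `"symmetric"` is the null world (ratio 1).
#'
#' @param name preset name.
#' @param ... overrides passed to [image_sim_params()] (e.g. `seed`).
#' @return an `image_sim_params` object.
#' @export
image_sim_preset <- function(name = c("E8.5d", "symmetric"), ...) {
  name <- match.arg(name)
  lr <- switch(name, "E8.5d" = 4.5, "symmetric" = 1)
  image_sim_params(lr_fold = lr, ...)
}

## Add a separable Gaussian blob to a 3D array, center in voxel units
## (1-based, possibly fractional), sigma in voxel units per axis.
add_blob <- function(vol, center, sigma_vox, amp) {
  d <- dim(vol)
  rng <- lapply(1:3, function(a) {
    r <- ceiling(4 * sigma_vox[a])
    lo <- max(1L, floor(center[a]) - r)
    hi <- min(d[a], ceiling(center[a]) + r)
    lo:hi
  })
  if (any(vapply(rng, length, 1L) == 0L)) return(vol)
  g <- lapply(1:3, function(a)
    exp(-(rng[[a]] - center[a])^2 / (2 * sigma_vox[a]^2)))
  blob <- amp * (g[[1]] %o% g[[2]] %o% g[[3]])
  vol[rng[[1]], rng[[2]], rng[[3]]] <-
    vol[rng[[1]], rng[[2]], rng[[3]]] + blob
  vol
}

## Signed distance value of voxel centers to a plane (a, b, c, d) given in
## micrometer coordinates; voxel i has coordinate (i - 1) * voxel_size.
plane_value_array <- function(shape, voxel_size, plane) {
  vx <- (seq_len(shape[1]) - 1) * voxel_size[1]
  vy <- (seq_len(shape[2]) - 1) * voxel_size[2]
  vz <- (seq_len(shape[3]) - 1) * voxel_size[3]
  outer(outer(plane[1] * vx, plane[2] * vy, `+`), plane[3] * vz, `+`) +
    plane[4]
}

#' Construct a spot image
#'
#' The in-memory container for a two-channel 3D volume: channel "nuclei"
#' (Hoechst) and channel "transcript", a region label mask sharing the same
#' voxel grid, the midline plane (coefficients (a, b, c, d) of
#' a x + b y + c z + d = 0 in micrometer coordinates, positive side =
#' embryo's left) and a region-label dictionary. Voxel i maps to micrometer
#' coordinate (i - 1) * voxel_size (0-based grid).
#'
#' @param volume 4D numeric array (x, y, z, channel) with 2 channels.
#' @param voxel_size_um positive triple.
#' @param region_mask 3D integer label array, same spatial shape.
#' @param midline_plane numeric(4) plane coefficients.
#' @param region_labels named integer vector, name -> label.
#' @param embryo_id,stage,genotype metadata.
#' @return a `spot_image`.
#' @export
spot_image <- function(volume, voxel_size_um, region_mask, midline_plane,
                       region_labels, embryo_id = "embryo", stage = "E8.5d",
                       genotype = "WT") {
  if (length(dim(volume)) != 4L || dim(volume)[4] != 2L)
    stop("volume must be a 4D array with 2 channels", call. = FALSE)
  if (!identical(dim(volume)[1:3], dim(region_mask)))
    stop("volume and region_mask shapes disagree", call. = FALSE)
  check_triple(voxel_size_um, "voxel_size_um", positive = TRUE)
  if (length(midline_plane) != 4L || all(abs(midline_plane[1:3]) < 1e-12))
    stop("degenerate midline plane", call. = FALSE)
  structure(list(volume = volume, voxel_size_um = voxel_size_um,
                 region_mask = region_mask, midline_plane = midline_plane,
                 region_labels = region_labels, embryo_id = embryo_id,
                 stage = stage, genotype = genotype,
                 channels = c(nuclei = 1L, transcript = 2L)),
            class = "spot_image")
}

#' @export
print.spot_image <- function(x, ...) {
  d <- dim(x$volume)
  cat(sprintf(
    "spot_image '%s' (%s, %s): %d x %d x %d voxels, %.2g x %.2g x %.2g um, regions: %s\n",
    x$embryo_id, x$stage, x$genotype, d[1], d[2], d[3],
    x$voxel_size_um[1], x$voxel_size_um[2], x$voxel_size_um[3],
    paste(names(x$region_labels), collapse = ", ")))
  invisible(x)
}

#' Simulate a two-channel embryo image
#'
#' Renders nuclei and transcript spots inside a heart-field region made of
#' two boxes mirrored across the midline plane at mid-X. Expected spot
#' count per side = density x region volume with left density =
#' `lr_fold` x right density; exact nucleus counts are placed per side.
#' Object profiles are Gaussians whose sigma is the object size convolved
#' (in quadrature) with the point-spread function. The intensity bias is
#' applied to one whole side, both channels, before noise.
#'
#' @param params an [image_sim_params()] object.
#' @return list with `image` (a [spot_image()]) and `truth`
#'   (`ground_truth`: true nucleus/spot coordinates and per-side counts).
#' @export
simulate_embryo_image <- function(params = image_sim_params()) {
  if (!inherits(params, "image_sim_params"))
    params <- do.call(image_sim_params, as.list(params))
  p <- params
  shp <- p$shape_voxels
  vox <- p$voxel_size_um
  if (any(shp < 24L))
    stop("shape_voxels too small to contain both region masks (min 24)",
         call. = FALSE)

  ## mirrored region boxes; midline between the two central voxel columns
  margin <- c(4L, 4L, 3L)
  gap <- 2L
  half <- shp[1] %/% 2L
  x_right <- (margin[1] + 1L):(half - gap)
  x_left <- (shp[1] - half + gap + 1L):(shp[1] - margin[1])
  yr <- (margin[2] + 1L):(shp[2] - margin[2])
  zr <- (margin[3] + 1L):(shp[3] - margin[3])
  if (!length(x_right) || !length(yr) || !length(zr))
    stop("shape_voxels too small to contain both region masks",
         call. = FALSE)
  mask <- array(0L, shp)
  mask[x_right, yr, zr] <- 1L
  mask[x_left, yr, zr] <- 1L
  plane <- c(1, 0, 0, -((half - 0.5) * vox[1]))  # >= 0 is left (high x)

  voxel_volume <- prod(vox)
  pv <- plane_value_array(shp, vox, plane)
  left_vox <- which(mask == 1L & pv >= 0, arr.ind = TRUE)
  right_vox <- which(mask == 1L & pv < 0, arr.ind = TRUE)
  v_left <- nrow(left_vox) * voxel_volume
  v_right <- nrow(right_vox) * voxel_volume

  sig_nuc <- sqrt(p$nucleus_sigma_um^2 + p$psf_sigma_um^2) / vox
  sig_spot <- sqrt(p$spot_sigma_um^2 + p$psf_sigma_um^2) / vox

  with_seed(p$seed, {
    place_uniform <- function(vox_idx, n) {
      if (n == 0L) return(matrix(numeric(0), 0, 3))
      rows <- vox_idx[sample.int(nrow(vox_idx), n, replace = TRUE), ,
                      drop = FALSE]
      rows + matrix(stats::runif(3 * n, -0.5, 0.5), n, 3)  # voxel units
    }
    ## nuclei exclude each other: sequential hard-core placement at one
    ## nuclear diameter (2.3 sigma), in micrometers
    place_hardcore <- function(vox_idx, n, r_min_um) {
      kept <- matrix(numeric(0), 0, 3)
      tries <- 0L
      while (nrow(kept) < n) {
        tries <- tries + 1L
        if (tries > 400L * n)
          stop("n_nuclei_per_side too large for the region at the ",
               "hard-core distance", call. = FALSE)
        cand <- place_uniform(vox_idx, 1L)
        if (nrow(kept)) {
          d2 <- rowSums(sweep(sweep(kept, 2, cand[1, ]), 2, vox, `*`)^2)
          if (min(d2) < r_min_um^2) next
        }
        kept <- rbind(kept, cand)
      }
      kept
    }
    r_hard <- 2.3 * p$nucleus_sigma_um
    nuc_l <- place_hardcore(left_vox, p$n_nuclei_per_side[1], r_hard)
    nuc_r <- place_hardcore(right_vox, p$n_nuclei_per_side[2], r_hard)
    n_spot_l <- stats::rpois(1, p$lr_fold * p$spot_density_right * v_left)
    n_spot_r <- stats::rpois(1, p$spot_density_right * v_right)
    spot_l <- place_uniform(left_vox, n_spot_l)
    spot_r <- place_uniform(right_vox, n_spot_r)

    ch_nuc <- array(p$background, shp)
    ch_spot <- array(p$background, shp)
    for (i in seq_len(nrow(nuc_l)))
      ch_nuc <- add_blob(ch_nuc, nuc_l[i, ], sig_nuc, p$nucleus_amp)
    for (i in seq_len(nrow(nuc_r)))
      ch_nuc <- add_blob(ch_nuc, nuc_r[i, ], sig_nuc, p$nucleus_amp)
    for (i in seq_len(nrow(spot_l)))
      ch_spot <- add_blob(ch_spot, spot_l[i, ], sig_spot, p$spot_amp)
    for (i in seq_len(nrow(spot_r)))
      ch_spot <- add_blob(ch_spot, spot_r[i, ], sig_spot, p$spot_amp)

    if (p$side_intensity_bias != 1) {
      biased <- if (p$bias_side == "left") pv >= 0 else pv < 0
      ch_nuc[biased] <- ch_nuc[biased] * p$side_intensity_bias
      ch_spot[biased] <- ch_spot[biased] * p$side_intensity_bias
    }
    if (p$noise_model == "poisson") {
      ch_nuc[] <- stats::rpois(length(ch_nuc), ch_nuc)
      ch_spot[] <- stats::rpois(length(ch_spot), ch_spot)
    } else if (p$gaussian_sd > 0) {
      ch_nuc[] <- pmax(0, ch_nuc + stats::rnorm(length(ch_nuc), 0,
                                                p$gaussian_sd))
      ch_spot[] <- pmax(0, ch_spot + stats::rnorm(length(ch_spot), 0,
                                                  p$gaussian_sd))
    }
    volume <- array(0, c(shp, 2L))
    volume[, , , 1] <- ch_nuc
    volume[, , , 2] <- ch_spot

    to_um <- function(m) sweep(m - 1, 2, vox, `*`)
    img <- spot_image(volume, vox, mask, plane,
                      region_labels = c(heart_field = 1L),
                      embryo_id = sprintf("sim%06d", p$seed),
                      stage = if (p$lr_fold == 4.5) "E8.5d" else "sim")
    truth <- structure(list(
      kind = "embryo_image",
      lr_fold = p$lr_fold,
      n_spots_left = n_spot_l, n_spots_right = n_spot_r,
      spot_um_left = to_um(spot_l), spot_um_right = to_um(spot_r),
      nuclei_um_left = to_um(nuc_l), nuclei_um_right = to_um(nuc_r),
      region_volume_left = v_left, region_volume_right = v_right,
      params = unclass(p)
    ), class = "ground_truth")
    list(image = img, truth = truth)
  })
}
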