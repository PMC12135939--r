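## Single-scale Laplacian-of-Gaussian spot detection on anisotropic 3D
## volumes. The open equivalent of a commercial "spot detector": a
## scale-normalized LoG response, local maxima, an intensity-percentile
## threshold and non-maximum suppression within one spot radius.

## 1D convolution along one array axis with a symmetric kernel (zero
## padding), via a banded matrix product; volumes here are small enough
## that the dense band matrix is the fastest portable route.
conv_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  n <- d[axis]
  r <- (length(kernel) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (k in -r:r) {
    i <- seq_len(n)
    j <- i + k
    ok <- j >= 1 & j <= n
    K[cbind(i[ok], j[ok])] <- kernel[k + r + 1L]
  }
  m <- K %*% matrix(a, nrow = n)
  out <- array(m, dim = d[perm])
  aperm(out, order(perm))
}

gauss_kernel <- function(sigma_vox, vox_um) {
  r <- max(1L, ceiling(4 * sigma_vox))
  x <- (-r:r) * vox_um
  s <- sigma_vox * vox_um
  g <- exp(-x^2 / (2 * s^2))
  g / sum(g)
}

## Second derivative of a Gaussian, sampled; zero-DC corrected so flat
## regions respond 0, normalized consistently with gauss_kernel.
gauss_d2_kernel <- function(sigma_vox, vox_um) {
  r <- max(1L, ceiling(4 * sigma_vox))
  x <- (-r:r) * vox_um
  s <- sigma_vox * vox_um
  g <- exp(-x^2 / (2 * s^2))
  d2 <- (x^2 - s^2) / s^4 * g / sum(g)
  d2 - sum(d2) / length(d2)
}

## Scale-normalized negative Laplacian of Gaussian (positive on bright
## blobs), sigma in micrometers per axis.
log_response <- function(arr, sigma_um, vox_um) {
  sig_vox <- sigma_um / vox_um
  g <- lapply(1:3, function(a) gauss_kernel(sig_vox[a], vox_um[a]))
  d2 <- lapply(1:3, function(a) gauss_d2_kernel(sig_vox[a], vox_um[a]))
  resp <- array(0, dim(arr))
  for (ax in 1:3) {
    term <- arr
    for (b in 1:3) {
      kern <- if (b == ax) d2[[b]] else g[[b]]
      term <- conv_axis(term, kern, b)
    }
    resp <- resp - sigma_um[ax]^2 * term
  }
  resp
}

## TRUE at strict-or-plateau local maxima over the 26-neighborhood.
local_maxima3 <- function(arr) {
  d <- dim(arr)
  mx <- arr
  shift_max <- function(a, axis) {
    d <- dim(a)
    idx_lo <- c(list(1), lapply(d[-1], seq_len))
    pad <- function(n) array(-Inf, replace(d, axis, 1))
    sl <- function(a, from, to) {
      idx <- lapply(d, seq_len)
      idx[[axis]] <- from:to
      do.call(`[`, c(list(a), idx, list(drop = FALSE)))
    }
    n <- d[axis]
    up <- if (n > 1) abind_axis(sl(a, 2, n), pad(n), axis) else pad(n)
    dn <- if (n > 1) abind_axis(pad(n), sl(a, 1, n - 1), axis) else pad(n)
    pmax(a, up, dn)
  }
  for (ax in 1:3) mx <- shift_max(mx, ax)
  arr >= mx  # arr == running 3^3 max
}

## bind two arrays along an axis (tiny abind substitute)
abind_axis <- function(a, b, axis) {
  d <- dim(a)
  d2 <- dim(b)
  perm <- c(setdiff(1:3, axis), axis)
  m <- cbind(matrix(aperm(a, perm), ncol = d[axis]),
             matrix(aperm(b, perm), ncol = d2[axis]))
  out <- array(m, c(d[perm[1:2]], d[axis] + d2[axis]))
  aperm(out, order(perm))
}

## Greedy non-maximum suppression: keep points in decreasing response
## order, dropping any within `radius` (micrometers) of a kept point.
## Returns the indices kept, in decreasing response order.
nms_points <- function(coords_um, response, radius) {
  ord <- order(response, decreasing = TRUE)
  kept <- matrix(numeric(0), 0, 3)
  keep_idx <- integer(0)
  for (i in ord) {
    if (nrow(kept) == 0L ||
        min(rowSums(sweep(kept, 2, coords_um[i, ])^2)) > radius^2) {
      keep_idx <- c(keep_idx, i)
      kept <- rbind(kept, coords_um[i, ])
    }
  }
  keep_idx
}

#' A detected spot set
#'
#' @param coords_um n x 3 matrix of detection coordinates (micrometers).
#' @param response LoG response at each detection.
#' @param intensity raw voxel intensity at each detection.
#' @param channel channel name or index.
#' @return a `spot_set`.
#' @export
spot_set <- function(coords_um, response = numeric(0),
                     intensity = numeric(0), channel = NA) {
  coords_um <- matrix(as.numeric(coords_um), ncol = 3)
  colnames(coords_um) <- c("x", "y", "z")
  structure(list(coords_um = coords_um, response = response,
                 intensity = intensity, channel = channel),
            class = "spot_set")
}

#' @export
print.spot_set <- function(x, ...) {
  cat(sprintf("spot_set: %d spots (channel %s)\n", nrow(x$coords_um),
              as.character(x$channel)))
  invisible(x)
}

#' @export
length.spot_set <- function(x) nrow(x$coords_um)

#' Detect spots in a 3D volume
#'
#' Local maxima of a scale-normalized Laplacian-of-Gaussian response at a
#' scale matched to the spot radius (sigma = radius / sqrt(3) per axis),
#' kept when the response exceeds the `intensity_percentile` of the
#' response distribution (over `mask` voxels when a mask is given,
#' otherwise the whole volume), then non-maximum-suppressed within one spot
#' radius. Coordinates are returned in micrometers (0-based voxel grid).
#'
#' @param x a [spot_image()] or a 3D numeric array.
#' @param channel channel name ("nuclei"/"transcript") or index; ignored
#'   for plain arrays.
#' @param spot_radius_um expected spot radius in micrometers; must be at
#'   least one voxel in every axis.
#' @param intensity_percentile response percentile for the detection
#'   threshold (default 99.5).
#' @param mask optional logical/integer 3D array restricting the threshold
#'   estimation (detections themselves are volume-wide).
#' @param voxel_size_um required when `x` is a plain array.
#' @return a [spot_set()].
#' @export
detect_spots <- function(x, channel = "transcript", spot_radius_um = 0.6,
                         intensity_percentile = 99.5, mask = NULL,
                         voxel_size_um = NULL) {
  if (inherits(x, "spot_image")) {
    ch <- if (is.character(channel)) x$channels[[channel]] else channel
    arr <- x$volume[, , , ch]
    vox <- x$voxel_size_um
  } else {
    arr <- x
    vox <- voxel_size_um
    if (is.null(vox))
      stop("voxel_size_um required for plain arrays", call. = FALSE)
  }
  check_triple(vox, "voxel_size_um", positive = TRUE)
  if (any(spot_radius_um < vox))
    stop(sprintf(paste0("spot radius %.3g um is under-resolved by the voxel",
                        " size (%.3g, %.3g, %.3g um); resample the volume",
                        " or increase the radius"),
                 spot_radius_um, vox[1], vox[2], vox[3]), call. = FALSE)
  sigma_um <- rep(spot_radius_um / sqrt(3), 3)
  resp <- log_response(arr, sigma_um, vox)
  pool <- if (is.null(mask)) resp else resp[mask > 0]
  thr <- stats::quantile(pool, intensity_percentile / 100, names = FALSE)
  cand <- which(local_maxima3(resp) & resp > pmax(thr, 0), arr.ind = TRUE)
  if (nrow(cand) == 0L)
    return(spot_set(matrix(numeric(0), 0, 3), channel = channel))
  rv <- resp[cand]
  um <- sweep(cand - 1, 2, vox, `*`)
  keep <- nms_points(um, rv, spot_radius_um)
  spot_set(um[keep, , drop = FALSE], response = rv[keep],
           intensity = arr[cand[keep, , drop = FALSE]], channel = channel)
}
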