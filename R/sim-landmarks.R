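#' Parameters for the heart-loop landmark simulator
#'
#' A stated world for E9.5 heart-loop geometry: a heart-tube polyline of
#' eight named landmarks built directly in the embryo frame so that the
#' right/left-ventricle axis angle, the normalized venous-pole offset and
#' the tube length equal the requested values exactly at zero noise.
#' Defaults describe a normal rightward loop: angle 0 degrees, venous pole
#' displaced 15% of the tube length to the left, 700 micrometer tube, 25
#' somites.
#'
#' @param rvlv_angle_deg true RV/LV axis angle, degrees in (-180, 180].
#' @param venous_offset_frac signed venous-pole offset as a fraction of
#'   tube length (left positive).
#' @param tube_length true tube length in micrometers.
#' @param noise_sd isotropic Gaussian landmark noise (micrometers).
#' @param rigid_jitter apply a random rotation + translation to the whole
#'   set (alignment must undo it).
#' @param somite_count somite stage (default 25; >= 18 passes QC).
#' @param seed integer seed.
#' @return a `landmark_sim_params` list.
#' @export
landmark_sim_params <- function(rvlv_angle_deg = 0, venous_offset_frac = 0.15,
                                tube_length = 700, noise_sd = 0,
                                rigid_jitter = FALSE, somite_count = 25,
                                seed = 1) {
  check_scalar(rvlv_angle_deg, "rvlv_angle_deg", lower = -180, upper = 180)
  if (rvlv_angle_deg <= -180)
    stop_field("rvlv_angle_deg", "must be in (-180, 180]")
  check_scalar(venous_offset_frac, "venous_offset_frac",
               lower = -0.45, upper = 0.45)
  check_scalar(tube_length, "tube_length", positive = TRUE)
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  stopifnot(is.logical(rigid_jitter), length(rigid_jitter) == 1L)
  check_scalar(somite_count, "somite_count", positive = TRUE,
               integerish = TRUE)
  check_scalar(seed, "seed", integerish = TRUE)
  structure(list(rvlv_angle_deg = rvlv_angle_deg,
                 venous_offset_frac = venous_offset_frac,
                 tube_length = tube_length, noise_sd = noise_sd,
                 rigid_jitter = rigid_jitter, somite_count = somite_count,
                 seed = seed),
            class = "landmark_sim_params")
}

random_rotation3 <- function() {
  ## uniform rotation via QR of a Gaussian matrix, det corrected to +1
  qrd <- qr(matrix(stats::rnorm(9), 3))
  q <- qr.Q(qrd)
  d <- diag(qr.R(qrd))
  q <- q %*% diag(sign(d))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Simulate a heart-loop landmark set
#'
#' Builds the eight heart-tube landmarks, five collinear notochord points
#' along Z (caudal-to-cranial order) and a ventral (+X) dorso-ventral
#' reference, realizing the requested angle, venous offset and tube length
#' exactly; then adds isotropic Gaussian noise and, optionally, a random
#' rigid motion of the whole set.
#'
#' @param params a [landmark_sim_params()] object.
#' @return list with `landmarks` (a [landmark_set()]) and `truth`
#'   (`ground_truth`: the requested angle/offset/length, the noise-free
#'   aligned-frame coordinates, the applied rigid motion).
#' @export
simulate_landmarks <- function(params = landmark_sim_params()) {
  if (!inherits(params, "landmark_sim_params"))
    params <- do.call(landmark_sim_params, as.list(params))
  p <- params
  L <- p$tube_length
  theta <- p$rvlv_angle_deg * pi / 180
  d_vent <- 0.25                       # inter-ventricle distance, frac of L

  ## template (unit tube scale); RV/LV around a transverse midpoint M
  template <- function(scale, vy) {
    M <- c(0.30, 0, 0.15) * scale
    half <- d_vent * scale / 2 * c(sin(theta), cos(theta), 0)
    pts <- rbind(
      outflow_exit            = c(0.10, 0.00, 0.40) * scale,
      OFT                     = c(0.25, -0.05, 0.30) * scale,
      RV                      = M - half,
      interventricular_sulcus = M + c(0.08, 0, 0) * scale,
      LV                      = M + half,
      AVC_LA                  = c(0.22, 0.08, -0.05) * scale,
      RA                      = c(0.15, -0.05, -0.15) * scale,
      venous_pole             = c(0.05, vy, -0.30) * scale
    )
    pts["venous_pole", 2] <- vy
    pts
  }
  polyline_len <- function(pts) {
    seg <- diff(pts[HEART_LANDMARKS, , drop = FALSE])
    sum(sqrt(rowSums(seg^2)))
  }
  ## fixed-point iteration: scale to hit tube length while pinning the
  ## venous-pole Y offset at venous_offset_frac * L
  scale <- L
  vy <- p$venous_offset_frac * L
  for (i in 1:60) {
    pts <- template(scale, vy)
    len <- polyline_len(pts)
    if (abs(len - L) < 1e-10 * L) break
    scale <- scale * L / len
  }
  noto <- cbind(0, 0, seq(-0.45, 0.55, length.out = 5) * L)  # caudal first
  dvref <- c(0.5 * L, 0, 0)

  truth_pts <- pts
  with_seed(p$seed, {
    if (p$noise_sd > 0) {
      pts <- pts + matrix(stats::rnorm(length(pts), 0, p$noise_sd),
                          nrow(pts))
      noto <- noto + matrix(stats::rnorm(length(noto), 0, p$noise_sd),
                            nrow(noto))
      dvref <- dvref + stats::rnorm(3, 0, p$noise_sd)
    }
    rot <- diag(3); trans <- c(0, 0, 0)
    if (p$rigid_jitter) {
      rot <- random_rotation3()
      trans <- stats::runif(3, -L, L)
      pts <- pts %*% t(rot) + matrix(trans, nrow(pts), 3, byrow = TRUE)
      noto <- noto %*% t(rot) + matrix(trans, nrow(noto), 3, byrow = TRUE)
      dvref <- as.numeric(rot %*% dvref + trans)
      rownames(pts) <- rownames(truth_pts)
    }
    lms <- landmark_set(pts, noto, dvref, somite_count = p$somite_count,
                        embryo_id = sprintf("sim%06d", p$seed))
    truth <- structure(list(
      kind = "landmarks",
      rvlv_angle_deg = p$rvlv_angle_deg,
      venous_offset_frac = p$venous_offset_frac,
      tube_length = L,
      aligned_points = truth_pts,
      rotation = rot, translation = trans,
      params = unclass(p)
    ), class = "ground_truth")
    list(landmarks = lms, truth = truth)
  })
}
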