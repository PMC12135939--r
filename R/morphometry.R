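## Landmark-based heart-loop morphometry.
##
## Frame convention (fixed here and anchored by tests, since the printed
## figures do not restate it): after alignment, +Z is the notochord axis
## pointing cranially, +X points ventrally (the dorso-ventral reference
## lies in the +X half-plane) and +Y completes a right-handed frame and is
## the embryo's left. The RV/LV angle is the signed angle in the transverse
## (XY) plane from the +Y (leftward) axis to the vector RV -> LV, positive
## counter-clockwise when viewed from cranial; a normal rightward loop (RV
## on the embryo's right, LV on its left) reads 0 degrees.

HEART_LANDMARKS <- c("outflow_exit", "OFT", "RV", "interventricular_sulcus",
                     "LV", "AVC_LA", "RA", "venous_pole")

#' Construct a landmark set
#'
#' @param points numeric matrix (rows = landmarks, columns x/y/z in
#'   micrometers) with rownames covering all eight heart-tube landmarks:
#'   `r paste(HEART_LANDMARKS, collapse = ", ")`.
#' @param notochord_points matrix of >= 2 points along the notochord,
#'   ordered caudal to cranial.
#' @param dorsoventral_ref single ventral-side reference point.
#' @param somite_count somite number of the embryo (NA = unknown).
#' @param embryo_id,genotype metadata strings.
#' @param aligned internal flag: TRUE once in the embryo frame.
#' @return a `landmark_set`.
#' @export
landmark_set <- function(points, notochord_points, dorsoventral_ref,
                         somite_count = NA_integer_, embryo_id = "embryo",
                         genotype = "WT", aligned = FALSE) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must be n x 3", call. = FALSE)
  colnames(points) <- c("x", "y", "z")
  miss <- setdiff(HEART_LANDMARKS, rownames(points))
  if (length(miss))
    stop("missing landmark(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  notochord_points <- as.matrix(notochord_points)
  if (nrow(notochord_points) < 2L || ncol(notochord_points) != 3L)
    stop("need >= 2 notochord points (n x 3)", call. = FALSE)
  dimnames(notochord_points) <- list(NULL, c("x", "y", "z"))
  if (max(stats::dist(notochord_points)) < 1e-9)
    stop("notochord points are all coincident", call. = FALSE)
  dorsoventral_ref <- as.numeric(dorsoventral_ref)
  if (length(dorsoventral_ref) != 3L)
    stop("dorsoventral_ref must be a 3-vector", call. = FALSE)
  structure(list(points = points, notochord_points = notochord_points,
                 dorsoventral_ref = dorsoventral_ref,
                 somite_count = somite_count, embryo_id = embryo_id,
                 genotype = genotype, aligned = isTRUE(aligned)),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("landmark_set '%s' (%s): %d landmarks, %d notochord points, %s somites%s\n",
              x$embryo_id, x$genotype, nrow(x$points),
              nrow(x$notochord_points),
              if (is.na(x$somite_count)) "?" else x$somite_count,
              if (x$aligned) ", aligned" else ""))
  invisible(x)
}

normalize3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("degenerate direction vector", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Align a landmark set to the embryo frame
#'
#' Rigid transform taking the total-least-squares notochord line to the Z
#' axis (cranial positive; orientation from the hemisphere containing the
#' outflow exit — order-free — falling back to the caudal-to-cranial
#' ordering of the notochord points when the outflow exit sits on the
#' transverse plane) and the dorso-ventral reference into the +X half-plane;
#' +Y then points to the embryo's left. Samples with fewer than 18 somites
#' (or unknown somite count, unless `require_somites = FALSE`) are rejected
#' as a staging quality-control failure.
#'
#' @param lm a [landmark_set()].
#' @param min_somites QC threshold (default 18).
#' @param require_somites reject when somite count is unknown (default
#'   TRUE).
#' @return the aligned `landmark_set`.
#' @export
align_to_embryo_frame <- function(lm, min_somites = 18,
                                  require_somites = TRUE) {
  stopifnot(inherits(lm, "landmark_set"))
  if (is.na(lm$somite_count)) {
    if (require_somites)
      stop("QC rejection: somite count unknown for '", lm$embryo_id,
           "'; morphometry requires staged embryos", call. = FALSE)
  } else if (lm$somite_count < min_somites) {
    stop(sprintf("QC rejection: embryo '%s' has %d somites (< %d)",
                 lm$embryo_id, lm$somite_count, min_somites), call. = FALSE)
  }
  np <- lm$notochord_points
  ctr <- colMeans(np)
  sv <- svd(sweep(np, 2, ctr))
  if (sv$d[1] < 1e-9 || (nrow(np) > 2 && sv$d[1] < 1e6 * .Machine$double.eps))
    stop("degenerate notochord: no well-defined axis", call. = FALSE)
  z <- sv$v[, 1]
  ## orient cranially: outflow-exit hemisphere (independent of the order
  ## notochord points were clicked in), ordering metadata as fallback
  oe <- sum((lm$points["outflow_exit", ] - ctr) * z)
  if (abs(oe) > 1e-9) {
    if (oe < 0) z <- -z
  } else {
    ord <- sum((np[nrow(np), ] - np[1, ]) * z)
    if (ord < 0) z <- -z
  }
  dv <- lm$dorsoventral_ref - ctr
  x <- dv - sum(dv * z) * z
  x <- normalize3(x)
  y <- cross3(z, x)
  rot <- cbind(x, y, z)                     # columns: new axes in old coords
  tf <- function(p) {
    p <- sweep(matrix(p, ncol = 3), 2, ctr)
    p %*% rot
  }
  out <- lm
  out$points <- tf(lm$points)
  rownames(out$points) <- rownames(lm$points)
  out$notochord_points <- tf(lm$notochord_points)
  out$dorsoventral_ref <- as.numeric(tf(lm$dorsoventral_ref))
  out$aligned <- TRUE
  out
}

check_aligned <- function(lm) {
  stopifnot(inherits(lm, "landmark_set"))
  if (!lm$aligned)
    stop("landmark set must be aligned first (align_to_embryo_frame)",
         call. = FALSE)
  lm
}

#' Signed RV/LV axis angle
#'
#' Projects the right- and left-ventricle centroids onto the transverse
#' (XY) plane and returns the signed angle (degrees, in (-180, 180]) from
#' the +Y leftward axis to the vector RV -> LV, counter-clockwise positive
#' viewed from cranial. 0 degrees is a normal rightward loop.
#'
#' @param aligned an aligned [landmark_set()].
#' @param tol projections closer than this (micrometers) are indeterminate
#'   (returns NA).
#' @return angle in degrees, or NA when indeterminate.
#' @export
rvlv_axis_angle <- function(aligned, tol = 1e-9) {
  lm <- check_aligned(aligned)
  v <- lm$points["LV", 1:2] - lm$points["RV", 1:2]
  if (sqrt(sum(v^2)) < tol) return(NA_real_)
  ang <- atan2(v[1], v[2]) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  unname(ang)
}

#' Heart-tube length
#'
#' Sum of Euclidean segment lengths along the ordered landmark polyline
#' outflow_exit -> OFT -> RV -> interventricular_sulcus -> LV -> AVC_LA ->
#' RA -> venous_pole.
#'
#' @param aligned an aligned [landmark_set()].
#' @return length in micrometers.
#' @export
tube_length <- function(aligned) {
  lm <- check_aligned(aligned)
  p <- lm$points[HEART_LANDMARKS, , drop = FALSE]
  seg <- diff(p)
  sum(sqrt(rowSums(seg^2)))
}

#' Normalized venous-pole displacement
#'
#' Signed left-right (Y, left positive) coordinate of the venous pole,
#' divided by the tube length. Positive values mean a leftward-displaced
#' venous pole, the normal situation during rightward looping.
#'
#' @param aligned an aligned [landmark_set()].
#' @return dimensionless signed real.
#' @export
venous_pole_displacement <- function(aligned) {
  lm <- check_aligned(aligned)
  len <- tube_length(lm)
  if (len <= 0) stop("zero tube length", call. = FALSE)
  unname(lm$points["venous_pole", 2] / len)
}

#' Looping direction call
#'
#' Rightward iff the right ventricle lies on the embryo's right of the left
#' ventricle (Y(RV) - Y(LV) < 0); leftward iff the opposite; indeterminate
#' when the left-right offset is below `tol` micrometers.
#'
#' @param aligned an aligned [landmark_set()].
#' @param tol indeterminate tolerance in micrometers (default 1).
#' @return one of "rightward", "leftward", "indeterminate".
#' @export
looping_direction <- function(aligned, tol = 1) {
  lm <- check_aligned(aligned)
  dy <- unname(lm$points["RV", 2] - lm$points["LV", 2])
  if (abs(dy) < tol) "indeterminate"
  else if (dy < 0) "rightward"
  else "leftward"
}

#' All loop metrics for one aligned embryo
#'
#' @param aligned an aligned [landmark_set()].
#' @return a `loop_metrics` list: `rvlv_angle_deg`,
#'   `venous_displacement_norm`, `tube_length`, `direction`.
#' @export
loop_metrics <- function(aligned) {
  lm <- check_aligned(aligned)
  structure(list(
    embryo_id = lm$embryo_id,
    genotype = lm$genotype,
    rvlv_angle_deg = rvlv_axis_angle(lm),
    venous_displacement_norm = venous_pole_displacement(lm),
    tube_length = tube_length(lm),
    direction = looping_direction(lm)
  ), class = "loop_metrics")
}

#' Looping-direction frequency test
#'
#' 1-df chi-squared goodness-of-fit with Yates' continuity correction of an
#' observed rightward/other split against an expected rightward proportion
#' (0.5 = randomized looping direction).
#'
#' @param n_rightward number of rightward loops observed.
#' @param n_total total embryos (>= 1).
#' @param expected_prop expected rightward proportion (default 0.5).
#' @return a `stat_result`.
#' @export
direction_frequency_test <- function(n_rightward, n_total,
                                     expected_prop = 0.5) {
  check_scalar(n_total, "n_total", positive = TRUE, integerish = TRUE)
  check_scalar(n_rightward, "n_rightward", nonneg = TRUE, integerish = TRUE)
  if (n_rightward > n_total)
    stop("n_rightward exceeds n_total", call. = FALSE)
  chi_squared_gof(c(n_rightward, n_total - n_rightward),
                  c(expected_prop, 1 - expected_prop), yates = TRUE)
}
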