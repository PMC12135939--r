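## Left/right quantification of spot images: midline bisection, Hoechst
## side-normalization and the normalized log2 left/right enrichment ratio.

#' Bisect a labeled region at the midline
#'
#' Partitions the voxels of one labeled region by the sign of the midline
#' plane equation evaluated at each voxel center: nonnegative values
#' (including voxels exactly on the plane, the documented tie-break) go to
#' the left half, negative to the right. Left and right are disjoint and
#' their union is the region.
#'
#' @param region_mask 3D integer label array.
#' @param label label value of the region to bisect.
#' @param midline_plane numeric(4) plane coefficients (micrometer
#'   coordinates, positive side = left).
#' @param voxel_size_um positive triple.
#' @return list with logical arrays `left`, `right` and a logical
#'   `one_side_empty` flag.
#' @export
bisect_mask_by_midline <- function(region_mask, label, midline_plane,
                                   voxel_size_um) {
  if (length(midline_plane) != 4L || all(abs(midline_plane[1:3]) < 1e-12))
    stop("degenerate midline plane", call. = FALSE)
  check_triple(voxel_size_um, "voxel_size_um", positive = TRUE)
  inreg <- region_mask == label
  if (!any(inreg)) stop("region label ", label, " is empty", call. = FALSE)
  pv <- plane_value_array(dim(region_mask), voxel_size_um, midline_plane)
  left <- inreg & pv >= 0
  right <- inreg & pv < 0
  list(left = left, right = right,
       one_side_empty = !any(left) || !any(right))
}

## Count spot-set detections whose containing voxel lies in a logical mask.
count_in_mask <- function(spots, mask, voxel_size_um) {
  if (length(spots) == 0L) return(0L)
  idx <- round(sweep(spots$coords_um, 2, voxel_size_um, `/`)) + 1
  d <- dim(mask)
  idx <- pmin(pmax(idx, 1), matrix(d, nrow(idx), 3, byrow = TRUE))
  sum(mask[matrix(as.integer(idx), ncol = 3)])
}

#' Hoechst side-normalization score
#'
#' Detects nuclear-scale candidate maxima on the Hoechst channel, then, on
#' each side separately, keeps the candidates above the highest threshold
#' retaining at least `coverage` (default 50%) of that side's candidates.
#' The score is H_L / H_R of the retained counts. Because thresholding is
#' per side (relative to each side's own response distribution), a
#' one-sided multiplicative intensity bias cancels out of the score.
#'
#' Interpretation note: the "coverage of 50% of spots on each side" rule of
#' the upstream acquisition software is not published; this function is the
#' single place holding our reading (per-side candidate maxima,
#' non-maximum-suppressed within one nuclear radius, a weak per-side
#' relative response floor of `rel_floor` x the side's maximum response to
#' exclude background ripples, then per-side 50% retention). Candidates
#' within one nuclear radius of the midline plane are excluded on both
#' sides: a side-to-side intensity step at the midline produces a
#' blob-scale edge ridge there that would otherwise be counted as nuclei
#' on the brighter side.
#'
#' @param image a [spot_image()].
#' @param left_mask,right_mask logical arrays from
#'   [bisect_mask_by_midline()].
#' @param nuclear_radius_um nuclear blob radius (default 3.5 micrometers,
#'   matching a sigma-2-micrometer nucleus).
#' @param coverage per-side retained fraction (default 0.5).
#' @param rel_floor relative response floor for candidates (default 0.1).
#' @return list with `score` (= H_L / H_R), `H_L`, `H_R`.
#' @export
hoechst_normalization_score <- function(image, left_mask, right_mask,
                                        nuclear_radius_um = 3.5,
                                        coverage = 0.5, rel_floor = 0.1) {
  stopifnot(inherits(image, "spot_image"))
  arr <- image$volume[, , , image$channels[["nuclei"]]]
  vox <- image$voxel_size_um
  sigma_um <- rep(nuclear_radius_um / sqrt(3), 3)
  resp <- log_response(arr, sigma_um, vox)
  is_max <- local_maxima3(resp) & resp > 0
  plane <- image$midline_plane
  plane_dist <- function(um)
    abs(um %*% plane[1:3] + plane[4]) / sqrt(sum(plane[1:3]^2))
  side_count <- function(side_mask) {
    idx <- which(is_max & side_mask, arr.ind = TRUE)
    if (nrow(idx) == 0L) return(0L)
    r <- resp[idx]
    um <- sweep(idx - 1, 2, vox, `*`)
    ok <- r >= rel_floor * max(r, 0) & plane_dist(um) > nuclear_radius_um
    um <- um[ok, , drop = FALSE]; r <- r[ok]
    if (length(r) == 0L) return(0L)
    r <- r[nms_points(um, r, nuclear_radius_um)]
    n <- length(r)
    thr <- sort(r, decreasing = TRUE)[ceiling(coverage * n)]
    sum(r >= thr)
  }
  h_l <- side_count(left_mask)
  h_r <- side_count(right_mask)
  if (h_r == 0L)
    stop("no nuclei detected on the right side; normalization score undefined",
         call. = FALSE)
  list(score = h_l / h_r, H_L = h_l, H_R = h_r)
}

#' Left/right asymmetry measurement for one region
#'
#' The full per-embryo quantification: transcript spots are detected and
#' counted per side (S_L, S_R), nuclei are counted per side via the Hoechst
#' normalization (H_L, H_R), side volumes come from voxel counts (V_L,
#' V_R), and the enrichment ratio is
#' log2\[ (S_L / (H_L V_L)) / (S_R / (H_R V_R)) \]. All components are
#' stored so alternative normalizations can be recomputed.
#'
#' @param image a [spot_image()].
#' @param region region name in `image$region_labels` (default
#'   "heart_field").
#' @param spot_radius_um transcript spot radius (default 0.6).
#' @param intensity_percentile detection threshold percentile (default 99.5).
#' @param nuclear_radius_um nuclear blob radius (default 3.5).
#' @return an `asym_measurement`: embryo_id, stage, region, S_L, S_R, H_L,
#'   H_R, V_L, V_R, norm_score, log2_ratio, valid, reason.
#' @export
lr_asymmetry <- function(image, region = "heart_field",
                         spot_radius_um = 0.6, intensity_percentile = 99.5,
                         nuclear_radius_um = 3.5) {
  stopifnot(inherits(image, "spot_image"))
  if (!region %in% names(image$region_labels))
    stop("unknown region '", region, "'", call. = FALSE)
  label <- image$region_labels[[region]]
  halves <- bisect_mask_by_midline(image$region_mask, label,
                                   image$midline_plane,
                                   image$voxel_size_um)
  voxvol <- prod(image$voxel_size_um)
  v_l <- sum(halves$left) * voxvol
  v_r <- sum(halves$right) * voxvol

  spots <- detect_spots(image, channel = "transcript",
                        spot_radius_um = spot_radius_um,
                        intensity_percentile = intensity_percentile,
                        mask = image$region_mask == label)
  s_l <- count_in_mask(spots, halves$left, image$voxel_size_um)
  s_r <- count_in_mask(spots, halves$right, image$voxel_size_um)

  valid <- TRUE; reason <- ""
  h_l <- h_r <- NA_real_; score <- NA_real_; ratio <- NA_real_
  if (v_l == 0 || v_r == 0) {
    valid <- FALSE; reason <- "empty side after bisection"
  } else {
    hs <- tryCatch(
      hoechst_normalization_score(image, halves$left, halves$right,
                                  nuclear_radius_um = nuclear_radius_um),
      error = function(e) NULL)
    if (is.null(hs)) {
      valid <- FALSE; reason <- "Hoechst normalization undefined"
    } else {
      h_l <- hs$H_L; h_r <- hs$H_R; score <- hs$score
      if (s_r == 0 || h_l == 0) {
        valid <- FALSE
        reason <- if (s_r == 0) "no right-side transcript spots"
                  else "no left-side nuclei"
      } else {
        ratio <- log2((s_l / (h_l * v_l)) / (s_r / (h_r * v_r)))
      }
    }
  }
  structure(list(embryo_id = image$embryo_id, stage = image$stage,
                 genotype = image$genotype, region = region,
                 S_L = s_l, S_R = s_r, H_L = h_l, H_R = h_r,
                 V_L = v_l, V_R = v_r, norm_score = score,
                 log2_ratio = ratio, valid = valid, reason = reason),
            class = "asym_measurement")
}

#' @export
print.asym_measurement <- function(x, ...) {
  cat(sprintf(
    "asym_measurement '%s' (%s, %s): S %d/%d, H %s/%s, log2 L/R = %s\n",
    x$embryo_id, x$stage, x$region, x$S_L, x$S_R,
    as.character(x$H_L), as.character(x$H_R),
    if (is.na(x$log2_ratio)) paste0("invalid (", x$reason, ")")
    else sprintf("%.3f", x$log2_ratio)))
  invisible(x)
}

#' Stage profile of asymmetry measurements
#'
#' Aggregates per-embryo log2 left/right ratios by grouping keys (default
#' stage and genotype): per group, mean, SD and n, plus a signed-rank test
#' of the symmetry hypothesis (log2 ratio = 0); when a stage has two or
#' more genotypes, pairwise Mann-Whitney tests between genotypes are added.
#' A Benjamini-Hochberg correction is applied across the whole reported
#' family of p-values.
#'
#' @param measurements list of `asym_measurement`s (invalid ones are
#'   dropped with a warning).
#' @param group_keys character, grouping fields (default c("stage",
#'   "genotype")).
#' @return list with `summary` (per-group data.frame) and `tests`
#'   (data.frame: group, comparison, statistic, p_value, bh_adjusted_p).
#' @export
stage_profile <- function(measurements, group_keys = c("stage", "genotype")) {
  rows <- lapply(measurements, function(m)
    data.frame(embryo_id = m$embryo_id, stage = m$stage,
               genotype = m$genotype, region = m$region,
               log2_ratio = m$log2_ratio, valid = m$valid,
               stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  if (any(!df$valid)) {
    warning(sum(!df$valid), " invalid measurement(s) dropped")
    df <- df[df$valid, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no valid measurements", call. = FALSE)
  df$group <- do.call(paste, c(df[group_keys], sep = ":"))

  groups <- split(df, df$group)
  summary <- do.call(rbind, lapply(groups, function(g)
    data.frame(group = g$group[1],
               mean_log2_ratio = mean(g$log2_ratio),
               sd_log2_ratio = stats::sd(g$log2_ratio),
               n = nrow(g), stringsAsFactors = FALSE)))
  rownames(summary) <- NULL

  tests <- do.call(rbind, lapply(groups, function(g) {
    res <- wilcoxon_signed_rank_vs_zero(g$log2_ratio)
    data.frame(group = g$group[1], comparison = "symmetry (log2 = 0)",
               statistic = res$statistic, p_value = res$p_value,
               stringsAsFactors = FALSE)
  }))
  if ("genotype" %in% group_keys) {
    for (st in unique(df$stage)) {
      sub <- df[df$stage == st, , drop = FALSE]
      gts <- sort(unique(sub$genotype))
      if (length(gts) >= 2) {
        prs <- utils::combn(gts, 2, simplify = FALSE)
        for (pr in prs) {
          res <- mann_whitney_u(sub$log2_ratio[sub$genotype == pr[1]],
                                sub$log2_ratio[sub$genotype == pr[2]])
          tests <- rbind(tests, data.frame(
            group = st, comparison = paste(pr, collapse = " vs "),
            statistic = res$statistic, p_value = res$p_value,
            stringsAsFactors = FALSE))
        }
      }
    }
  }
  tests$bh_adjusted_p <- bh_adjust(tests$p_value)
  rownames(tests) <- NULL
  list(summary = summary, tests = tests)
}
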