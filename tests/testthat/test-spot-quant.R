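test_that("midline bisection: tie-break, empty side flag, random oracle", {
  mask <- array(0L, c(10, 8, 6))
  mask[3:8, 2:7, 2:5] <- 1L
  vox <- c(1, 1, 1)
  # plane through voxel centers at x = 5 (0-based um coordinate 4)
  halves <- bisect_mask_by_midline(mask, 1L, c(1, 0, 0, -4), vox)
  # on-plane voxels go left
  expect_true(all(halves$left[5, 2:7, 2:5]))
  expect_false(halves$one_side_empty)
  expect_equal(halves$left | halves$right, mask == 1L)
  expect_false(any(halves$left & halves$right))

  out <- bisect_mask_by_midline(mask, 1L, c(1, 0, 0, 100), vox)
  expect_true(out$one_side_empty)

  set.seed(61)
  rnd <- array(rbinom(480, 1, 0.4), c(10, 8, 6))
  pl <- c(0.5, -1, 0.25, -2)
  h <- bisect_mask_by_midline(rnd, 1L, pl, vox)
  val <- asymscreen:::plane_value_array(dim(rnd), vox, pl)
  expect_equal(h$left, rnd == 1L & val >= 0)
  expect_equal(h$right, rnd == 1L & val < 0)

  expect_error(bisect_mask_by_midline(mask, 1L, c(0, 0, 0, 1), vox),
               "degenerate")
  expect_error(bisect_mask_by_midline(mask, 7L, c(1, 0, 0, -4), vox),
               "empty")
})

test_that("Hoechst score: symmetric nuclei give 1, bias cancels", {
  # a mid-sized world: nuclei well separated so the score is stable
  mid <- function(...) image_sim_params(shape_voxels = c(96, 96, 48),
                                        n_nuclei_per_side = c(40, 40),
                                        spot_density_right = 0.01, ...)
  scores <- scores_biased <- numeric(3)
  for (s in 1:3) {
    sim <- simulate_embryo_image(mid(seed = s))
    img <- sim$image
    h <- bisect_mask_by_midline(img$region_mask, 1, img$midline_plane,
                                img$voxel_size_um)
    scores[s] <- hoechst_normalization_score(img, h$left, h$right)$score

    simb <- simulate_embryo_image(mid(side_intensity_bias = 1.5, seed = s))
    hb <- bisect_mask_by_midline(simb$image$region_mask, 1,
                                 simb$image$midline_plane,
                                 simb$image$voxel_size_um)
    scores_biased[s] <- hoechst_normalization_score(simb$image, hb$left,
                                                    hb$right)$score
  }
  expect_lt(abs(mean(scores) - 1), 0.2)
  expect_lt(abs(mean(scores_biased) - 1), 0.2)
})

test_that("Hoechst score tracks a doubled left nucleus count", {
  scores <- numeric(3)
  for (s in 1:3) {
    sim <- simulate_embryo_image(image_sim_params(
      shape_voxels = c(96, 96, 48), n_nuclei_per_side = c(50, 25),
      spot_density_right = 0.01, seed = s))
    img <- sim$image
    h <- bisect_mask_by_midline(img$region_mask, 1, img$midline_plane,
                                img$voxel_size_um)
    scores[s] <- hoechst_normalization_score(img, h$left, h$right)$score
  }
  expect_lt(abs(mean(scores) - 2) / 2, 0.25)
})

test_that("lr_asymmetry stores all components and flags failures", {
  sim <- simulate_embryo_image(small_image_params(seed = 2))
  m <- lr_asymmetry(sim$image)
  expect_true(m$valid)
  expect_true(is.finite(m$log2_ratio))
  expect_equal(m$V_L, m$V_R)
  expect_equal(m$log2_ratio,
               log2((m$S_L / (m$H_L * m$V_L)) / (m$S_R / (m$H_R * m$V_R))))
  expect_equal(m$norm_score, m$H_L / m$H_R)

  # plane outside the region: one side empty -> invalid with a reason
  off <- sim$image
  off$midline_plane <- c(1, 0, 0, 1)
  m0 <- lr_asymmetry(off)
  expect_false(m0$valid)
  expect_match(m0$reason, "empty side")
  expect_error(lr_asymmetry(sim$image, region = "node"), "unknown region")
})

test_that("mirroring the volume across the midline negates the ratio", {
  sim <- simulate_embryo_image(small_image_params(
    lr_fold = 2.5, noise_model = "gaussian", gaussian_sd = 0, seed = 4))
  img <- sim$image
  flip <- function(a) a[dim(a)[1]:1, , , drop = FALSE]
  mimg <- img
  mimg$volume <- array(0, dim(img$volume))
  mimg$volume[, , , 1] <- flip(img$volume[, , , 1])
  mimg$volume[, , , 2] <- flip(img$volume[, , , 2])
  mimg$region_mask <- img$region_mask[dim(img$region_mask)[1]:1, , ]
  m <- lr_asymmetry(img)
  mm <- lr_asymmetry(mimg)
  expect_equal(mm$S_L, m$S_R)
  expect_equal(mm$S_R, m$S_L)
  expect_lt(abs(m$log2_ratio + mm$log2_ratio), 1e-6)
})

test_that("stage profile: exact symmetric null and enumeration p-values", {
  ms <- lapply(1:6, function(i) make_meas(0, embryo_id = paste0("e", i)))
  out <- stage_profile(ms)
  expect_equal(out$summary$mean_log2_ratio, 0)
  expect_equal(out$summary$n, 6)
  expect_equal(out$tests$p_value[1], 1)

  pos <- lapply(1:6, function(i) make_meas(0.8, embryo_id = paste0("e", i)))
  out2 <- stage_profile(pos)
  expect_equal(out2$tests$p_value[1], 2 / 2^6)
})

test_that("stage profile: groups, genotype comparisons, BH family", {
  ms <- c(
    lapply(1:5, function(i) make_meas(0.9 + 0.01 * i, stage = "E8.5d",
                                      genotype = "WT",
                                      embryo_id = paste0("w", i))),
    lapply(1:5, function(i) make_meas(0.05 * i - 0.2, stage = "E8.5d",
                                      genotype = "mutant",
                                      embryo_id = paste0("m", i))),
    lapply(1:3, function(i) make_meas(0.2, stage = "E8.5c",
                                      genotype = "WT",
                                      embryo_id = paste0("c", i))))
  out <- stage_profile(ms)
  expect_equal(nrow(out$summary), 3)
  expect_equal(sum(out$summary$n), 13)
  # one between-genotype comparison at E8.5d
  mw <- out$tests[out$tests$comparison == "WT vs mutant", ]
  expect_equal(nrow(mw), 1)
  expect_equal(mw$p_value,
               mann_whitney_u(c(0.91, 0.92, 0.93, 0.94, 0.95),
                              c(-0.15, -0.1, -0.05, 0, 0.05))$p_value)
  expect_equal(out$tests$bh_adjusted_p, bh_adjust(out$tests$p_value))

  # invalid measurements are dropped with a warning
  ms2 <- c(ms, list(make_meas(NA_real_)))
  expect_warning(stage_profile(ms2), "invalid")
})
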