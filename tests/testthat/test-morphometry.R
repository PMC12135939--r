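# build an already-in-frame landmark set (notochord on Z, ventral ref +X)
frame_set <- function(points, somites = 25) {
  landmark_set(points,
               notochord_points = cbind(0, 0, seq(-350, 350, length.out = 5)),
               dorsoventral_ref = c(350, 0, 0),
               somite_count = somites)
}

base_points <- function(rv = c(0, -100, 100), lv = c(0, 100, 100),
                        venous = c(30, 80, -200)) {
  rbind(outflow_exit = c(60, 0, 280),
        OFT = c(170, -30, 210),
        RV = rv,
        interventricular_sulcus = c(230, 0, 105),
        LV = lv,
        AVC_LA = c(150, 55, -40),
        RA = c(100, -35, -110),
        venous_pole = venous)
}

test_that("convention anchors: RV right of LV reads 0 degrees, rightward", {
  lm <- align_to_embryo_frame(frame_set(base_points()))
  expect_equal(rvlv_axis_angle(lm), 0, tolerance = 1e-9)
  expect_equal(looping_direction(lm), "rightward")

  # mirrored (Y negated everywhere): +/-180 degrees, leftward
  pts <- base_points(); pts[, 2] <- -pts[, 2]
  ls <- frame_set(pts)
  ls$notochord_points[, 2] <- -ls$notochord_points[, 2]
  mlm <- align_to_embryo_frame(ls)
  expect_equal(abs(rvlv_axis_angle(mlm)), 180, tolerance = 1e-9)
  expect_equal(looping_direction(mlm), "leftward")
  expect_equal(venous_pole_displacement(mlm), -venous_pole_displacement(lm),
               tolerance = 1e-12)
})

test_that("rotating landmarks about Z (frame fixed) shifts the angle by -a", {
  lm0 <- frame_set(base_points())
  a0 <- rvlv_axis_angle(align_to_embryo_frame(lm0))
  th <- 30 * pi / 180
  rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  lm1 <- lm0
  lm1$points <- lm0$points %*% t(rz)   # rotate hearts, not the frame
  rownames(lm1$points) <- rownames(lm0$points)
  a1 <- rvlv_axis_angle(align_to_embryo_frame(lm1))
  expect_equal(a1, a0 - 30, tolerance = 1e-9)
})

test_that("tube length: collinear chain and isometry", {
  pts <- base_points()
  pts[] <- 0
  pts[, 3] <- 7:0          # 8 collinear landmarks spaced 1 um
  pts[, 1] <- 1e-6         # off the notochord axis to keep angle defined
  lm <- align_to_embryo_frame(frame_set(pts))
  expect_equal(tube_length(lm), 7, tolerance = 1e-9)

  # brute-force segment sum on a random chain
  set.seed(41)
  rnd <- base_points() + matrix(rnorm(24, 0, 10), 8)
  lm2 <- align_to_embryo_frame(frame_set(rnd))
  ord <- c("outflow_exit", "OFT", "RV", "interventricular_sulcus", "LV",
           "AVC_LA", "RA", "venous_pole")
  brute <- sum(sqrt(rowSums(diff(lm2$points[ord, ])^2)))
  expect_equal(tube_length(lm2), brute)
})

test_that("venous-pole displacement: closed form and null case", {
  lm <- align_to_embryo_frame(frame_set(base_points()))
  expect_equal(venous_pole_displacement(lm),
               lm$points["venous_pole", 2] / tube_length(lm))
  on_axis <- base_points(venous = c(0, 0, -200))
  lm0 <- align_to_embryo_frame(frame_set(on_axis))
  expect_equal(venous_pole_displacement(lm0), 0, tolerance = 1e-12)
})

test_that("looping direction tolerance band", {
  near <- base_points(rv = c(0, -0.4, 100), lv = c(0, 0.4, 100))
  lm <- align_to_embryo_frame(frame_set(near))
  expect_equal(looping_direction(lm), "indeterminate")
  expect_equal(looping_direction(lm, tol = 0.1), "rightward")
})

test_that("somite staging QC rejects young or unstaged embryos", {
  expect_error(align_to_embryo_frame(frame_set(base_points(), somites = 17)),
               "QC rejection.*17 somites")
  expect_error(align_to_embryo_frame(frame_set(base_points(),
                                               somites = NA_integer_)),
               "somite count unknown")
  expect_s3_class(align_to_embryo_frame(frame_set(base_points(),
                                                  somites = NA_integer_),
                                        require_somites = FALSE),
                  "landmark_set")
})

test_that("alignment: identity on in-frame sets, order-free notochord", {
  lm <- frame_set(base_points())
  al <- align_to_embryo_frame(lm)
  expect_equal(al$points, lm$points, tolerance = 1e-9)

  rev_noto <- lm
  rev_noto$notochord_points <- lm$notochord_points[5:1, ]
  al2 <- align_to_embryo_frame(rev_noto)
  expect_equal(al2$points, al$points, tolerance = 1e-9)

  degen <- lm
  degen$notochord_points <- matrix(c(0, 0, 0, 1e-12, 0, 0), 2, 3,
                                   byrow = TRUE)
  expect_error(landmark_set(degen$points, degen$notochord_points,
                            degen$dorsoventral_ref), "coincident")
})

test_that("metrics are rigid-motion invariant (100 random motions)", {
  truth <- simulate_landmarks(landmark_sim_params(
    rvlv_angle_deg = -40, venous_offset_frac = 0.2, seed = 1))
  ref <- loop_metrics(align_to_embryo_frame(truth$landmarks))
  for (s in 1:100) {
    jit <- simulate_landmarks(landmark_sim_params(
      rvlv_angle_deg = -40, venous_offset_frac = 0.2, rigid_jitter = TRUE,
      seed = s))
    m <- loop_metrics(align_to_embryo_frame(jit$landmarks))
    expect_equal(m$rvlv_angle_deg, ref$rvlv_angle_deg, tolerance = 1e-6)
    expect_equal(m$venous_displacement_norm, ref$venous_displacement_norm,
                 tolerance = 1e-6)
    expect_equal(m$tube_length, ref$tube_length, tolerance = 1e-6)
    expect_equal(m$direction, ref$direction)
  }
})

test_that("simulator recovery: exact at zero noise over a parameter grid", {
  for (ang in c(-135, -30, 0, 45, 179)) {
    for (off in c(-0.2, 0, 0.3)) {
      sim <- simulate_landmarks(landmark_sim_params(
        rvlv_angle_deg = ang, venous_offset_frac = off, tube_length = 700,
        seed = 2))
      m <- loop_metrics(align_to_embryo_frame(sim$landmarks))
      expect_equal(m$rvlv_angle_deg, ang, tolerance = 1e-7)
      expect_equal(m$venous_displacement_norm, off, tolerance = 1e-7)
      expect_equal(m$tube_length, 700, tolerance = 1e-6)
    }
  }
})

test_that("simulator recovery: unbiased under noise (100 seeds)", {
  angs <- offs <- numeric(100)
  for (s in 1:100) {
    sim <- simulate_landmarks(landmark_sim_params(
      rvlv_angle_deg = 25, venous_offset_frac = 0.15, noise_sd = 5,
      rigid_jitter = TRUE, seed = s))
    m <- loop_metrics(align_to_embryo_frame(sim$landmarks))
    angs[s] <- m$rvlv_angle_deg
    offs[s] <- m$venous_displacement_norm
  }
  expect_lt(abs(mean(angs) - 25), 2 * sd(angs) / 10)
  expect_lt(abs(mean(offs) - 0.15), 2 * sd(offs) / 10)
})

test_that("landmark simulator is deterministic and well-formed", {
  a <- simulate_landmarks(landmark_sim_params(noise_sd = 3, seed = 8))
  b <- simulate_landmarks(landmark_sim_params(noise_sd = 3, seed = 8))
  expect_identical(a$landmarks$points, b$landmarks$points)
  expect_setequal(rownames(a$landmarks$points),
                  c("outflow_exit", "OFT", "RV", "interventricular_sulcus",
                    "LV", "AVC_LA", "RA", "venous_pole"))
  # notochord collinear at zero noise
  z <- simulate_landmarks(landmark_sim_params(seed = 1))
  np <- z$landmarks$notochord_points
  sv <- svd(sweep(np, 2, colMeans(np)))
  expect_lt(sv$d[2], 1e-9)
  expect_error(landmark_sim_params(rvlv_angle_deg = -180), "rvlv_angle_deg")
  expect_error(landmark_sim_params(tube_length = 0), "tube_length")
})

test_that("direction frequency test: observed-equals-expected and Yates", {
  r <- direction_frequency_test(38, 76)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_equal(direction_frequency_test(30, 76)$statistic, 2 * 7.5^2 / 38)
  expect_error(direction_frequency_test(10, 5), "exceeds")
  expect_error(direction_frequency_test(4, 5, expected_prop = 1),
               "positive")
})
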