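# Independent brute-force oracles and small fixture builders. These never
# call the package code paths they are used to check.

# exact two-sided Mann-Whitney p by enumeration of all group labelings
oracle_mann_whitney_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  u_of <- function(sel) {
    xs <- pooled[sel]; ys <- pooled[-sel]
    sum(outer(xs, ys, `>`)) + 0.5 * sum(outer(xs, ys, `==`))
  }
  u_obs <- u_of(seq_len(nx))
  combs <- utils::combn(nx + ny, nx, simplify = FALSE)
  u_all <- vapply(combs, u_of, numeric(1))
  mu <- nx * ny / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}

# exact two-sided signed-rank p by enumeration of sign patterns
oracle_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% r
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

# BH step-up closed form, written independently (loop from the largest p)
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  run_min <- Inf
  for (i in m:1) {
    run_min <- min(run_min, m * ps[i] / i)
    adj[i] <- min(1, run_min)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# brute-force variant filter as one set comprehension
oracle_variant_pass <- function(cons, macs, revel, cadd,
                                max_mac = 2, revel_min = 0.932,
                                cadd_min = 28.1) {
  ptv <- cons %in% c("stop_gained", "frameshift_variant",
                     "splice_donor_variant", "splice_acceptor_variant")
  pav <- cons %in% c("missense_variant", "inframe_insertion",
                     "inframe_deletion")
  rare <- all(macs <= max_mac)
  severe <- (!is.na(revel) && revel >= revel_min) ||
    (!is.na(cadd) && cadd >= cadd_min)
  rare && (ptv || (pav && severe))
}

# a paired count_matrix fixture with prescribed columns
make_cm <- function(values, normalized = FALSE, stage = "E8.5f") {
  n <- ncol(values)
  stopifnot(n %% 2 == 0)
  emb <- rep(sprintf("e%02d", seq_len(n / 2)), each = 2)
  side <- rep(c("L", "R"), n / 2)
  colnames(values) <- paste0(emb, "_", side)
  samples <- data.frame(sample_id = colnames(values), embryo_id = emb,
                        side = side, stage = stage,
                        stringsAsFactors = FALSE)
  count_matrix(values, samples, normalized = normalized)
}

# an asym_measurement fixture without running the image pipeline
make_meas <- function(log2_ratio, stage = "E8.5d", genotype = "WT",
                      embryo_id = "e1") {
  structure(list(embryo_id = embryo_id, stage = stage, genotype = genotype,
                 region = "heart_field", S_L = 10L, S_R = 10L, H_L = 5,
                 H_R = 5, V_L = 100, V_R = 100, norm_score = 1,
                 log2_ratio = log2_ratio, valid = !is.na(log2_ratio),
                 reason = ""),
            class = "asym_measurement")
}

# small, fast image world for tests that only need structure, not accuracy;
# nuclei are scaled down with the field of view to keep hard-core packing
# feasible
small_image_params <- function(...) {
  args <- list(shape_voxels = c(48, 48, 28),
               n_nuclei_per_side = c(25, 25),
               nucleus_sigma_um = 1.2,
               spot_density_right = 0.02)
  do.call(image_sim_params, utils::modifyList(args, list(...)))
}
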