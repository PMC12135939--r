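test_that("mean-coverage normalization follows the stated rule", {
  # totals (100, 300); gene with raw (10, 30) must come out (20, 20)
  cm <- make_cm(matrix(c(10, 30, 90, 270), 2, byrow = TRUE))
  norm <- normalize_to_mean_coverage(cm)
  expect_equal(unname(norm$values[1, ]), c(20, 20))
  expect_true(norm$normalized)

  # equal totals: unchanged
  cm2 <- make_cm(matrix(c(5, 5, 15, 15), 2, byrow = TRUE))
  expect_equal(normalize_to_mean_coverage(cm2)$values, cm2$values)

  # conservation: every column total equals the mean raw total
  set.seed(21)
  cm3 <- make_cm(matrix(rpois(400, 40), 50))
  n3 <- normalize_to_mean_coverage(cm3)
  expect_equal(unname(colSums(n3$values)),
               rep(mean(colSums(cm3$values)), 8), tolerance = 1e-9)

  cm4 <- make_cm(matrix(c(1, 0, 1, 0), 2, byrow = TRUE))
  expect_error(normalize_to_mean_coverage(cm4), "e01_R")
})

test_that("expression flags: inclusive boundary at 20, oracle equality", {
  cm <- make_cm(matrix(c(20, 19.999, 0, 0), 2, byrow = TRUE),
                normalized = TRUE)
  fl <- compute_flags(cm)
  expect_equal(unname(fl$flags[1, ]), c(1, 0))
  expect_equal(unname(fl$flags[2, ]), c(0, 0))
  expect_equal(unname(fl$n_flagged), c(1, 0))

  set.seed(22)
  cm2 <- make_cm(matrix(runif(600, 0, 40), 75), normalized = TRUE)
  fl2 <- compute_flags(cm2)
  expect_equal(fl2$flags, (cm2$values >= 20) * 1L)  # brute force
  expect_error(compute_flags(make_cm(matrix(1:4, 2))), "normalized")
})

test_that("P50 filter: at-least-half rule, including odd sample counts", {
  mk_flags <- function(n_flagged, S) {
    flags <- t(vapply(n_flagged, function(k) c(rep(1L, k), rep(0L, S - k)),
                      integer(S)))
    rownames(flags) <- sprintf("g%d", seq_along(n_flagged))
    structure(list(flags = flags, n_flagged = rowSums(flags),
                   threshold = 20, n_samples = S), class = "flag_table")
  }
  expect_equal(p50_filter(mk_flags(c(4, 3, 8), 8)), c("g1", "g3"))
  expect_equal(p50_filter(mk_flags(c(4, 3), 7)), "g1")   # ceil(7/2) = 4
})

test_that("paired test: null gene, pair requirements, classical-t oracle", {
  v <- matrix(c(7, 7, 13, 13, 20, 20, 8, 8), 1)
  cm <- make_cm(v, normalized = TRUE)
  res <- paired_lr_test(cm)
  expect_equal(res$mean_log2_ratio, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$fold_change, 1)

  expect_error(paired_lr_test(make_cm(matrix(1:2, 1), normalized = TRUE)),
               "2 embryo pairs")

  # with moderation off the statistic is the classical paired t
  set.seed(23)
  vv <- matrix(rpois(4 * 8, 60), 4)
  cm2 <- make_cm(vv, normalized = TRUE)
  res2 <- paired_lr_test(cm2, prior_df = 0)
  for (g in 1:4) {
    d <- log2(vv[g, c(1, 3, 5, 7)] + 0.5) - log2(vv[g, c(2, 4, 6, 8)] + 0.5)
    ref <- stats::t.test(d)
    expect_equal(res2$t_statistic[g], unname(ref$statistic))
    expect_equal(res2$p_value[g], ref$p.value)
    expect_equal(res2$mean_log2_ratio[g], mean(d))
  }
})

test_that("paired test: BH column is BH of the p column over tested genes", {
  set.seed(24)
  cm <- make_cm(matrix(rpois(50 * 8, 80), 50), normalized = TRUE)
  res <- paired_lr_test(cm)
  expect_equal(res$bh_adjusted_p, bh_adjust(res$p_value))
  expect_true(all(res$bh_adjusted_p >= res$p_value))
})

test_that("truly asymmetric genes rank ahead of nulls in every seed", {
  for (s in 1:20) {
    sim <- simulate_paired_counts(count_sim_params(
      n_genes = 1000, n_asym = 50, asym_fold = 2, n_pairs = 4, seed = s))
    norm <- normalize_to_mean_coverage(sim$counts)
    res <- paired_lr_test(norm)
    asym <- res$gene %in% sim$truth$asym_genes
    expect_lt(median(res$p_value[asym]), median(res$p_value[!asym]))
  }
})

test_that("thresholding: inclusive printed boundaries, brute-force oracle", {
  res <- data.frame(gene = c("a", "b", "c"),
                    fold_change = c(1.2, 1.19, 3),
                    p_value = c(0.05, 0.001, 0.049))
  expect_setequal(apply_thresholds(res), c("a", "c"))

  set.seed(25)
  rnd <- data.frame(gene = sprintf("g%d", 1:500),
                    fold_change = runif(500, 1, 1.4),
                    p_value = runif(500, 0, 0.1))
  expect_setequal(apply_thresholds(rnd),
                  rnd$gene[rnd$fold_change >= 1.2 & rnd$p_value <= 0.05])
})

test_that("consensus union behaves as a set union", {
  expect_setequal(consensus_union(list(c("a", "b"), c("b", "c"))),
                  c("a", "b", "c"))
  expect_setequal(consensus_union(list(c("x", "y"))), c("x", "y"))
  expect_length(consensus_union(list(letters[1:3], letters[4:5])), 5)
  expect_error(consensus_union(list()), "non-empty")
})

test_that("MA statistics: closed forms", {
  cm <- make_cm(matrix(7, 2, 8), normalized = TRUE)
  ma <- ma_statistics(cm)
  expect_equal(nrow(ma), 2)
  expect_equal(ma$A, rep(log2(7.5), 2))
  expect_equal(ma$M, c(0, 0))

  # L = 2R exactly, pseudocount 0 -> M = 1
  v <- matrix(rep(c(40, 20), 4), 1)
  ma2 <- ma_statistics(make_cm(v, normalized = TRUE), pseudocount = 0)
  expect_equal(ma2$M, 1)
})

test_that("background call: strict below-5.6 rule", {
  expect_false(classify_background(5.6))
  expect_true(classify_background(0))
  set.seed(26)
  v <- runif(200, 0, 12)
  expect_equal(classify_background(v), v < 5.6)
})

test_that("co-expression fraction: printed worked example and edge cases", {
  # 309 A-positive cells of which 234 also express B -> 75%
  expr <- cbind(a = c(rep(1, 309), rep(0, 100)),
                b = c(rep(1, 234), rep(0, 75), rep(1, 50), rep(0, 50)))
  r <- coexpression_fraction(expr, "a", "b")
  expect_equal(r$n_a_positive, 309)
  expect_equal(r$n_both, 234)
  expect_equal(r$fraction, 234 / 309)
  # reported as the integer percent, 75% (234/309 = 75.7%, truncated in
  # the usual "seventy-five percent" reading)
  expect_equal(floor(100 * r$fraction), 75)

  none <- cbind(a = c(1, 1), b = c(0, 0))
  expect_equal(coexpression_fraction(none, "a", "b")$fraction, 0)
  all_b <- cbind(a = c(1, 1), b = c(2, 3))
  expect_equal(coexpression_fraction(all_b, "a", "b")$fraction, 1)
  expect_error(coexpression_fraction(cbind(a = 0, b = 1), "a", "b"),
               "undefined")
})

test_that("delta-delta-Ct relative expression", {
  rec <- data.frame(sample_id = c("cal", "s1", "s2"),
                    ct_target = c(22, 21, 23),
                    ct_reference = c(20, 20, 20))
  out <- relative_expression_ddct(rec, "cal")
  expect_equal(out$relative_expression[1], 1)
  expect_equal(out$relative_expression[2], 2)   # dCt 1 vs calibrator 2
  # one extra target cycle halves expression
  rec2 <- rec; rec2$ct_target[2] <- rec$ct_target[2] + 1
  out2 <- relative_expression_ddct(rec2, "cal")
  expect_equal(out2$relative_expression[2], out$relative_expression[2] / 2)
  expect_error(relative_expression_ddct(rec, "nope"), "calibrator")
})
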