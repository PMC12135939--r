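mk_var <- function(cons = "missense_variant", mac = c(g = 0, u = 0),
                   revel = NA_real_, cadd = NA_real_) {
  variant_record("19", 15159038, "C", "T", cons, mac, revel = revel,
                 cadd_phred = cadd)
}

test_that("consequence classification covers the printed classes", {
  expect_equal(classify_consequence(mk_var("stop_gained")), "PTV")
  expect_equal(classify_consequence(mk_var("frameshift_variant")), "PTV")
  expect_equal(classify_consequence(mk_var("splice_acceptor_variant")),
               "PTV")
  expect_equal(classify_consequence(mk_var("missense_variant")), "PAV")
  expect_equal(classify_consequence(mk_var("inframe_deletion")), "PAV")
  expect_equal(classify_consequence(mk_var("synonymous_variant")), "other")
  # splice-region (non-canonical) and unknown strings fall to other
  expect_equal(classify_consequence(mk_var("splice_region_variant")),
               "other")
  expect_equal(classify_consequence(mk_var("mystery_annotation")), "other")
  # multi-consequence strings: any PTV term wins
  expect_equal(classify_consequence(
    mk_var("missense_variant&splice_donor_variant")), "PTV")
})

test_that("rarity: MAC <= 2 in every dataset, boundary inclusive", {
  expect_true(passes_rarity(mk_var(mac = c(g = 2, u = 2, i = 2))))
  expect_false(passes_rarity(mk_var(mac = c(g = 0, u = 3))))
  expect_true(passes_rarity(mk_var(mac = c(g = 0, u = 0))))
  empty <- mk_var()
  empty$mac <- stats::setNames(numeric(0), character(0))
  expect_error(passes_rarity(empty), "no population MAC")
})

test_that("severity: printed thresholds inclusive, missing scores fail", {
  expect_true(passes_severity(mk_var(revel = 0.932, cadd = 10)))
  expect_true(passes_severity(mk_var(revel = 0.5, cadd = 28.1)))
  expect_false(passes_severity(mk_var(revel = 0.5, cadd = 20)))
  expect_false(passes_severity(mk_var()))            # both absent
  expect_true(passes_severity(mk_var(revel = NA, cadd = 30)))
  expect_error(passes_severity(mk_var("stop_gained")), "PAV")
})

test_that("full filter equals the brute-force set comprehension", {
  set.seed(31)
  all_cons <- c("stop_gained", "frameshift_variant", "splice_donor_variant",
                "missense_variant", "inframe_insertion", "inframe_deletion",
                "synonymous_variant", "splice_region_variant")
  recs <- lapply(1:300, function(i)
    mk_var(sample(all_cons, 1),
           mac = c(g = rpois(1, 1), u = rpois(1, 1)),
           revel = ifelse(runif(1) < 0.7, runif(1), NA),
           cadd = ifelse(runif(1) < 0.7, runif(1, 0, 45), NA)))
  out <- filter_variants(recs)
  want <- vapply(recs, function(v)
    oracle_variant_pass(v$consequence, v$mac, v$revel, v$cadd), logical(1))
  expect_equal(out$audit$pass, want)
  expect_equal(length(out$passing), sum(want))

  # order never matters
  perm <- sample(seq_along(recs))
  out2 <- filter_variants(recs[perm])
  expect_equal(out2$audit$pass, want[perm])
})

test_that("tightening any threshold only shrinks the pass set", {
  set.seed(32)
  recs <- lapply(1:200, function(i)
    mk_var(sample(c("stop_gained", "missense_variant"), 1),
           mac = c(g = rpois(1, 1.5)),
           revel = runif(1), cadd = runif(1, 0, 40)))
  base <- filter_variants(recs)$audit$pass
  for (args in list(list(max_mac = 1), list(revel_min = 0.99),
                    list(cadd_min = 35))) {
    tight <- do.call(filter_variants, c(list(recs), args))$audit$pass
    expect_true(all(!tight | base))   # tight subset of base
  }
})

test_that("degenerate inputs", {
  out <- filter_variants(list())
  expect_length(out$passing, 0)
  expect_equal(nrow(out$audit), 0)

  common <- lapply(1:5, function(i)
    mk_var("stop_gained", mac = c(g = 100), cadd = 40))
  expect_length(filter_variants(common)$passing, 0)
})

test_that("variant table generator covers every branch and matches truth", {
  sim <- simulate_variant_table(8, seed = 5)
  expect_length(sim$records, 8)
  audit <- filter_variants(sim$records)$audit
  # cross-module oracle: generator truth agrees with the filter
  expect_equal(unname(sim$truth$expected_pass), audit$pass)
  # both outcomes and classes are represented
  expect_setequal(unique(audit$pass), c(TRUE, FALSE))
  expect_true(all(c("PTV", "PAV") %in% audit$consequence_class))
  # boundary fixtures sit exactly at the printed thresholds
  revels <- vapply(sim$records, function(v) v$revel, numeric(1))
  cadds <- vapply(sim$records, function(v) v$cadd_phred, numeric(1))
  expect_true(0.932 %in% revels)
  expect_true(28.1 %in% cadds)

  big <- simulate_variant_table(40, seed = 9)
  expect_equal(unname(big$truth$expected_pass),
               filter_variants(big$records)$audit$pass)

  expect_identical(simulate_variant_table(12, seed = 2)$truth$expected_pass,
                   simulate_variant_table(12, seed = 2)$truth$expected_pass)
  expect_error(simulate_variant_table(5), "n")
})
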