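#' Simulate an annotated variant table covering every filter branch
#'
#' The first eight records are constructive, one per branch of the
#' ultrarare/severity filter: a passing PTV; a missense passing on REVEL; a
#' missense passing on CADD; a failing missense; a rarity (MAC) failure; and
#' the three printed boundaries (MAC exactly 2, REVEL exactly 0.932,
#' CADD_phred exactly 28.1, all passing). Records beyond eight are random
#' draws over consequence classes, MACs and scores. The ground truth stores
#' the expected pass flag for every record, computed from the filter
#' definition (not by calling the filter).
#'
#' @param n number of records (>= 8).
#' @param seed integer seed.
#' @return list with `records` (list of [variant_record()]) and `truth`
#'   (`ground_truth` with `expected_pass` flags).
#' @export
simulate_variant_table <- function(n = 8, seed = 1) {
  check_scalar(n, "n", integerish = TRUE)
  if (n < 8) stop_field("n", "must be >= 8 to cover all filter branches")
  check_scalar(seed, "seed", integerish = TRUE)
  datasets <- c("gnomAD_V3", "UK_biobank", "internal")
  mk_mac <- function(vals) stats::setNames(vals, datasets)

  base <- list(
    ## PTV, ultrarare -> pass
    list(cons = "stop_gained", mac = c(1, 0, 0), revel = NA, cadd = NA,
         pass = TRUE),
    ## missense passing on REVEL alone
    list(cons = "missense_variant", mac = c(0, 1, 0), revel = 0.97,
         cadd = 12, pass = TRUE),
    ## missense passing on CADD alone
    list(cons = "missense_variant", mac = c(1, 1, 0), revel = 0.40,
         cadd = 33, pass = TRUE),
    ## missense failing both severity branches
    list(cons = "missense_variant", mac = c(0, 0, 0), revel = 0.50,
         cadd = 20, pass = FALSE),
    ## severe but too common in one dataset
    list(cons = "stop_gained", mac = c(0, 7, 0), revel = NA, cadd = 35,
         pass = FALSE),
    ## boundary MAC = 2 everywhere, PTV -> pass
    list(cons = "frameshift_variant", mac = c(2, 2, 2), revel = NA,
         cadd = NA, pass = TRUE),
    ## boundary REVEL = 0.932 -> pass
    list(cons = "missense_variant", mac = c(0, 0, 1), revel = 0.932,
         cadd = 10, pass = TRUE),
    ## boundary CADD = 28.1 -> pass
    list(cons = "inframe_deletion", mac = c(1, 0, 0), revel = 0.10,
         cadd = 28.1, pass = TRUE)
  )

  with_seed(seed, {
    recs <- vector("list", n)
    expected <- logical(n)
    all_cons <- c(PTV_CONSEQUENCES, PAV_CONSEQUENCES, "synonymous_variant",
                  "splice_region_variant", "intron_variant")
    for (i in seq_len(n)) {
      if (i <= 8L) {
        b <- base[[i]]
        cons <- b$cons; mac <- mk_mac(b$mac)
        revel <- b$revel; cadd <- b$cadd
      } else {
        cons <- sample(all_cons, 1)
        mac <- mk_mac(stats::rpois(3, 1))
        revel <- if (stats::runif(1) < 0.8) stats::runif(1) else NA_real_
        cadd <- if (stats::runif(1) < 0.8) stats::runif(1, 0, 45) else NA_real_
      }
      recs[[i]] <- variant_record(
        chrom = "19", pos = 15159038 + i * 13, ref = "C",
        alt = sample(c("T", "G", "A"), 1), consequence = cons,
        mac = mac, revel = revel, cadd_phred = cadd,
        classification = "PM2")
      ## expected flag, re-derived from the filter definition
      split_cons <- trimws(strsplit(cons, "[,&]")[[1]])
      cls <- if (any(split_cons %in% PTV_CONSEQUENCES)) "PTV"
             else if (any(split_cons %in% PAV_CONSEQUENCES)) "PAV"
             else "other"
      rare <- all(mac <= 2)
      severe <- (!is.na(revel) && revel >= 0.932) ||
        (!is.na(cadd) && cadd >= 28.1)
      expected[i] <- rare && (cls == "PTV" || (cls == "PAV" && severe))
    }
    truth <- structure(list(
      kind = "variant_table",
      expected_pass = stats::setNames(expected,
                                      vapply(recs, `[[`, "", "id")),
      params = list(n = n, seed = seed)
    ), class = "ground_truth")
    list(records = recs, truth = truth)
  })
}
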