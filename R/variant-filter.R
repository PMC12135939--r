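## Ultrarare-variant severity filter: a variant passes when it is ultrarare
## in every population dataset (MAC <= 2) AND is either protein-truncating
## or a protein-altering variant with a severe in-silico effect
## (REVEL >= 0.932 or CADD_phred >= 28.1).

PTV_CONSEQUENCES <- c("stop_gained", "frameshift_variant",
                      "splice_donor_variant", "splice_acceptor_variant")
PAV_CONSEQUENCES <- c("missense_variant", "inframe_insertion",
                      "inframe_deletion")

#' Construct a single annotated variant record
#'
#' @param chrom,pos,ref,alt variant coordinates and alleles.
#' @param consequence VEP-style consequence string (e.g.
#'   "missense_variant").
#' @param mac named integer vector: minor allele count per population
#'   dataset.
#' @param revel REVEL score in \[0, 1\] or `NA`.
#' @param cadd_phred CADD Phred score (>= 0) or `NA`.
#' @param classification free-text label (e.g. ACMG terms); carried, never
#'   computed.
#' @param id variant identifier (default "chrom:pos:ref:alt").
#' @return a `variant_record`.
#' @export
variant_record <- function(chrom, pos, ref, alt, consequence, mac,
                           revel = NA_real_, cadd_phred = NA_real_,
                           classification = "", id = NULL) {
  if (!is.numeric(mac) || is.null(names(mac)) || any(names(mac) == ""))
    stop("mac must be a named numeric vector (dataset -> count)",
         call. = FALSE)
  if (any(mac < 0)) stop("MAC values must be nonnegative", call. = FALSE)
  if (!is.na(revel) && (revel < 0 || revel > 1))
    stop("revel must be in [0, 1]", call. = FALSE)
  if (!is.na(cadd_phred) && cadd_phred < 0)
    stop("cadd_phred must be >= 0", call. = FALSE)
  structure(list(
    id = if (is.null(id)) paste(chrom, pos, ref, alt, sep = ":") else id,
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    consequence = consequence, mac = mac, revel = revel,
    cadd_phred = cadd_phred, classification = classification
  ), class = "variant_record")
}

#' Classify a variant's consequence
#'
#' PTV: stop gain, frameshift, or canonical (+/-1,2) splice donor/acceptor.
#' PAV: missense, inframe insertion/deletion. Everything else (including
#' splice-region variants outside the canonical sites) is "other";
#' unrecognized strings fall through to "other".
#'
#' @param v a [variant_record()].
#' @return one of "PTV", "PAV", "other".
#' @export
classify_consequence <- function(v) {
  stopifnot(inherits(v, "variant_record"))
  cons <- strsplit(as.character(v$consequence), "[,&]")[[1]]
  cons <- trimws(cons)
  if (any(cons %in% PTV_CONSEQUENCES)) return("PTV")
  if (any(cons %in% PAV_CONSEQUENCES)) return("PAV")
  "other"
}

#' Ultrarare population-frequency test
#'
#' TRUE iff the variant's minor allele count is at most `max_mac` in every
#' listed population dataset (conservative per-dataset reading; boundary
#' inclusive, MAC = 2 passes).
#'
#' @param v a [variant_record()].
#' @param max_mac maximum allowed MAC (default 2).
#' @return logical.
#' @export
passes_rarity <- function(v, max_mac = 2) {
  stopifnot(inherits(v, "variant_record"))
  if (length(v$mac) == 0L)
    stop("variant has no population MAC annotations", call. = FALSE)
  all(v$mac <= max_mac)
}

#' In-silico severity test for protein-altering variants
#'
#' TRUE iff REVEL >= `revel_min` or CADD_phred >= `cadd_min` (boundaries
#' inclusive). A missing score fails its branch rather than erroring. Only
#' defined for PAV variants.
#'
#' @param v a [variant_record()] classified as PAV.
#' @param revel_min REVEL threshold (default 0.932).
#' @param cadd_min CADD Phred threshold (default 28.1).
#' @return logical.
#' @export
passes_severity <- function(v, revel_min = 0.932, cadd_min = 28.1) {
  stopifnot(inherits(v, "variant_record"))
  if (classify_consequence(v) != "PAV")
    stop("passes_severity is only defined for PAV variants", call. = FALSE)
  (!is.na(v$revel) && v$revel >= revel_min) ||
    (!is.na(v$cadd_phred) && v$cadd_phred >= cadd_min)
}

#' Apply the full variant filter
#'
#' A variant passes iff it passes rarity AND (it is a PTV, OR it is a PAV
#' passing severity). The audit table records every branch outcome per
#' variant.
#'
#' @param records list of [variant_record()]s.
#' @param max_mac,revel_min,cadd_min thresholds (defaults 2, 0.932, 28.1).
#' @return list with `passing` (sub-list of records) and `audit`
#'   (data.frame: id, consequence_class, rarity_pass, severity_pass, pass).
#' @export
filter_variants <- function(records, max_mac = 2, revel_min = 0.932,
                            cadd_min = 28.1) {
  if (length(records) == 0L)
    return(list(passing = list(),
                audit = data.frame(id = character(0),
                                   consequence_class = character(0),
                                   rarity_pass = logical(0),
                                   severity_pass = logical(0),
                                   pass = logical(0))))
  rows <- lapply(records, function(v) {
    cls <- classify_consequence(v)
    rar <- passes_rarity(v, max_mac)
    sev <- if (cls == "PAV") passes_severity(v, revel_min, cadd_min) else NA
    pass <- rar && (cls == "PTV" || (cls == "PAV" && isTRUE(sev)))
    data.frame(id = v$id, consequence_class = cls, rarity_pass = rar,
               severity_pass = sev, pass = pass, stringsAsFactors = FALSE)
  })
  audit <- do.call(rbind, rows)
  list(passing = records[audit$pass], audit = audit)
}
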