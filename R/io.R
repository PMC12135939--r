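## Readers and writers. Tabular interchange is TSV with a header row;
## nested metadata and ground truth are JSON. All writer/reader pairs
## round-trip.

#' Write a count matrix and its sample sheet
#'
#' @param cm a [count_matrix()].
#' @param path_counts TSV path for the gene x sample matrix (genes in rows).
#' @param path_samples TSV path for the sample sheet.
#' @return invisibly, the two paths.
#' @export
write_counts <- function(cm, path_counts, path_samples) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(gene = rownames(cm$values), cm$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path_counts, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cm$samples, path_samples, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path_counts, path_samples))
}

#' Read a count matrix and its sample sheet
#'
#' Validates numeric cells and the L/R pairing invariant; tolerant of CRLF
#' line endings and stray whitespace.
#'
#' @param path_counts,path_samples TSV paths written by [write_counts()]
#'   (or equivalent).
#' @param normalized whether the stored values are normalized.
#' @return a [count_matrix()].
#' @export
read_counts <- function(path_counts, path_samples, normalized = FALSE) {
  for (p in c(path_counts, path_samples))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  tab <- utils::read.delim(path_counts, check.names = FALSE,
                           strip.white = TRUE, stringsAsFactors = FALSE)
  if (!"gene" %in% names(tab))
    stop("counts file must have a 'gene' column", call. = FALSE)
  genes <- trimws(as.character(tab$gene))
  vals <- as.matrix(tab[setdiff(names(tab), "gene")])
  if (!is.numeric(vals)) {
    num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals)))
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
    if (nrow(bad) == 0L) bad <- which(is.na(num), arr.ind = TRUE)
    stop(sprintf("non-numeric count at row %d, column '%s'",
                 bad[1, 1], colnames(vals)[bad[1, 2]]), call. = FALSE)
  }
  rownames(vals) <- genes
  samples <- utils::read.delim(path_samples, strip.white = TRUE,
                               stringsAsFactors = FALSE)
  for (col in c("sample_id", "embryo_id", "side"))
    if (col %in% names(samples)) samples[[col]] <- trimws(samples[[col]])
  count_matrix(vals, samples, normalized = normalized)
}

#' Write a landmark set (JSON or CSV by extension)
#'
#' @param lm a [landmark_set()].
#' @param path output path ending in .json or .csv.
#' @return invisibly, the path.
#' @export
write_landmarks <- function(lm, path) {
  stopifnot(inherits(lm, "landmark_set"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- list(
      points = lapply(seq_len(nrow(lm$points)), function(i)
        list(name = rownames(lm$points)[i],
             x = lm$points[i, 1], y = lm$points[i, 2], z = lm$points[i, 3])),
      notochord_points = unname(apply(lm$notochord_points, 1, function(r)
        list(x = r[1], y = r[2], z = r[3]), simplify = FALSE)),
      dorsoventral_ref = list(x = lm$dorsoventral_ref[1],
                              y = lm$dorsoventral_ref[2],
                              z = lm$dorsoventral_ref[3]),
      somite_count = lm$somite_count, embryo_id = lm$embryo_id,
      genotype = lm$genotype, units = "um")
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  } else {
    rows <- rbind(
      data.frame(name = rownames(lm$points), kind = "landmark",
                 x = lm$points[, 1], y = lm$points[, 2], z = lm$points[, 3]),
      data.frame(name = sprintf("notochord_%02d",
                                seq_len(nrow(lm$notochord_points))),
                 kind = "notochord", x = lm$notochord_points[, 1],
                 y = lm$notochord_points[, 2], z = lm$notochord_points[, 3]),
      data.frame(name = "dorsoventral_ref", kind = "reference",
                 x = lm$dorsoventral_ref[1], y = lm$dorsoventral_ref[2],
                 z = lm$dorsoventral_ref[3]))
    rows$somite_count <- lm$somite_count
    rows$embryo_id <- lm$embryo_id
    rows$genotype <- lm$genotype
    utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a landmark set (JSON or CSV)
#'
#' Errors name any missing required landmark. An absent somite count is
#' kept as NA; downstream morphometry then rejects the embryo with an
#' explicit staging message.
#'
#' @param path path written by [write_landmarks()] (or equivalent).
#' @return a [landmark_set()].
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    pts <- as.matrix(obj$points[c("x", "y", "z")])
    rownames(pts) <- obj$points$name
    noto <- as.matrix(obj$notochord_points[c("x", "y", "z")])
    dv <- unlist(obj$dorsoventral_ref[c("x", "y", "z")])
    somites <- if (is.null(obj$somite_count) || is.na(obj$somite_count))
      NA_integer_ else as.integer(obj$somite_count)
    landmark_set(pts, noto, dv, somite_count = somites,
                 embryo_id = obj$embryo_id %||% "embryo",
                 genotype = obj$genotype %||% "WT")
  } else {
    rows <- utils::read.csv(path, strip.white = TRUE,
                            stringsAsFactors = FALSE)
    lpts <- rows[rows$kind == "landmark", , drop = FALSE]
    pts <- as.matrix(lpts[c("x", "y", "z")])
    rownames(pts) <- lpts$name
    nt <- rows[rows$kind == "notochord", , drop = FALSE]
    dvr <- rows[rows$kind == "reference", , drop = FALSE]
    somites <- if ("somite_count" %in% names(rows) &&
                   !is.na(rows$somite_count[1]))
      as.integer(rows$somite_count[1]) else NA_integer_
    landmark_set(pts, as.matrix(nt[c("x", "y", "z")]),
                 as.numeric(dvr[1, c("x", "y", "z")]),
                 somite_count = somites,
                 embryo_id = if ("embryo_id" %in% names(rows))
                   rows$embryo_id[1] else "embryo",
                 genotype = if ("genotype" %in% names(rows))
                   rows$genotype[1] else "WT")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write variant records as TSV
#'
#' One row per variant; MAC columns are `mac_<dataset>`.
#'
#' @param records list of [variant_record()]s.
#' @param path output TSV path.
#' @return invisibly, the path.
#' @export
write_variants_tsv <- function(records, path) {
  datasets <- unique(unlist(lapply(records, function(v) names(v$mac))))
  rows <- lapply(records, function(v) {
    r <- data.frame(id = v$id, chrom = v$chrom, pos = v$pos, ref = v$ref,
                    alt = v$alt, consequence = v$consequence,
                    revel = v$revel, cadd_phred = v$cadd_phred,
                    classification = v$classification,
                    stringsAsFactors = FALSE)
    for (ds in datasets) r[[paste0("mac_", ds)]] <-
        if (ds %in% names(v$mac)) v$mac[[ds]] else NA_real_
    r
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read variant records from TSV
#'
#' @param path TSV path written by [write_variants_tsv()] (or equivalent;
#'   MAC columns are `mac_<dataset>`).
#' @return list of [variant_record()]s.
#' @export
read_variants_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, strip.white = TRUE,
                           stringsAsFactors = FALSE)
  mac_cols <- grep("^mac_", names(tab), value = TRUE)
  lapply(seq_len(nrow(tab)), function(i) {
    mac <- unlist(tab[i, mac_cols])
    names(mac) <- sub("^mac_", "", mac_cols)
    mac <- mac[!is.na(mac)]
    variant_record(tab$chrom[i], tab$pos[i], tab$ref[i], tab$alt[i],
                   tab$consequence[i], mac,
                   revel = tab$revel[i], cadd_phred = tab$cadd_phred[i],
                   classification = tab$classification[i] %||% "",
                   id = tab$id[i])
  })
}

#' Write variant records as a minimal VCF
#'
#' Site-only VCFv4.2 with INFO keys `MAC_<dataset>`, `REVEL`, `CADD_PHRED`
#' and `CSQ` (the consequence string). Not a general-purpose VCF writer.
#'
#' @param records list of [variant_record()]s.
#' @param path output .vcf path (uncompressed).
#' @return invisibly, the path.
#' @export
write_variants_vcf <- function(records, path) {
  datasets <- unique(unlist(lapply(records, function(v) names(v$mac))))
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##INFO=<ID=MAC_%s,Number=1,Type=Integer,Description=\"Minor allele count in %s\">",
                   datasets, datasets),
           "##INFO=<ID=REVEL,Number=1,Type=Float,Description=\"REVEL score\">",
           "##INFO=<ID=CADD_PHRED,Number=1,Type=Float,Description=\"CADD Phred score\">",
           "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- vapply(records, function(v) {
    info <- c(sprintf("MAC_%s=%d", names(v$mac), as.integer(v$mac)),
              if (!is.na(v$revel)) sprintf("REVEL=%g", v$revel),
              if (!is.na(v$cadd_phred)) sprintf("CADD_PHRED=%g",
                                                v$cadd_phred),
              sprintf("CSQ=%s", v$consequence))
    paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", ".",
          paste(info, collapse = ";"), sep = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a minimal VCF of annotated variants
#'
#' Reads site lines of an uncompressed VCF carrying the INFO keys written
#' by [write_variants_vcf()].
#'
#' @param path .vcf path.
#' @return list of [variant_record()]s.
#' @export
read_variants_vcf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  lapply(body, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    kv <- strsplit(strsplit(f[8], ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    info <- stats::setNames(vapply(kv, function(x) x[2] %||% "", ""),
                            vapply(kv, `[`, "", 1))
    mac_keys <- grep("^MAC_", names(info), value = TRUE)
    mac <- stats::setNames(as.numeric(info[mac_keys]),
                           sub("^MAC_", "", mac_keys))
    variant_record(f[1], as.integer(f[2]), f[4], f[5],
                   info[["CSQ"]] %||% "",
                   mac,
                   revel = if ("REVEL" %in% names(info))
                     as.numeric(info[["REVEL"]]) else NA_real_,
                   cadd_phred = if ("CADD_PHRED" %in% names(info))
                     as.numeric(info[["CADD_PHRED"]]) else NA_real_,
                   id = f[3])
  })
}

#' Write a ground-truth record as JSON
#'
#' @param truth a `ground_truth` from a simulator.
#' @param path output .json path.
#' @return invisibly, the path.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  ## named atomic vectors become JSON objects so names survive round trips
  json_ready <- function(x) {
    if (is.matrix(x)) x
    else if (is.list(x)) lapply(x, json_ready)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  jsonlite::write_json(json_ready(unclass(truth)), path, auto_unbox = TRUE,
                       digits = NA, na = "null", matrix = "rowmajor")
  invisible(path)
}

#' Read a ground-truth record
#'
#' @param path .json path written by [write_ground_truth()].
#' @return a `ground_truth` list.
#' @export
read_ground_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(obj, class = "ground_truth")
}
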