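#' Gene-by-sample count matrix with paired left/right metadata
#'
#' The substrate of the paired screen: a nonnegative gene x sample matrix
#' plus a sample sheet. Every embryo must contribute exactly one left (L)
#' and one right (R) sample.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). Nonnegative.
#' @param samples data.frame with columns `sample_id`, `embryo_id`,
#'   `side` ("L"/"R") and optionally `stage`, `sex`. Row order must match the
#'   column order of `values`.
#' @param normalized logical; `FALSE` for raw counts.
#' @return an object of class `count_matrix`.
#' @export
count_matrix <- function(values, samples, normalized = FALSE) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("values must be numeric", call. = FALSE)
  if (any(values < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("gene%05d", seq_len(nrow(values)))
  req <- c("sample_id", "embryo_id", "side")
  miss <- setdiff(req, names(samples))
  if (length(miss))
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (nrow(samples) != ncol(values))
    stop("sample sheet rows must match matrix columns", call. = FALSE)
  if (is.null(colnames(values))) colnames(values) <- samples$sample_id
  if (!identical(colnames(values), as.character(samples$sample_id)))
    stop("matrix column names must equal sample sheet sample_id, in order",
         call. = FALSE)
  if (!all(samples$side %in% c("L", "R")))
    stop("side must be 'L' or 'R'", call. = FALSE)
  bad <- Filter(function(e) {
    s <- samples$side[samples$embryo_id == e]
    !(length(s) == 2L && setequal(s, c("L", "R")))
  }, unique(samples$embryo_id))
  if (length(bad))
    stop("embryo(s) without exactly one L and one R sample: ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(list(values = values, samples = samples,
                 normalized = isTRUE(normalized)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%d embryo pairs, %s)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$samples$embryo_id)),
              if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

## Column indices of the L and R sample for each embryo, in embryo order.
lr_index <- function(cm) {
  embryos <- unique(cm$samples$embryo_id)
  li <- vapply(embryos, function(e)
    which(cm$samples$embryo_id == e & cm$samples$side == "L"), integer(1))
  ri <- vapply(embryos, function(e)
    which(cm$samples$embryo_id == e & cm$samples$side == "R"), integer(1))
  list(embryos = embryos, left = li, right = ri)
}
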