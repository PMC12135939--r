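#' Co-expression fraction in single cells
#'
#' Among cells positive for `gene_a` (expression strictly above
#' `positivity_threshold`), the fraction also positive for `gene_b`. Used,
#' for example, to ask what fraction of Nodal-positive cardiac cells also
#' express Notch3.
#'
#' @param expr cell x gene numeric matrix with gene column names.
#' @param gene_a,gene_b gene column names.
#' @param positivity_threshold expression above this counts as positive
#'   (default 0).
#' @return list with `n_a_positive`, `n_both`, `fraction`.
#' @export
coexpression_fraction <- function(expr, gene_a, gene_b,
                                  positivity_threshold = 0) {
  expr <- as.matrix(expr)
  miss <- setdiff(c(gene_a, gene_b), colnames(expr))
  if (length(miss))
    stop("gene(s) not in matrix: ", paste(miss, collapse = ", "),
         call. = FALSE)
  a_pos <- expr[, gene_a] > positivity_threshold
  n_a <- sum(a_pos)
  if (n_a == 0L)
    stop("no cells positive for ", gene_a, "; fraction undefined",
         call. = FALSE)
  n_both <- sum(a_pos & expr[, gene_b] > positivity_threshold)
  list(n_a_positive = n_a, n_both = n_both, fraction = n_both / n_a)
}

#' Relative expression by the delta-delta-Ct method
#'
#' Standard qPCR quantification relative to a reference gene and a
#' calibrator sample: dCt_s = Ct_target,s - Ct_reference,s;
#' ddCt_s = dCt_s - dCt_calibrator; relative expression = 2^(-ddCt_s).
#' The calibrator's relative expression is 1 by construction.
#'
#' @param records data.frame with columns `sample_id`, `ct_target`,
#'   `ct_reference` (cycles, finite).
#' @param calibrator_id sample id of the calibrator.
#' @return data.frame with columns `sample_id`, `delta_ct`,
#'   `delta_delta_ct`, `relative_expression`.
#' @export
relative_expression_ddct <- function(records, calibrator_id) {
  req <- c("sample_id", "ct_target", "ct_reference")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("records missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(records$ct_target)) ||
      any(!is.finite(records$ct_reference)))
    stop("Ct values must be finite", call. = FALSE)
  if (!calibrator_id %in% records$sample_id)
    stop("calibrator sample '", calibrator_id, "' not found", call. = FALSE)
  dct <- records$ct_target - records$ct_reference
  dct_cal <- dct[match(calibrator_id, records$sample_id)]
  ddct <- dct - dct_cal
  data.frame(sample_id = records$sample_id,
             delta_ct = dct,
             delta_delta_ct = ddct,
             relative_expression = 2^(-ddct),
             row.names = NULL, stringsAsFactors = FALSE)
}
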