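#' Parameters for the paired-count simulator
#'
#' Describes a paired left/right bulk RNA-seq design: each embryo contributes
#' one left and one right heart-field sample. Counts are negative binomial
#' with gene-wise means drawn log-normally around `baseline_mean`; a minority
#' of genes is truly left-enriched by a multiplicative fold on the left mean.
#'
#' Defaults mirror the screen's stated world: 4 embryo pairs, a realistic
#' bulk dynamic range (sdlog 1 around a mean of 100 mean-coverage units),
#' moderate biological dispersion (0.05) and up to two-fold library-size
#' spread.
#'
#' @param n_genes number of genes.
#' @param n_pairs number of embryos (each yields an L and an R sample).
#' @param baseline_mean scale of gene-wise negative binomial means.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param n_asym number of truly left-enriched genes.
#' @param asym_fold true L/R fold for asymmetric genes (> 1).
#' @param library_size_spread max/min ratio of per-sample scaling factors
#'   (>= 1).
#' @param mean_sdlog sdlog of the log-normal spread of gene means.
#' @param seed integer seed.
#' @return a `count_sim_params` list.
#' @export
count_sim_params <- function(n_genes = 5000, n_pairs = 4, baseline_mean = 100,
                             dispersion = 0.05, n_asym = 50, asym_fold = 2,
                             library_size_spread = 2, mean_sdlog = 1,
                             seed = 1) {
  check_scalar(n_genes, "n_genes", positive = TRUE, integerish = TRUE)
  check_scalar(n_pairs, "n_pairs", positive = TRUE, integerish = TRUE)
  check_scalar(baseline_mean, "baseline_mean", positive = TRUE)
  check_scalar(dispersion, "dispersion", positive = TRUE)
  check_scalar(n_asym, "n_asym", nonneg = TRUE, integerish = TRUE)
  if (n_asym > n_genes) stop_field("n_asym", "must be <= n_genes")
  if (n_asym > 0 && asym_fold <= 1)
    stop_field("asym_fold", "must be > 1 when n_asym > 0")
  check_scalar(library_size_spread, "library_size_spread", lower = 1)
  check_scalar(mean_sdlog, "mean_sdlog", nonneg = TRUE)
  check_scalar(seed, "seed", integerish = TRUE)
  structure(list(n_genes = n_genes, n_pairs = n_pairs,
                 baseline_mean = baseline_mean, dispersion = dispersion,
                 n_asym = n_asym, asym_fold = asym_fold,
                 library_size_spread = library_size_spread,
                 mean_sdlog = mean_sdlog, seed = seed),
            class = "count_sim_params")
}

#' Simulate a paired left/right count matrix
#'
#' Negative binomial counts for a paired L/R design. Symmetric genes share
#' one mean per gene across sides and embryos; asymmetric genes have
#' expected left mean = `asym_fold` x right mean. Per-sample library factors
#' span `library_size_spread` geometrically. Same seed, same output.
#'
#' @param params a [count_sim_params()] object.
#' @return list with `counts` (a [count_matrix()], raw) and `truth` (a
#'   `ground_truth` record: asymmetric gene ids, fold, gene means, library
#'   factors).
#' @export
simulate_paired_counts <- function(params = count_sim_params()) {
  if (!inherits(params, "count_sim_params"))
    params <- do.call(count_sim_params, as.list(params))
  p <- params
  with_seed(p$seed, {
    genes <- sprintf("gene%05d", seq_len(p$n_genes))
    mu <- stats::rlnorm(p$n_genes,
                        meanlog = log(p$baseline_mean) - p$mean_sdlog^2 / 2,
                        sdlog = p$mean_sdlog)
    asym_idx <- if (p$n_asym > 0) sort(sample.int(p$n_genes, p$n_asym))
                else integer(0)
    mu_r <- mu
    mu_l <- mu
    mu_l[asym_idx] <- mu_l[asym_idx] * p$asym_fold

    n_samp <- 2L * p$n_pairs
    lib <- if (p$library_size_spread > 1)
      exp(stats::runif(n_samp, 0, log(p$library_size_spread)))
    else rep(1, n_samp)
    lib <- lib / mean(lib)

    size <- 1 / p$dispersion
    values <- matrix(0L, nrow = p$n_genes, ncol = n_samp)
    embryos <- sprintf("embryo%02d", seq_len(p$n_pairs))
    sides <- rep(c("L", "R"), p$n_pairs)
    emb_col <- rep(embryos, each = 2L)
    for (j in seq_len(n_samp)) {
      m <- if (sides[j] == "L") mu_l else mu_r
      values[, j] <- stats::rnbinom(p$n_genes, mu = m * lib[j], size = size)
    }
    rownames(values) <- genes
    sample_ids <- paste0(emb_col, "_", sides)
    colnames(values) <- sample_ids
    samples <- data.frame(sample_id = sample_ids, embryo_id = emb_col,
                          side = sides, stage = "E8.5f",
                          stringsAsFactors = FALSE)
    truth <- structure(list(
      kind = "paired_counts",
      asym_genes = genes[asym_idx],
      asym_fold = p$asym_fold,
      gene_mean_right = stats::setNames(mu_r, genes),
      library_factors = stats::setNames(lib, sample_ids),
      params = unclass(p)
    ), class = "ground_truth")
    list(counts = count_matrix(values, samples, normalized = FALSE),
         truth = truth)
  })
}
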