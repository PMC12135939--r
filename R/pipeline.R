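## Configuration and the end-to-end orchestrator. Every printed analysis
## threshold lives here as a named default so a resolved configuration is
## self-documenting.

run_config_defaults <- function() {
  list(
    stages = c("simulate", "screen", "variants"),
    seed = 1,
    out_dir = "asymscreen_run",
    log_level = "info",
    counts = list(n_genes = 2000, n_pairs = 4, baseline_mean = 100,
                  dispersion = 0.05, n_asym = 50, asym_fold = 2,
                  library_size_spread = 2, mean_sdlog = 1),
    screen = list(flag_threshold = 20, min_fold = 1.2, max_p = 0.05,
                  background_threshold = 5.6, pseudocount = 0.5,
                  trim = 0.1),
    image = list(preset = "symmetric"),
    morphometry = list(min_somites = 18),
    variants = list(n = 12, max_mac = 2, revel_min = 0.932,
                    cadd_min = 28.1)
  )
}

#' Build a run configuration
#'
#' Merges user settings over the documented defaults (flag threshold 20,
#' fold 1.2, p 0.05, background 5.6, MAC 2, REVEL 0.932, CADD 28.1, somite
#' QC 18). Unknown keys, at either level, are rejected before any work.
#'
#' @param config named list of overrides, or a path to a JSON file of them.
#' @return the fully resolved `run_config` list.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  defaults <- run_config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (k in names(config)) {
    if (is.list(defaults[[k]]) && is.list(config[[k]])) {
      bad <- setdiff(names(config[[k]]), names(defaults[[k]]))
      if (length(bad))
        stop("unknown config key(s) under '", k, "': ",
             paste(bad, collapse = ", "), call. = FALSE)
      defaults[[k]][names(config[[k]])] <- config[[k]]
    } else {
      defaults[[k]] <- config[[k]]
    }
  }
  structure(defaults, class = "run_config")
}

log_msg <- function(cfg, level, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf("[asymscreen %s] %s", level, paste0(...)))
}

#' Run the pipeline end to end
#'
#' Executes the selected stages (simulate counts -> screen -> variant
#' filter) into one output directory, deterministically for a given seed,
#' and writes a manifest with package version, resolved configuration,
#' per-stage counts and md5 hashes of every output file.
#'
#' @param config a [run_config()] (or overrides / JSON path accepted by
#'   it).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(cfg), file.path(out, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(package_version = as.character(utils::packageVersion("asymscreen")),
                   seed = cfg$seed, stage_counts = list())

  if ("simulate" %in% cfg$stages || "screen" %in% cfg$stages) {
    log_msg(cfg, "info", "simulating paired counts")
    sim <- simulate_paired_counts(do.call(count_sim_params,
      c(cfg$counts, list(seed = derive_seed(cfg$seed, 1)))))
    write_counts(sim$counts, file.path(out, "counts.tsv"),
                 file.path(out, "samples.tsv"))
    write_ground_truth(sim$truth, file.path(out, "counts_truth.json"))
    manifest$stage_counts$genes_in <- nrow(sim$counts$values)
  }
  if ("screen" %in% cfg$stages) {
    log_msg(cfg, "info", "running paired left/right screen")
    sc <- cfg$screen
    norm <- normalize_to_mean_coverage(sim$counts)
    flags <- compute_flags(norm, threshold = sc$flag_threshold)
    p50 <- p50_filter(flags)
    res <- paired_lr_test(norm, genes = p50, pseudocount = sc$pseudocount,
                          trim = sc$trim, in_p50 = p50)
    hits <- apply_thresholds(res, min_fold = sc$min_fold, max_p = sc$max_p)
    ma <- ma_statistics(norm, pseudocount = sc$pseudocount)
    de <- merge(ma, as.data.frame(res), by = "gene", all.x = TRUE)
    de$n_flagged <- flags$n_flagged[de$gene]
    de$pass <- de$gene %in% hits
    de <- de[order(de$gene), ]
    utils::write.table(de, file.path(out, "de_table.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeLines(hits, file.path(out, "genes_pass.txt"))
    writeLines(p50, file.path(out, "genes_p50.txt"))
    manifest$stage_counts <- c(manifest$stage_counts, list(
      genes_flagged = sum(flags$n_flagged > 0), genes_p50 = length(p50),
      genes_thresholded = length(hits),
      genes_consensus = length(consensus_union(list(hits)))))
  }
  if ("variants" %in% cfg$stages) {
    log_msg(cfg, "info", "simulating and filtering variants")
    vc <- cfg$variants
    vs <- simulate_variant_table(vc$n, seed = derive_seed(cfg$seed, 4))
    flt <- filter_variants(vs$records, max_mac = vc$max_mac,
                           revel_min = vc$revel_min,
                           cadd_min = vc$cadd_min)
    write_variants_tsv(vs$records, file.path(out, "variants.tsv"))
    write_variants_tsv(flt$passing, file.path(out, "variants_pass.tsv"))
    utils::write.table(flt$audit, file.path(out, "variants_audit.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stage_counts <- c(manifest$stage_counts, list(
      variants_in = length(vs$records),
      variants_pass = length(flt$passing)))
  }

  files <- setdiff(list.files(out), "manifest.json")
  manifest$outputs <- lapply(files, function(f)
    list(file = f, md5 = unname(tools::md5sum(file.path(out, f)))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  log_msg(cfg, "info", "run complete: ", out)
  invisible(manifest)
}
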