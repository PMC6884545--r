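#' Pipeline configuration with standard defaults
#'
#' Collects every tunable threshold of the pipeline with its standard value:
#' 5 kb calling windows, log2 ratio cut-off of 2 (4-fold), GC bounds
#' 30-60%, 5th-percentile low-coverage filter, at least 10 germline alt
#' reads with soma depth of at least 10 for an SNV call, at least 5 SNVs for
#' gene-level high confidence, 100 RNA reads with an alt/ref ratio above 1%
#' for transcription support, f = 0.364 GRCs per haploid genome, and 10,000
#' randomisation draws for enrichment. The simulation block defines the
#' demonstration dataset.
#'
#' @param ... Overrides of any default field.
#' @return Named list of class `grc_config`.
#' @export
grc_pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    # simulation
    n_chrom = 1L, chrom_len = 500e3, n_genes = 50L, gene_len = 5000L,
    gc_profile = list(kind = "gradient", from = 0.35, to = 0.55),
    n_grc_genes = 5L, grc_copies = c(2L, 8L, 9L, 50L, 308L),
    p_div = 0.01, grc_fraction = 0.364, grc_size_mb = 167.3,
    depth_soma = 15, depth_germ = NULL, error_rate = 1e-3,
    # coverage calling
    window_size = 5000L, cutoff_log2 = 2, gc_bounds = c(0.30, 0.60),
    low_pct = 5,
    # SNV calling
    min_germ = 10L, min_soma_depth = 10L, snv_mode = "alt_reads",
    min_snvs = 5L,
    # RNA verification
    rna_min_reads = 100L, rna_min_ratio = 0.01, rna_depth = 200,
    rna_alt_fraction = 0.3,
    # enrichment
    n_reps = 10000L, frac_unexpressed = 0.1,
    # strata
    trees_per_stratum = 2L, min_bootstrap = 50)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  structure(utils::modifyList(cfg, over), class = c("grc_config", "list"))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the end-to-end GRC discovery pipeline on simulated data
#'
#' Executes the full cascade on a dataset simulated from the configuration:
#' genome and pileup simulation, coverage-ratio amplification calling with
#' the soma-excess negative control, germline-specific SNV calling with the
#' soma-swap negative control and the high-confidence union rule, per-gene
#' copy-number estimation in both tissues, RNA transcription verification,
#' gonad-expression enrichment of the high-confidence set, and stratum
#' assignment of simulated gene trees. All seeds derive from `config$seed`,
#' so reruns reproduce the report exactly.
#'
#' @param config A [grc_pipeline_config()].
#' @return list of class `grc_report`: the config, per-stage results and
#'   record counts, the high-confidence gene set, negative-control counts,
#'   and truth-recovery metrics.
#' @export
run_pipeline <- function(config = grc_pipeline_config()) {
  seed <- config$seed
  depth_germ <- if (is.null(config$depth_germ)) config$depth_soma
                else config$depth_germ

  sim <- .stage("simulate", {
    gen <- simulate_genome(config$n_chrom, config$chrom_len, config$n_genes,
                           config$gc_profile, seed = seed,
                           gene_len = config$gene_len)
    n_grc <- config$n_grc_genes
    grc_ids <- gen$annotation$gene_id[
      round(seq(1, nrow(gen$annotation), length.out = n_grc))]
    grc <- grc_model(config$grc_fraction,
                     data.frame(gene_id = grc_ids,
                                copies = rep_len(config$grc_copies, n_grc),
                                p_div = rep_len(config$p_div, n_grc)),
                     grc_size_mb = config$grc_size_mb)
    simulate_pileups(gen$reference, gen$annotation, grc,
                     depth_soma = config$depth_soma, depth_germ = depth_germ,
                     error_rate = config$error_rate, seed = seed + 1L)
  })

  coverage <- .stage("coverage", call_grc_windows(
    sim$germline_pileup, sim$soma_pileup, sim$reference, sim$annotation,
    window_size = config$window_size, cutoff_log2 = config$cutoff_log2,
    gc_bounds = config$gc_bounds, low_pct = config$low_pct))

  snv <- .stage("snv", {
    calls <- call_specific_snvs(sim$germline_pileup, sim$soma_pileup,
                                min_germ = config$min_germ,
                                min_soma_depth = config$min_soma_depth,
                                mode = config$snv_mode)
    nc <- negative_control(sim$germline_pileup, sim$soma_pileup,
                           min_germ = config$min_germ,
                           min_soma_depth = config$min_soma_depth,
                           mode = config$snv_mode)
    genes <- summarise_genes(calls, sim$annotation, coverage$genes,
                             min_snvs = config$min_snvs)
    list(calls = calls, n_soma_specific = as.integer(nc), genes = genes)
  })
  high_conf <- snv$genes$gene_id[snv$genes$high_confidence]

  copynum <- .stage("copynum", {
    germ <- gene_copy_number(sim$germline_pileup, sim$annotation,
                             sim$library_bases["germline"],
                             sim$genome_size["germline"])
    soma <- gene_copy_number(sim$soma_pileup, sim$annotation,
                             sim$library_bases["soma"],
                             sim$genome_size["soma"])
    data.frame(gene_id = germ$gene_id,
               cn_germline = germ$copies_per_haploid,
               cn_soma = soma$copies_per_haploid,
               cn_excess = germ$copies_per_haploid - soma$copies_per_haploid)
  })

  rna <- .stage("rna", {
    if (nrow(sim$truth$grc$genes)) {
      rp <- simulate_rna_pileup(sim, depth = config$rna_depth,
                                alt_fraction = config$rna_alt_fraction,
                                seed = seed + 2L)
      verify_transcription(snv$calls, rp, sim$annotation,
                           min_reads = config$rna_min_reads,
                           min_ratio = config$rna_min_ratio)
    } else list(snvs = NULL,
                genes = data.frame(gene_id = sim$annotation$gene_id,
                                   expressed = FALSE))
  })

  enrich <- .stage("enrich", {
    expr <- simulate_expression_table(
      nrow(sim$annotation), seed = seed + 3L,
      frac_unexpressed = config$frac_unexpressed,
      gene_ids = sim$annotation$gene_id)
    bg <- build_background(expr, universe = sim$annotation$gene_id)
    query <- intersect(high_conf, bg$gene_id)
    if (length(query))
      randomisation_test(bg, query, n_reps = config$n_reps, seed = seed + 4L)
    else NULL
  })

  strata <- .stage("strata", {
    truth_strata <- rep(1:5, each = config$trees_per_stratum)
    trees <- lapply(seq_along(truth_strata), function(i)
      simulate_gene_tree(insertion_branch = truth_strata[i],
                         seed = seed + 10L + i))
    names(trees) <- sprintf("tree_s%d_%02d", truth_strata,
                            seq_along(truth_strata))
    asg <- assign_strata(trees, min_bootstrap = config$min_bootstrap)
    asg$truth <- truth_strata
    asg
  })

  truth_genes <- sim$truth$grc$genes$gene_id
  metrics <- list(
    n_amplified_windows = sum(coverage$windows$amplified),
    n_blocks = nrow(coverage$blocks),
    n_soma_excess_windows = coverage$n_soma_excess,
    n_snv_calls = nrow(snv$calls),
    n_soma_specific_snvs = snv$n_soma_specific,
    n_high_confidence = length(high_conf),
    coverage_recall = if (length(truth_genes))
      mean(truth_genes %in% coverage$genes) else NA_real_,
    coverage_false_genes = length(setdiff(coverage$genes, truth_genes)),
    strata_accuracy = mean(strata$stratum == strata$truth, na.rm = FALSE))

  structure(list(config = config, simulation = sim, coverage = coverage,
                 snv = snv, copynum = copynum, rna = rna, enrich = enrich,
                 strata = strata, high_confidence = high_conf,
                 metrics = metrics),
            class = "grc_report")
}

#' @export
print.grc_report <- function(x, ...) {
  m <- x$metrics
  cat("GRC discovery report\n")
  cat("  amplified windows:", m$n_amplified_windows,
      "| blocks:", m$n_blocks,
      "| soma-excess (neg ctrl):", m$n_soma_excess_windows, "\n")
  cat("  germline-specific SNVs:", m$n_snv_calls,
      "| soma-specific (neg ctrl):", m$n_soma_specific_snvs, "\n")
  cat("  high-confidence genes:", m$n_high_confidence,
      "| coverage recall:", round(m$coverage_recall, 3),
      "| false genes:", m$coverage_false_genes, "\n")
  cat("  strata accuracy:", round(m$strata_accuracy, 3), "\n")
  invisible(x)
}

#' Serialise a pipeline report to JSON
#'
#' Writes the configuration (provenance), stage counts, the
#' high-confidence gene set, negative-control counts and recovery metrics;
#' bulky per-position objects are summarised, not embedded.
#'
#' @param report `grc_report` from [run_pipeline()].
#' @param path Output JSON path.
#' @export
write_report <- function(report, path) {
  out <- list(
    config = unclass(report$config),
    metrics = report$metrics,
    high_confidence = report$high_confidence,
    blocks = report$coverage$blocks,
    gene_summary = report$snv$genes,
    copy_number = report$copynum,
    enrichment = if (!is.null(report$enrich)) list(
      n = report$enrich$n, N = report$enrich$N,
      K = as.list(report$enrich$K),
      observed = as.list(report$enrich$observed),
      p = report$enrich$p) else NULL,
    strata = report$strata)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
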