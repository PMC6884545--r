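PILEUP_COLS <- c("chrom", "pos0", "ref", "A", "C", "G", "T")

#' Read a pileup TSV
#'
#' Dialect: tab-separated with header columns `chrom`, `pos0` (0-based
#' position), `ref` (reference base) and per-base read counts `A`, `C`, `G`,
#' `T`. Malformed records raise a line-numbered error.
#'
#' @param path File path.
#' @return Pileup data.frame.
#' @export
read_pileup <- function(path) {
  p <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(PILEUP_COLS %in% names(p)))
    stop("pileup ", path, " must have columns: ",
         paste(PILEUP_COLS, collapse = ", "))
  p <- p[, PILEUP_COLS]
  bad <- which(!is.finite(p$pos0) | p$pos0 < 0 | p$pos0 != round(p$pos0) |
                 !p$ref %in% c(BASES, "N") |
                 p$A < 0 | p$C < 0 | p$G < 0 | p$T < 0)
  if (length(bad))
    stop("malformed pileup record at line ", bad[1] + 1L, " of ", path)
  p
}

#' Write a pileup TSV
#' @param pileup Pileup data.frame.
#' @param path File path.
#' @export
write_pileup <- function(pileup, path) {
  utils::write.table(pileup[, PILEUP_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED annotation (0-based half-open on disk)
#'
#' Parsed with [rtracklayer::import()]; the BED name field becomes
#' `gene_id`. Coordinates are returned 0-based half-open, matching the
#' package's internal convention.
#'
#' @param path BED file; columns chrom, start, end and optionally name
#'   (gene id) and score.
#' @return data.frame `chrom`, `start`, `end`, `gene_id` (and `score` when
#'   present).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr))
  mc <- S4Vectors::mcols(gr)
  if ("name" %in% names(mc)) out$gene_id <- mc$name
  if ("score" %in% names(mc)) out$score <- mc$score
  out
}

#' Write intervals as BED (0-based half-open on disk)
#'
#' Written with [rtracklayer::export()]; a `gene_id` column becomes the BED
#' name field.
#'
#' @param x data.frame with `chrom`, `start`, `end`; optional `gene_id`.
#' @param path File path.
#' @param score_col Optional column to write as BED score (e.g.
#'   `"log2_ratio"` for coverage windows).
#' @export
write_bed <- function(x, path, score_col = NULL) {
  gr <- GenomicRanges::GRanges(x$chrom,
                               IRanges::IRanges(x$start + 1L, x$end))
  if ("gene_id" %in% names(x)) gr$name <- x$gene_id
  score <- if (!is.null(score_col)) x[[score_col]]
           else if ("score" %in% names(x)) x$score else NULL
  if (!is.null(score)) {
    score[!is.finite(score)] <- 0
    gr$score <- score
  }
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write germline-specific SNV calls as VCF
#'
#' One VCF 4.2 record per call; per-tissue allele depths and site depths are
#' carried in INFO fields `GAD`/`GDP` (germline) and `SAD`/`SDP` (soma).
#'
#' @param calls Call data.frame from [call_specific_snvs()].
#' @param path Output path.
#' @export
write_vcf <- function(calls, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=grcscan",
    "##INFO=<ID=GAD,Number=1,Type=Integer,Description=\"Germline alt read depth\">",
    "##INFO=<ID=GDP,Number=1,Type=Integer,Description=\"Germline site depth\">",
    "##INFO=<ID=SAD,Number=1,Type=Integer,Description=\"Soma alt read depth\">",
    "##INFO=<ID=SDP,Number=1,Type=Integer,Description=\"Soma site depth\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(calls)) sprintf(
    "%s\t%d\t.\t%s\t%s\t.\tPASS\tGAD=%d;GDP=%d;SAD=%d;SDP=%d",
    calls$chrom, calls$pos0 + 1L, calls$ref, calls$alt,
    calls$germ_alt_reads, calls$germ_depth,
    calls$soma_alt_reads, calls$soma_depth) else character()
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a Newick gene tree
#'
#' Thin wrapper over [ape::read.tree()]; internal node labels (bootstrap
#' support) are preserved.
#' @param path Newick file (may hold several trees).
#' @return `phylo` or `multiPhylo`.
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

#' Read a gene-by-tissue expression table (TSV)
#' @param path TSV with a `gene_id` column and one numeric column per tissue.
#' @return data.frame.
#' @export
read_expression_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene_id" %in% names(x))
    stop("expression table must have a gene_id column")
  x
}

#' Serialise a simulation's truth tables
#'
#' Writes the machine-readable truth of a simulated dataset: the divergence
#' SNVs as TSV and the GRC model plus library metadata as JSON.
#'
#' @param sim `grc_simulation` from [simulate_pileups()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_truth <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, "truth_snvs.tsv")
  utils::write.table(sim$truth$snvs, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  js <- file.path(dir, "truth.json")
  jsonlite::write_json(list(
    grc_fraction = sim$truth$grc$grc_fraction,
    grc_genes = sim$truth$grc$genes,
    grc_size_mb = sim$truth$grc$grc_size_mb,
    library_bases = as.list(sim$library_bases),
    genome_size = as.list(sim$genome_size)), js,
    auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, js))
}

#' Read a pipeline configuration (YAML)
#'
#' Unknown keys are rejected; missing keys take the defaults of
#' [grc_pipeline_config()].
#' @param path YAML file.
#' @return Config list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  defaults <- grc_pipeline_config()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  utils::modifyList(defaults, user)
}
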