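#' Call germline-specific SNVs from paired pileups
#'
#' A site/allele pair is called germline-specific when a non-reference base
#' is well supported in the germline pileup while entirely absent from the
#' soma pileup of the same individual at an adequately covered soma site.
#' Only single-base substitutions are considered; each alternate allele of a
#' multi-allelic site is evaluated independently (at most one call per
#' locus+alt). Soma sites below `min_soma_depth` are skipped: absence of
#' evidence is not evidence of absence.
#'
#' Two readings of the germline support threshold are available: the default
#' `"alt_reads"` requires at least `min_germ` germline reads carrying the
#' alternate allele; `"site_depth"` requires germline site depth of at least
#' `min_germ` with any alternate support. The allele-supporting reading is
#' the default because site depth alone would admit single-read sequencing
#' errors.
#'
#' @param germ_pileup,soma_pileup Pileup data.frames
#'   (`chrom`, `pos0`, `ref`, `A`, `C`, `G`, `T`) on shared coordinates.
#' @param min_germ Germline support threshold (default 10 reads).
#' @param min_soma_depth Minimum soma site depth for the site to be
#'   evaluable (default 10).
#' @param mode `"alt_reads"` (default) or `"site_depth"`; see Details.
#' @param sample_id Optional sample label carried through to the calls.
#' @return data.frame of calls: `chrom`, `pos0`, `ref`, `alt`,
#'   `germ_alt_reads`, `germ_depth`, `soma_alt_reads`, `soma_depth`,
#'   `sample_id`.
#' @export
call_specific_snvs <- function(germ_pileup, soma_pileup, min_germ = 10L,
                               min_soma_depth = 10L,
                               mode = c("alt_reads", "site_depth"),
                               sample_id = NA_character_) {
  mode <- match.arg(mode)
  m <- merge(germ_pileup, soma_pileup,
             by = c("chrom", "pos0", "ref"), suffixes = c(".g", ".s"))
  gm <- as.matrix(m[, paste0(BASES, ".g")])
  sm <- as.matrix(m[, paste0(BASES, ".s")])
  germ_depth <- rowSums(gm)
  soma_depth <- rowSums(sm)
  ref_code <- match(m$ref, BASES)

  out <- vector("list", 4L)
  for (b in 1:4) {
    is_alt <- ref_code != b
    support <- if (mode == "alt_reads") gm[, b] >= min_germ
               else germ_depth >= min_germ & gm[, b] > 0L
    hit <- is_alt & support & sm[, b] == 0L & soma_depth >= min_soma_depth
    if (any(hit))
      out[[b]] <- data.frame(
        chrom = m$chrom[hit], pos0 = m$pos0[hit], ref = m$ref[hit],
        alt = BASES[b], germ_alt_reads = gm[hit, b],
        germ_depth = germ_depth[hit], soma_alt_reads = 0L,
        soma_depth = soma_depth[hit], sample_id = sample_id)
  }
  calls <- do.call(rbind, out)
  if (is.null(calls))
    calls <- data.frame(chrom = character(), pos0 = integer(),
                        ref = character(), alt = character(),
                        germ_alt_reads = integer(), germ_depth = integer(),
                        soma_alt_reads = integer(), soma_depth = integer(),
                        sample_id = character())
  calls <- calls[order(calls$chrom, calls$pos0, calls$alt), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Soma-swap negative control
#'
#' Repeats the germline-specific calling rule with the tissue roles
#' exchanged and returns the number of soma-specific calls. On genuine
#' GRC data this count is expected to be zero.
#'
#' @inheritParams call_specific_snvs
#' @return Integer count of soma-specific calls; the calls themselves are
#'   attached as `attr(, "calls")`.
#' @export
negative_control <- function(germ_pileup, soma_pileup, min_germ = 10L,
                             min_soma_depth = 10L,
                             mode = c("alt_reads", "site_depth")) {
  calls <- call_specific_snvs(soma_pileup, germ_pileup, min_germ,
                              min_soma_depth, mode)
  structure(nrow(calls), calls = calls)
}

#' Intersect calls across germline samples
#'
#' A call survives only if the same locus and alternate allele is called in
#' every provided sample; the reported support is the per-sample minimum.
#'
#' @param calls_list list of call data.frames from [call_specific_snvs()],
#'   one per germline sample.
#' @return data.frame of intersected calls (`chrom`, `pos0`, `ref`, `alt`,
#'   `germ_alt_reads` = min across samples, `n_samples`).
#' @export
intersect_samples <- function(calls_list) {
  stopifnot(length(calls_list) >= 1L)
  if (length(calls_list) == 1L) {
    out <- calls_list[[1L]]
    out$n_samples <- 1L
    return(out)
  }
  key <- function(d) paste(d$chrom, d$pos0, d$alt, sep = "\r")
  shared <- Reduce(intersect, lapply(calls_list, key))
  first <- calls_list[[1L]]
  out <- first[key(first) %in% shared, , drop = FALSE]
  if (nrow(out)) {
    for (d in calls_list[-1L]) {
      idx <- match(key(out), key(d))
      out$germ_alt_reads <- pmin(out$germ_alt_reads, d$germ_alt_reads[idx])
    }
  }
  out$sample_id <- NULL
  out$n_samples <- rep(length(calls_list), nrow(out))
  rownames(out) <- NULL
  out
}

#' Per-gene SNV summary and high-confidence flag
#'
#' Tallies germline-specific SNVs per annotated gene and applies the
#' high-confidence union rule: a gene is high-confidence when it carries at
#' least `min_snvs` germline-specific SNVs or belongs to the
#' coverage-amplified gene set.
#'
#' @param calls Call data.frame (typically after [intersect_samples()]).
#' @param annotation Gene annotation data.frame.
#' @param amplified_genes Character vector of coverage-amplified gene ids.
#' @param min_snvs SNV-count threshold (default 5).
#' @return data.frame `gene_id`, `n_specific_snvs`, `amplified`,
#'   `high_confidence`, one row per annotated gene.
#' @export
summarise_genes <- function(calls, annotation, amplified_genes = character(),
                            min_snvs = 5L) {
  n <- integer(nrow(annotation))
  if (nrow(calls)) {
    gr_c <- GenomicRanges::GRanges(calls$chrom,
                                   IRanges::IRanges(calls$pos0 + 1L, width = 1L))
    gr_a <- GenomicRanges::GRanges(annotation$chrom,
                                   IRanges::IRanges(annotation$start + 1L,
                                                    annotation$end))
    hits <- GenomicRanges::countOverlaps(gr_a, gr_c)
    n <- as.integer(hits)
  }
  data.frame(gene_id = annotation$gene_id,
             n_specific_snvs = n,
             amplified = annotation$gene_id %in% amplified_genes,
             high_confidence = n >= min_snvs |
               annotation$gene_id %in% amplified_genes)
}

#' Build soma ('ref') and germline-specific ('alt') consensus sequences
#'
#' For each annotated gene, the ref consensus is the reference sequence of
#' the gene body and the alt consensus is the same sequence with every
#' called alternate base substituted in; the two are equal in length.
#'
#' @param calls Call data.frame.
#' @param reference [Biostrings::DNAStringSet].
#' @param annotation Gene annotation data.frame.
#' @param genes Optional subset of gene ids (default: genes with calls).
#' @return [Biostrings::DNAStringSet] with entries `<gene>_ref` and
#'   `<gene>_alt` per gene.
#' @export
build_consensus <- function(calls, reference, annotation, genes = NULL) {
  if (is.null(genes)) {
    gr_c <- if (nrow(calls))
      GenomicRanges::GRanges(calls$chrom,
                             IRanges::IRanges(calls$pos0 + 1L, width = 1L))
    else GenomicRanges::GRanges()
    gr_a <- GenomicRanges::GRanges(annotation$chrom,
                                   IRanges::IRanges(annotation$start + 1L,
                                                    annotation$end))
    genes <- annotation$gene_id[GenomicRanges::countOverlaps(gr_a, gr_c) > 0]
  }
  ann <- annotation[annotation$gene_id %in% genes, , drop = FALSE]
  seqs <- character(0)
  for (j in seq_len(nrow(ann))) {
    g <- ann[j, ]
    ref_seq <- as.character(Biostrings::subseq(reference[[g$chrom]],
                                               g$start + 1L, g$end))
    alt_chars <- strsplit(ref_seq, "", fixed = TRUE)[[1]]
    cc <- calls[calls$chrom == g$chrom & calls$pos0 >= g$start &
                  calls$pos0 < g$end, , drop = FALSE]
    if (nrow(cc))
      alt_chars[cc$pos0 - g$start + 1L] <- cc$alt
    seqs[paste0(g$gene_id, "_ref")] <- ref_seq
    seqs[paste0(g$gene_id, "_alt")] <- paste(alt_chars, collapse = "")
  }
  Biostrings::DNAStringSet(seqs)
}

#' Verify transcription of germline-specific SNVs in RNA pileups
#'
#' An SNV is transcription-supported when the RNA pileup at its site has at
#' least `min_reads` total reads and an alt/ref read ratio strictly above
#' `min_ratio`. Sites below the read minimum are not evaluated. A gene is
#' flagged expressed when any of its specific SNVs is supported.
#'
#' @param calls Call data.frame.
#' @param rna_pileup RNA pileup data.frame.
#' @param annotation Gene annotation data.frame.
#' @param min_reads Minimum RNA depth at the site (default 100).
#' @param min_ratio Alt/ref ratio threshold (default 0.01, strict).
#' @return list with `snvs` (calls plus `rna_depth`, `rna_alt`, `rna_ref`,
#'   `evaluated`, `supported`) and `genes` (`gene_id`, `expressed`).
#' @export
verify_transcription <- function(calls, rna_pileup, annotation,
                                 min_reads = 100L, min_ratio = 0.01) {
  snvs <- calls
  idx <- match(paste(calls$chrom, calls$pos0),
               paste(rna_pileup$chrom, rna_pileup$pos0))
  rna_mat <- as.matrix(rna_pileup[, BASES])
  depth <- ifelse(is.na(idx), 0L, rowSums(rna_mat)[idx])
  alt <- ifelse(is.na(idx), 0L,
                rna_mat[cbind(idx, match(calls$alt, BASES))])
  refr <- ifelse(is.na(idx), 0L,
                 rna_mat[cbind(idx, match(calls$ref, BASES))])
  snvs$rna_depth <- depth
  snvs$rna_alt <- alt
  snvs$rna_ref <- refr
  snvs$evaluated <- depth >= min_reads
  ratio <- ifelse(refr > 0, alt / refr, ifelse(alt > 0, Inf, 0))
  snvs$supported <- snvs$evaluated & ratio > min_ratio

  gr_c <- if (nrow(snvs))
    GenomicRanges::GRanges(snvs$chrom,
                           IRanges::IRanges(snvs$pos0 + 1L, width = 1L))
  else GenomicRanges::GRanges()
  gr_a <- GenomicRanges::GRanges(annotation$chrom,
                                 IRanges::IRanges(annotation$start + 1L,
                                                  annotation$end))
  expressed <- logical(nrow(annotation))
  if (nrow(snvs)) {
    hits <- GenomicRanges::findOverlaps(gr_a, gr_c)
    sup <- tapply(snvs$supported[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits), any)
    expressed[as.integer(names(sup))] <- unname(sup)
  }
  list(snvs = snvs,
       genes = data.frame(gene_id = annotation$gene_id, expressed = expressed))
}
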