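#' Copy number per haploid genome from read depth
#'
#' Depth-based copy-number estimator:
#' `copies = mean_depth * genome_size / library_bases`. With a library of
#' `library_bases` total sequenced bases spread over a haploid genome of
#' `genome_size` bp, the expected depth of a single-copy locus is
#' `library_bases / genome_size`, so the ratio of observed depth to that
#' expectation is the locus's copies per haploid genome.
#'
#' @param mean_depth Mean per-position read depth over the locus (x-fold).
#' @param library_bases Total sequenced (mapped) bases of the library.
#' @param genome_size Haploid genome size in bp. For soma libraries this is
#'   the assembly size; for germline libraries use
#'   [germline_genome_size()] to include the GRC contribution.
#' @return Copies per haploid genome (vectorised over `mean_depth`).
#' @examples
#' estimate_copy_number(10, 10000, 1000)  # 1.0
#' @export
estimate_copy_number <- function(mean_depth, library_bases, genome_size) {
  if (any(library_bases <= 0)) stop("library_bases must be positive")
  if (any(genome_size <= 0)) stop("genome_size must be positive")
  if (any(mean_depth < 0)) stop("mean_depth must be non-negative")
  mean_depth * genome_size / library_bases
}

#' Per-gene copy-number estimates from a pileup
#'
#' Computes mean per-position depth over each annotated gene body and
#' converts it to copies per haploid genome with [estimate_copy_number()].
#'
#' @param pileup Pileup data.frame (`chrom`, `pos0`, `ref`, `A`, `C`, `G`,
#'   `T`).
#' @param annotation Gene annotation data.frame.
#' @param library_bases Total sequenced bases of the library.
#' @param genome_size Haploid genome size in bp for this tissue.
#' @return data.frame `gene_id`, `mean_depth`, `copies_per_haploid`.
#' @export
gene_copy_number <- function(pileup, annotation, library_bases, genome_size) {
  depth <- pileup$A + pileup$C + pileup$G + pileup$T
  md <- numeric(nrow(annotation))
  for (j in seq_len(nrow(annotation))) {
    g <- annotation[j, ]
    sel <- pileup$chrom == g$chrom & pileup$pos0 >= g$start & pileup$pos0 < g$end
    md[j] <- sum(depth[sel]) / (g$end - g$start)
  }
  data.frame(gene_id = annotation$gene_id, mean_depth = md,
             copies_per_haploid = estimate_copy_number(md, library_bases,
                                                       genome_size))
}

#' GRCs per haploid A-genome set from cytogenetic cell counts
#'
#' In a mixed tissue with `n_germ` tetraploid germline cells carrying two
#' GRCs each and `n_soma` diploid somatic cells carrying none, the average
#' number of GRCs per haploid A-chromosome set is
#' `f = 2*n_germ / (4*n_germ + 2*n_soma)`.
#'
#' @param n_germ Count of germline (FISH-positive) cells.
#' @param n_soma Count of somatic (FISH-negative) cells.
#' @return `f` in `[0, 0.5]`.
#' @examples
#' grc_per_haploid(67, 50)  # ~0.364
#' @export
grc_per_haploid <- function(n_germ, n_soma) {
  if (n_germ < 0 || n_soma < 0) stop("cell counts must be non-negative")
  if (n_germ + n_soma == 0) stop("at least one cell count must be positive")
  2 * n_germ / (4 * n_germ + 2 * n_soma)
}

#' GRC physical size from the synaptonemal-complex length ratio
#'
#' Converts the relative pachytene axis length of the GRC versus a reference
#' chromosome into a physical size: `grc_size = sc_length_ratio *
#' chr_size_mb`.
#'
#' @param sc_length_ratio GRC / reference-chromosome synaptonemal-complex
#'   length ratio.
#' @param chr_size_mb Reference chromosome assembly size in Mb.
#' @return GRC size in Mb.
#' @examples
#' grc_size(1.07, 156.41)  # 167.36 Mb
#' @export
grc_size <- function(sc_length_ratio, chr_size_mb) {
  if (sc_length_ratio <= 0 || chr_size_mb <= 0)
    stop("inputs must be positive")
  sc_length_ratio * chr_size_mb
}

#' Effective germline genome size
#'
#' The germline library samples the A-chromosome assembly plus `f` GRC
#' equivalents, so its effective haploid genome size is
#' `assembly_size + f * grc_size` (all in the same unit).
#'
#' @param assembly_size A-chromosome assembly size.
#' @param f GRCs per haploid genome, see [grc_per_haploid()].
#' @param grc_size GRC size in the same unit as `assembly_size`.
#' @return Effective germline genome size.
#' @export
germline_genome_size <- function(assembly_size, f, grc_size) {
  if (assembly_size <= 0) stop("assembly_size must be positive")
  if (f < 0) stop("f must be non-negative")
  assembly_size + f * grc_size
}

#' Split a transcript's depth profile into high/low coverage segments
#'
#' Genes whose per-position depth varies strongly along the transcript (for
#' example when only part of the gene is GRC-amplified) are split before
#' copy-number estimation. If the coefficient of variation of depth exceeds
#' `cv_threshold`, positions are partitioned by 2-means on depth, contiguity
#' is enforced by merging runs shorter than `min_run` into their longer
#' neighbour, and one row per contiguous segment is returned; otherwise the
#' transcript is a single segment.
#'
#' @param depth Numeric vector of per-position depth over the transcript
#'   (length >= 200).
#' @param cv_threshold Coefficient-of-variation threshold (default 0.5).
#' @param min_run Minimum run length in bp kept as its own segment
#'   (default 50).
#' @return data.frame `start`, `end` (0-based half-open, transcript
#'   coordinates), `mean_depth`, `level` (`"high"`/`"low"`/`"all"`).
#' @export
split_high_variance <- function(depth, cv_threshold = 0.5, min_run = 50L) {
  L <- length(depth)
  if (L < 200) stop("transcript must be at least 200 bp")
  m <- mean(depth)
  one <- data.frame(start = 0L, end = L, mean_depth = m, level = "all")
  if (m == 0) return(one)
  if (stats::sd(depth) / m <= cv_threshold) return(one)

  km <- stats::kmeans(depth, centers = sort(c(min(depth), max(depth))))
  hi_cluster <- which.max(km$centers)
  lab <- km$cluster == hi_cluster
  # enforce contiguity: absorb short runs into their neighbours
  repeat {
    r <- rle(lab)
    if (length(r$lengths) <= 1L || all(r$lengths >= min_run)) break
    k <- which.min(r$lengths)
    r$values[k] <- !r$values[k]
    lab <- inverse.rle(r)
  }
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-length(ends)])
  data.frame(start = as.integer(starts), end = as.integer(ends),
             mean_depth = vapply(seq_along(starts), function(k)
               mean(depth[(starts[k] + 1L):ends[k]]), numeric(1)),
             level = ifelse(r$values, "high", "low"))
}
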