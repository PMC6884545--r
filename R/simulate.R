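BASES <- c("A", "C", "G", "T")

#' Simulate a reference genome and gene annotation
#'
#' Generates per-chromosome sequence with a controllable GC profile and a
#' non-overlapping gene annotation. GC content can vary along chromosomes
#' (a linear gradient) so that downstream GC filtering of coverage windows is
#' exercised on realistic composition heterogeneity.
#'
#' Gene models default to `gene_len` = 5 kb placed on a `gene_len` grid, so an
#' amplified gene spans whole coverage-calling windows, mirroring the
#' multi-kilobase scale of real GRC-amplified blocks. Set
#' `align_genes = FALSE` for arbitrary non-overlapping placement.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Length of each chromosome in bp (>= 50 kb recommended).
#' @param n_genes Total number of genes across chromosomes.
#' @param gc_profile Either a single number (uniform GC fraction) or a list:
#'   `list(kind = "uniform", gc = 0.45)` or
#'   `list(kind = "gradient", from = 0.25, to = 0.65)` (GC varies linearly
#'   from `from` at the chromosome start to `to` at its end, in 1 kb tiles).
#' @param seed Integer seed; output is byte-identical for a fixed seed.
#' @param gene_len Gene length in bp (default 5000).
#' @param align_genes Place genes on a `gene_len` grid (default TRUE).
#'
#' @return list with `reference` (a [Biostrings::DNAStringSet]) and
#'   `annotation` (data.frame `chrom`, `start`, `end`, `gene_id`; 0-based
#'   half-open coordinates).
#' @examples
#' g <- simulate_genome(1, 100e3, 10, gc_profile = 0.45, seed = 7)
#' nrow(g$annotation)
#' @export
simulate_genome <- function(n_chrom = 1L, chrom_len = 100e3, n_genes = 10L,
                            gc_profile = 0.45, seed = 1L,
                            gene_len = 5000L, align_genes = TRUE) {
  stopifnot(n_chrom >= 1, n_genes >= 0, gene_len >= 100)
  if (chrom_len < 50e3) stop("chrom_len must be at least 50 kb")
  if (is.numeric(gc_profile) && length(gc_profile) == 1L)
    gc_profile <- list(kind = "uniform", gc = gc_profile)
  set.seed(seed)

  tile <- 1000L
  seqs <- character(n_chrom)
  for (i in seq_len(n_chrom)) {
    n_tiles <- ceiling(chrom_len / tile)
    gc_tiles <- switch(gc_profile$kind,
      uniform  = rep(gc_profile$gc, n_tiles),
      gradient = seq(gc_profile$from, gc_profile$to, length.out = n_tiles),
      stop("unknown gc_profile kind: ", gc_profile$kind))
    gcv <- rep(gc_tiles, each = tile)[seq_len(chrom_len)]
    u <- stats::runif(chrom_len)
    v <- stats::runif(chrom_len)
    is_gc <- u < gcv
    base <- ifelse(is_gc, ifelse(v < 0.5, "G", "C"),
                          ifelse(v < 0.5, "A", "T"))
    seqs[i] <- paste(base, collapse = "")
  }
  names(seqs) <- paste0("chr", seq_len(n_chrom))
  reference <- Biostrings::DNAStringSet(seqs)

  ann <- data.frame(chrom = character(), start = integer(),
                    end = integer(), gene_id = character())
  if (n_genes > 0) {
    if (align_genes) {
      slots_per_chrom <- floor(chrom_len / gene_len)
      slots <- expand.grid(chrom = names(seqs),
                           slot = seq_len(slots_per_chrom) - 1L,
                           stringsAsFactors = FALSE)
      if (nrow(slots) < n_genes)
        stop("requested genes do not fit: ", n_genes, " genes, ",
             nrow(slots), " available slots")
      pick <- slots[sort(sample.int(nrow(slots), n_genes)), , drop = FALSE]
      ann <- data.frame(chrom = pick$chrom,
                        start = pick$slot * gene_len,
                        end   = pick$slot * gene_len + gene_len,
                        gene_id = sprintf("gene%03d", seq_len(n_genes)))
    } else {
      # random non-overlapping placement via spaced starts
      per_chrom <- diff(floor(seq(0, n_genes, length.out = n_chrom + 1L)))
      rows <- vector("list", n_chrom)
      gid <- 0L
      for (i in seq_len(n_chrom)) {
        k <- per_chrom[i]
        if (k == 0L) next
        free <- chrom_len - k * gene_len
        if (free < 0) stop("requested genes do not fit on ", names(seqs)[i])
        gaps <- diff(c(0, sort(sample.int(free + 1L, k)) - 1L))
        starts <- cumsum(gaps) + (seq_len(k) - 1L) * gene_len
        rows[[i]] <- data.frame(chrom = names(seqs)[i], start = starts,
                                end = starts + gene_len,
                                gene_id = sprintf("gene%03d", gid + seq_len(k)))
        gid <- gid + k
      }
      ann <- do.call(rbind, rows)
      rownames(ann) <- NULL
    }
    ann <- ann[order(ann$chrom, ann$start), , drop = FALSE]
    rownames(ann) <- NULL
  }
  list(reference = reference, annotation = ann)
}

# Per-position allele-count matrix (L x 4, columns ACGT) for `depth` reads of
# the intended base `code`, with sequencing errors moved uniformly onto the
# three other bases.
.count_matrix <- function(code, depth, error_rate) {
  L <- length(depth)
  M <- matrix(0L, L, 4L)
  err <- if (error_rate > 0) stats::rbinom(L, depth, error_rate) else integer(L)
  M[cbind(seq_len(L), code)] <- depth - err
  idx <- which(err > 0L)
  if (length(idx)) {
    pos_rep <- rep.int(idx, err[idx])
    choice <- sample.int(3L, length(pos_rep), replace = TRUE)
    nonref <- rbind(c(2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 4L), c(1L, 2L, 3L))
    bcode <- nonref[cbind(code[pos_rep], choice)]
    M <- M + matrix(tabulate((pos_rep - 1L) * 4L + bcode, nbins = L * 4L),
                    ncol = 4L, byrow = TRUE)
  }
  M
}

.matrix_to_pileup <- function(chrom, M, ref_chars) {
  data.frame(chrom = chrom, pos0 = seq_len(nrow(M)) - 1L, ref = ref_chars,
             A = M[, 1L], C = M[, 2L], G = M[, 3L], T = M[, 4L])
}

#' Simulate paired germline and soma pileups under a GRC model
#'
#' Emits per-position allele counts for a soma library (diploid A chromosomes
#' only) and a germline library (A chromosomes plus GRC paralogs of the genes
#' in the model). Read depth is Poisson around the library mean; a GRC gene
#' with copy number `c` adds Poisson(`depth_germ * f * c`) reads over its
#' body, so germline depth there has expectation `depth_soma * (1 + f*c)`
#' when the libraries are sequenced to the same depth. Each GRC gene carries
#' `round(p_div * length)` divergence sites, chosen uniformly within the gene
#' body, at which all GRC-derived reads carry a fixed alternate base; the
#' expected germline alternate-allele fraction there is
#' `f*c / (1 + f*c)`. Sequencing errors fall uniformly on the three
#' non-template bases. The soma pileup contains no GRC-derived alleles by
#' construction.
#'
#' Both libraries share a locus-level depth bias: a per-kilobase
#' multiplicative factor (gamma, mean 1, standard deviation `bias_sd`)
#' emulating mappability and composition effects on library coverage. The
#' bias is identical between tissues, so it cancels in germline/soma
#' coverage ratios while giving the tight inter-tissue window correlation
#' seen in real paired libraries.
#'
#' @param reference [Biostrings::DNAStringSet] from [simulate_genome()].
#' @param annotation Gene annotation data.frame (chrom, start, end, gene_id).
#' @param grc A [grc_model()]; every modelled gene must be annotated.
#' @param depth_soma Mean soma depth (x-fold), > 0.
#' @param depth_germ Mean germline baseline depth; defaults to `depth_soma`.
#' @param error_rate Per-base sequencing error rate, < 0.01.
#' @param seed Integer seed.
#' @param bias_sd Standard deviation of the shared per-kilobase depth bias
#'   (default 0.05; 0 disables it).
#' @param divergence Optional divergence-site table (`gene_id`, `chrom`,
#'   `pos0`, `ref`, `alt`, as in `truth$snvs`) to reuse across simulated
#'   individuals: replicate germline samples of the same population carry
#'   the same GRC divergence alleles. Default: sites are drawn fresh.
#'
#' @return list of class `grc_simulation`: `reference`, `annotation`,
#'   `soma_pileup`, `germline_pileup` (data.frames chrom, pos0, ref,
#'   A, C, G, T), `library_bases` (named total sequenced bases per tissue),
#'   `genome_size` (named bp per tissue; germline includes `f` times the
#'   simulated GRC span), and `truth` (the model plus the data.frame of
#'   divergence sites `gene_id`, `chrom`, `pos0`, `ref`, `alt`).
#' @export
simulate_pileups <- function(reference, annotation, grc,
                             depth_soma = 20, depth_germ = depth_soma,
                             error_rate = 1e-3, seed = 1L,
                             bias_sd = 0.05, divergence = NULL) {
  stopifnot(inherits(grc, "grc_model"), depth_soma > 0, depth_germ > 0)
  if (error_rate >= 0.01) stop("error_rate must be below 0.01")
  if (nrow(grc$genes) && !all(grc$genes$gene_id %in% annotation$gene_id))
    stop("grc model references unannotated genes")
  set.seed(seed)
  f <- grc$grc_fraction

  soma_list <- germ_list <- vector("list", length(reference))
  truth_rows <- list()
  for (i in seq_along(reference)) {
    chrom <- names(reference)[i]
    ref_chars <- strsplit(as.character(reference[[i]]), "", fixed = TRUE)[[1]]
    code <- match(ref_chars, BASES)
    L <- length(code)

    bias <- if (bias_sd > 0) {
      shape <- 1 / bias_sd^2
      rep(stats::rgamma(ceiling(L / 1000), shape = shape, rate = shape),
          each = 1000L)[seq_len(L)]
    } else rep(1, L)
    soma_M <- .count_matrix(code, stats::rpois(L, depth_soma * bias), error_rate)
    germ_M <- .count_matrix(code, stats::rpois(L, depth_germ * bias), error_rate)

    gmod <- merge(grc$genes, annotation[annotation$chrom == chrom, ],
                  by = "gene_id")
    for (j in seq_len(nrow(gmod))) {
      g <- gmod[j, ]
      span <- (g$start + 1L):g$end          # 1-based rows of the matrices
      glen <- length(span)
      gcode <- code[span]                    # GRC template = ref, then diverge
      if (is.null(divergence)) {
        n_div <- round(g$p_div * glen)
        div_at <- if (n_div > 0) sort(sample.int(glen, n_div)) else integer(0)
        for (d in div_at) gcode[d] <- sample(setdiff(1:4, gcode[d]), 1L)
      } else {
        dv <- divergence[divergence$gene_id == g$gene_id, , drop = FALSE]
        div_at <- dv$pos0 - g$start + 1L
        gcode[div_at] <- match(dv$alt, BASES)
      }
      if (length(div_at))
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          gene_id = g$gene_id, chrom = chrom,
          pos0 = g$start + div_at - 1L,
          ref = ref_chars[span][div_at], alt = BASES[gcode[div_at]])
      extra <- stats::rpois(glen, depth_germ * f * g$copies * bias[span])
      germ_M[span, ] <- germ_M[span, ] + .count_matrix(gcode, extra, error_rate)
    }
    soma_list[[i]] <- .matrix_to_pileup(chrom, soma_M, ref_chars)
    germ_list[[i]] <- .matrix_to_pileup(chrom, germ_M, ref_chars)
  }

  soma_pileup <- do.call(rbind, soma_list)
  germline_pileup <- do.call(rbind, germ_list)
  rownames(soma_pileup) <- rownames(germline_pileup) <- NULL
  truth_snvs <- if (length(truth_rows)) {
    out <- do.call(rbind, truth_rows); rownames(out) <- NULL; out
  } else data.frame(gene_id = character(), chrom = character(),
                    pos0 = integer(), ref = character(), alt = character())

  total_len <- sum(Biostrings::width(reference))
  grc_span <- if (nrow(grc$genes)) {
    ann <- merge(grc$genes, annotation, by = "gene_id")
    sum(ann$copies * (ann$end - ann$start))
  } else 0
  structure(list(
    reference = reference, annotation = annotation,
    soma_pileup = soma_pileup, germline_pileup = germline_pileup,
    library_bases = c(soma = sum(soma_pileup[, BASES]),
                      germline = sum(germline_pileup[, BASES])),
    genome_size = c(soma = total_len, germline = total_len + f * grc_span),
    truth = list(grc = grc, snvs = truth_snvs)),
    class = "grc_simulation")
}

#' Simulate an RNA pileup with GRC transcript expression
#'
#' Produces per-position allele counts for RNA reads over annotated gene
#' bodies. Expressed GRC genes transcribe a mixture of the A-chromosomal
#' template and the GRC (divergent) template: a fraction `alt_fraction` of
#' reads carries the alternate base at the simulation's truth divergence
#' sites.
#'
#' @param sim A `grc_simulation` from [simulate_pileups()].
#' @param expressed_genes Character vector of expressed gene ids; defaults to
#'   the model's GRC genes.
#' @param depth Mean RNA depth over expressed genes.
#' @param alt_fraction Fraction of transcripts from the GRC paralog.
#' @param error_rate Per-base error rate.
#' @param seed Integer seed.
#' @return RNA pileup data.frame (chrom, pos0, ref, A, C, G, T) restricted to
#'   expressed gene bodies.
#' @export
simulate_rna_pileup <- function(sim, expressed_genes = sim$truth$grc$genes$gene_id,
                                depth = 200, alt_fraction = 0.3,
                                error_rate = 0, seed = 1L) {
  stopifnot(inherits(sim, "grc_simulation"), depth > 0,
            alt_fraction >= 0, alt_fraction <= 1)
  set.seed(seed)
  ann <- sim$annotation[sim$annotation$gene_id %in% expressed_genes, ,
                        drop = FALSE]
  rows <- vector("list", nrow(ann))
  for (j in seq_len(nrow(ann))) {
    g <- ann[j, ]
    chrom_seq <- as.character(sim$reference[[g$chrom]])
    span <- (g$start + 1L):g$end
    ref_chars <- strsplit(substr(chrom_seq, g$start + 1L, g$end), "",
                          fixed = TRUE)[[1]]
    ref_code <- match(ref_chars, BASES)
    alt_code <- ref_code
    tr <- sim$truth$snvs[sim$truth$snvs$gene_id == g$gene_id, , drop = FALSE]
    if (nrow(tr))
      alt_code[tr$pos0 - g$start + 1L] <- match(tr$alt, BASES)
    is_grc <- g$gene_id %in% sim$truth$grc$genes$gene_id
    frac <- if (is_grc) alt_fraction else 0
    M <- .count_matrix(ref_code, stats::rpois(length(span), depth * (1 - frac)),
                       error_rate)
    if (frac > 0)
      M <- M + .count_matrix(alt_code, stats::rpois(length(span), depth * frac),
                             error_rate)
    p <- .matrix_to_pileup(g$chrom, M, ref_chars)
    p$pos0 <- p$pos0 + g$start
    rows[[j]] <- p
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a gene-by-tissue expression table
#'
#' Each expressed gene receives strictly positive expression in every tissue
#' with a unique arg-max tissue drawn from `tissue_probs`; a stated fraction
#' of genes is unexpressed (zero everywhere) to exercise the background
#' exclusion rule of enrichment testing.
#'
#' @param n_genes Number of genes.
#' @param tissue_probs Named numeric vector of probabilities (summing to 1)
#'   that a gene's maximal expression falls in each tissue. The default panel
#'   is brain, heart, kidney, liver and gonad for each sex (testis/ovary).
#' @param seed Integer seed.
#' @param frac_unexpressed Fraction of genes unexpressed in all tissues.
#' @param gene_ids Optional gene identifiers (length `n_genes`).
#' @return data.frame with `gene_id` and one expression column per tissue.
#' @export
simulate_expression_table <- function(n_genes,
                                      tissue_probs = default_tissue_probs(),
                                      seed = 1L, frac_unexpressed = 0.1,
                                      gene_ids = sprintf("gene%04d", seq_len(n_genes))) {
  stopifnot(n_genes >= 0, abs(sum(tissue_probs) - 1) < 1e-8,
            !is.null(names(tissue_probs)))
  tissues <- names(tissue_probs)
  if (n_genes == 0)
    return(stats::setNames(
      data.frame(matrix(numeric(0), 0, length(tissues) + 1L)),
      c("gene_id", tissues)))
  set.seed(seed)
  expr <- matrix(stats::runif(n_genes * length(tissues), 0.05, 1),
                 n_genes, length(tissues), dimnames = list(NULL, tissues))
  max_t <- sample.int(length(tissues), n_genes, replace = TRUE,
                      prob = tissue_probs)
  expr[cbind(seq_len(n_genes), max_t)] <- apply(expr, 1, max) * 1.5 + 0.1
  unexpr <- sample.int(n_genes, round(frac_unexpressed * n_genes))
  expr[unexpr, ] <- 0
  cbind(data.frame(gene_id = gene_ids), as.data.frame(expr))
}

#' Default tissue panel probabilities
#'
#' Five male and five female tissues (brain, heart, kidney, liver, gonad per
#' sex). The default arg-max probabilities follow the chicken panel
#' proportions used as the enrichment background: 1376/7918 testis-max and
#' 685/7918 ovary-max, with the remainder spread over somatic tissues.
#' @return Named numeric vector summing to 1.
#' @export
default_tissue_probs <- function() {
  p_testis <- 1376 / 7918
  p_ovary <- 685 / 7918
  soma <- c("brain_m", "heart_m", "kidney_m", "liver_m",
            "brain_f", "heart_f", "kidney_f", "liver_f")
  c(stats::setNames(rep((1 - p_testis - p_ovary) / length(soma), length(soma)),
                    soma),
    testis = p_testis, ovary = p_ovary)
}
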