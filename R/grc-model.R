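#' GRC model: dosage and divergence parameters of a germline-restricted chromosome
#'
#' A `grc_model` describes the germline-restricted chromosome (GRC) carried by
#' the simulated individual: how many GRC equivalents are present per haploid
#' A-chromosome set in the sequenced germline tissue (`grc_fraction`, the
#' cytogenetic quantity *f*), and which annotated genes have GRC-linked
#' paralogs, each with an amplification copy number and a per-site divergence
#' rate from its A-chromosomal paralog.
#'
#' The expected germline/soma depth ratio over a GRC gene with copy number `c`
#' is `1 + f * c`: one A-chromosomal copy per haploid genome plus `f * c` GRC
#' copies.
#'
#' @param grc_fraction GRC copies per haploid A-genome set in the germline
#'   tissue (dimensionless). Mixed germ/soma tissue such as testis gives
#'   values below the all-germline limit of 0.5; the zebra finch estimate is
#'   0.364. Must lie in `[0, 0.5]`.
#' @param genes data.frame with columns `gene_id` (character), `copies`
#'   (positive integer, GRC copy number of the gene) and `p_div` (per-site
#'   divergence rate of the GRC paralog from the A paralog, in `[0, 0.2)`).
#'   May have zero rows for a GRC-free null model.
#' @param grc_size_mb Physical size of the GRC in Mb, used for germline
#'   genome-size correction in copy-number estimation. Optional.
#'
#' @return An object of class `grc_model`.
#' @examples
#' grc_model(0.364, data.frame(gene_id = "gene001", copies = 9, p_div = 0.01))
#' @export
grc_model <- function(grc_fraction, genes = data.frame(gene_id = character(),
                                                       copies = integer(),
                                                       p_div = numeric()),
                      grc_size_mb = NULL) {
  stopifnot(is.numeric(grc_fraction), length(grc_fraction) == 1L)
  if (grc_fraction < 0 || grc_fraction > 0.5)
    stop("grc_fraction must lie in [0, 0.5]")
  genes <- as.data.frame(genes)
  req <- c("gene_id", "copies", "p_div")
  if (!all(req %in% names(genes)))
    stop("genes must have columns gene_id, copies, p_div")
  if (nrow(genes)) {
    if (any(genes$copies < 1) || any(genes$copies != round(genes$copies)))
      stop("copies must be positive integers")
    if (any(genes$p_div < 0 | genes$p_div >= 0.2))
      stop("p_div must lie in [0, 0.2)")
    if (anyDuplicated(genes$gene_id))
      stop("duplicated gene_id in grc genes")
  }
  structure(list(grc_fraction = grc_fraction,
                 genes = genes,
                 grc_size_mb = grc_size_mb),
            class = "grc_model")
}

#' @export
print.grc_model <- function(x, ...) {
  cat("GRC model: f =", x$grc_fraction, "|", nrow(x$genes), "GRC-linked gene(s)")
  if (!is.null(x$grc_size_mb)) cat(" | size", x$grc_size_mb, "Mb")
  cat("\n")
  invisible(x)
}
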