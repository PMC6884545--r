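# Shared fixtures, built once per test run.

# A hand-rolled pileup row set for rule-level tests.
make_pileup <- function(chrom, pos0, ref, A = 0L, C = 0L, G = 0L, T = 0L) {
  data.frame(chrom = chrom, pos0 = pos0, ref = ref, A = A, C = C, G = G, T = T)
}

# Uniform-depth pileup over a reference: every position `depth` reads of ref.
uniform_pileup <- function(reference, depth) {
  out <- lapply(seq_along(reference), function(i) {
    chars <- strsplit(as.character(reference[[i]]), "", fixed = TRUE)[[1]]
    p <- make_pileup(names(reference)[i], seq_along(chars) - 1L, chars)
    for (b in c("A", "C", "G", "T")) p[[b]] <- ifelse(p$ref == b, depth, 0L)
    p
  })
  do.call(rbind, out)
}

# Medium simulated dataset shared across module tests: 600 kb, 30 genes,
# 3 GRC genes spanning the copy-number range, error rate 1e-3, 20x depth.
fixture_genome <- simulate_genome(1, 600e3, 30, gc_profile = 0.45, seed = 11)
fixture_grc <- grc_model(
  0.364,
  data.frame(gene_id = c("gene003", "gene012", "gene025"),
             copies = c(9L, 50L, 308L), p_div = 0.01),
  grc_size_mb = 167.3)
fixture_sim <- simulate_pileups(fixture_genome$reference,
                                fixture_genome$annotation, fixture_grc,
                                depth_soma = 20, error_rate = 1e-3, seed = 12)
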