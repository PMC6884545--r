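test_that("germline-specific calling applies the support and absence rules", {
  germ <- make_pileup("chr1", 0:3, c("A", "A", "A", "A"),
                      A = c(28L, 31L, 30L, 25L), G = c(12L, 9L, 10L, 15L))
  soma <- make_pileup("chr1", 0:3, c("A", "A", "A", "A"),
                      A = c(15L, 30L, 29L, 5L), G = c(0L, 0L, 1L, 0L))
  calls <- call_specific_snvs(germ, soma)
  # pos 0: germ alt 12, soma alt 0/15         -> called
  # pos 1: germ alt 9 (below threshold)       -> not called
  # pos 2: soma alt 1 ("found in soma")       -> not called
  # pos 3: soma depth 5 < 10 (not evaluable)  -> not called
  expect_equal(calls$pos0, 0L)
  expect_equal(calls$alt, "G")
  expect_equal(calls$germ_alt_reads, 12L)
  expect_true(all(calls$soma_alt_reads == 0L))

  # swapped tissues at the called site yield nothing (asymmetry)
  expect_equal(as.integer(negative_control(germ, soma)), 0L)

  # site-depth reading calls any supported alt at >= min_germ site depth
  calls_sd <- call_specific_snvs(germ, soma, mode = "site_depth")
  expect_setequal(calls_sd$pos0, c(0L, 1L))
})

test_that("calls shrink monotonically as the support threshold rises", {
  germ <- fixture_sim$germline_pileup
  soma <- fixture_sim$soma_pileup
  n_prev <- Inf
  for (m in c(5L, 10L, 20L, 40L)) {
    n <- nrow(call_specific_snvs(germ, soma, min_germ = m))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("no call ever carries soma alternate support and the swap control is clean", {
  calls <- call_specific_snvs(fixture_sim$germline_pileup,
                              fixture_sim$soma_pileup)
  expect_true(all(calls$soma_alt_reads == 0L))
  expect_gt(nrow(calls), 0L)
  expect_equal(as.integer(negative_control(fixture_sim$germline_pileup,
                                           fixture_sim$soma_pileup)), 0L)
})

test_that("sample intersection keeps only universally supported calls", {
  a <- make_pileup("chr1", c(10L, 20L), "A", A = 30L, C = c(15L, 12L))
  b <- make_pileup("chr1", c(10L, 20L), "A", A = 30L)
  soma <- make_pileup("chr1", c(10L, 20L), "A", A = 30L)
  ca <- call_specific_snvs(a, soma, sample_id = "s1")
  cb <- call_specific_snvs(b, soma, sample_id = "s2")
  expect_equal(nrow(ca), 2L)
  expect_equal(nrow(cb), 0L)
  expect_equal(nrow(intersect_samples(list(ca, cb))), 0L)
  expect_equal(nrow(intersect_samples(list(ca, ca))), 2L)
  expect_equal(nrow(intersect_samples(list(ca))), 2L)

  # replicate individuals sharing the GRC divergence truth retain them all
  sims <- lapply(1:3, function(s)
    simulate_pileups(fixture_genome$reference, fixture_genome$annotation,
                     fixture_grc, depth_soma = 20, error_rate = 1e-3,
                     seed = 100 + s, divergence = fixture_sim$truth$snvs))
  per_sample <- lapply(sims, function(s)
    call_specific_snvs(s$germline_pileup, s$soma_pileup,
                       sample_id = "rep"))
  inter <- intersect_samples(per_sample)
  truth_keys <- paste(fixture_sim$truth$snvs$chrom, fixture_sim$truth$snvs$pos0)
  expect_gt(mean(truth_keys %in% paste(inter$chrom, inter$pos0)), 0.95)
  expect_equal(unique(inter$n_samples), 3L)
})

test_that("gene summaries implement the high-confidence union rule", {
  ann <- data.frame(chrom = "chr1", start = c(0L, 1000L, 2000L),
                    end = c(1000L, 2000L, 3000L),
                    gene_id = c("five", "four", "amponly"))
  calls <- make_pileup("chr1", c(0:4, 1000:1003), "A", A = 0L)[, 1:3]
  calls$alt <- "G"
  s <- summarise_genes(calls, ann, amplified_genes = "amponly")
  expect_equal(s$n_specific_snvs, c(5L, 4L, 0L))
  expect_equal(s$high_confidence, c(TRUE, FALSE, TRUE))

  s0 <- summarise_genes(calls[0, ], ann, amplified_genes = "amponly")
  expect_equal(s0$high_confidence, c(FALSE, FALSE, TRUE))
})

test_that("consensus pairs differ exactly at the called sites", {
  ref <- Biostrings::DNAStringSet(c(chr1 = paste(rep("A", 50e3), collapse = "")))
  ann <- data.frame(chrom = "chr1", start = 100L, end = 200L, gene_id = "g1")
  calls <- data.frame(chrom = "chr1", pos0 = c(110L, 150L, 199L),
                      ref = "A", alt = c("C", "G", "T"))
  cons <- build_consensus(calls, ref, ann)
  expect_setequal(names(cons), c("g1_ref", "g1_alt"))
  r <- strsplit(as.character(cons[["g1_ref"]]), "")[[1]]
  a <- strsplit(as.character(cons[["g1_alt"]]), "")[[1]]
  expect_equal(length(r), 100L)
  expect_equal(sum(r != a), 3L)
  expect_equal(a[c(11L, 51L, 100L)], c("C", "G", "T"))

  cons0 <- build_consensus(calls[0, ], ref, ann, genes = "g1")
  expect_equal(as.character(cons0[["g1_ref"]]), as.character(cons0[["g1_alt"]]))
})

test_that("alt consensus recovers simulated divergence sites at depth", {
  calls <- call_specific_snvs(fixture_sim$germline_pileup,
                              fixture_sim$soma_pileup)
  tr <- fixture_sim$truth$snvs
  cons <- build_consensus(calls, fixture_genome$reference,
                          fixture_genome$annotation,
                          genes = unique(tr$gene_id))
  recovered <- 0L
  for (g in unique(tr$gene_id)) {
    a <- fixture_genome$annotation[fixture_genome$annotation$gene_id == g, ]
    alt <- strsplit(as.character(cons[[paste0(g, "_alt")]]), "")[[1]]
    tg <- tr[tr$gene_id == g, ]
    recovered <- recovered + sum(alt[tg$pos0 - a$start + 1L] == tg$alt)
  }
  expect_gt(recovered / nrow(tr), 0.95)
})

test_that("transcription verification applies the read and ratio thresholds", {
  calls <- data.frame(chrom = "chr1", pos0 = c(10L, 20L, 30L), ref = "A",
                      alt = "G")
  # site 10: depth 100, alt/ref 1/99 > 1%   -> supported
  # site 20: depth 99                       -> not evaluated
  # site 30: depth 200, alt/ref 1/199 < 1%  -> evaluated, unsupported
  rna <- make_pileup("chr1", c(10L, 20L, 30L), "A",
                     A = c(99L, 98L, 199L), G = c(1L, 1L, 1L))
  ann <- data.frame(chrom = "chr1", start = c(0L, 25L), end = c(25L, 50L),
                    gene_id = c("gA", "gB"))
  v <- verify_transcription(calls, rna, ann)
  expect_equal(v$snvs$evaluated, c(TRUE, FALSE, TRUE))
  expect_equal(v$snvs$supported, c(TRUE, FALSE, FALSE))
  expect_equal(v$genes$expressed, c(TRUE, FALSE))
})

test_that("expressed GRC genes are transcription-supported in simulated RNA", {
  rna <- simulate_rna_pileup(fixture_sim, depth = 200, alt_fraction = 0.3,
                             seed = 9)
  calls <- call_specific_snvs(fixture_sim$germline_pileup,
                              fixture_sim$soma_pileup)
  v <- verify_transcription(calls, rna, fixture_genome$annotation)
  grc_ids <- fixture_grc$genes$gene_id
  expect_true(all(v$genes$expressed[v$genes$gene_id %in% grc_ids]))
  expect_false(any(v$genes$expressed[!v$genes$gene_id %in% grc_ids]))
})
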