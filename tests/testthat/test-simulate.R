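test_that("genome simulation is deterministic and respects sizing", {
  g1 <- simulate_genome(1, 100e3, 10, gc_profile = 0.45, seed = 7)
  g2 <- simulate_genome(1, 100e3, 10, gc_profile = 0.45, seed = 7)
  expect_identical(as.character(g1$reference), as.character(g2$reference))
  expect_identical(g1$annotation, g2$annotation)
  expect_equal(nrow(g1$annotation), 10L)
  # gene intervals are disjoint
  a <- g1$annotation[order(g1$annotation$start), ]
  expect_true(all(a$start[-1] >= a$end[-nrow(a)]))

  g0 <- simulate_genome(2, 200e3, 0, gc_profile = 0.45, seed = 7)
  expect_equal(nrow(g0$annotation), 0L)
  expect_equal(length(g0$reference), 2L)
  expect_equal(unname(Biostrings::width(g0$reference)), c(200e3, 200e3))

  expect_error(simulate_genome(1, 50e3, 100, seed = 1), "do not fit")
  expect_error(simulate_genome(1, 10e3, 1, seed = 1), "50 kb")
})

test_that("GC gradient produces windows beyond both filter bounds", {
  g <- simulate_genome(1, 100e3, 10,
                       gc_profile = list(kind = "gradient",
                                         from = 0.25, to = 0.65), seed = 7)
  p0 <- uniform_pileup(g$reference, 1L)
  w <- window_depths(p0, p0, g$reference, 5000L)
  expect_true(any(w$gc < 0.30))
  expect_true(any(w$gc > 0.60))
})

test_that("germline dosage and divergence-allele fractions match the GRC model", {
  ann <- fixture_genome$annotation
  germ <- fixture_sim$germline_pileup
  soma <- fixture_sim$soma_pileup
  depth_of <- function(p) rowSums(p[, c("A", "C", "G", "T")])

  # expected germline depth over a GRC gene is depth_soma * (1 + f*c)
  for (k in seq_len(nrow(fixture_grc$genes))) {
    g <- merge(fixture_grc$genes[k, ], ann)
    sel <- germ$chrom == g$chrom & germ$pos0 >= g$start & germ$pos0 < g$end
    expected <- 20 * (1 + 0.364 * g$copies)
    expect_lt(abs(mean(depth_of(germ[sel, ])) - expected) / expected, 0.05)
  }

  # divergence-allele fraction at truth sites ~ f*c/(1+f*c) for c = 308
  tr <- fixture_sim$truth$snvs[fixture_sim$truth$snvs$gene_id == "gene025", ]
  M <- as.matrix(germ[, c("A", "C", "G", "T")])
  i <- match(paste(tr$chrom, tr$pos0), paste(germ$chrom, germ$pos0))
  frac <- mean(M[cbind(i, match(tr$alt, colnames(M)))] / rowSums(M[i, ]))
  expect_lt(abs(frac - 0.364 * 308 / (1 + 0.364 * 308)), 0.02)

  # truth SNVs all lie inside GRC gene bodies
  tr_all <- merge(fixture_sim$truth$snvs, ann, by = c("gene_id", "chrom"))
  expect_true(all(tr_all$pos0 >= tr_all$start & tr_all$pos0 < tr_all$end))
  expect_true(all(fixture_sim$truth$snvs$gene_id %in% fixture_grc$genes$gene_id))
})

test_that("soma pileup carries no non-error alternate alleles at error rate 0", {
  g <- simulate_genome(1, 60e3, 4, gc_profile = 0.45, seed = 2)
  grc <- grc_model(0.364, data.frame(gene_id = "gene001", copies = 5L,
                                     p_div = 0.01))
  sim <- simulate_pileups(g$reference, g$annotation, grc, depth_soma = 10,
                          error_rate = 0, seed = 3)
  p <- sim$soma_pileup
  M <- as.matrix(p[, c("A", "C", "G", "T")])
  alt_reads <- rowSums(M) - M[cbind(seq_len(nrow(M)), match(p$ref, colnames(M)))]
  expect_true(all(alt_reads == 0))
})

test_that("a GRC-free model yields tissues that differ only by sampling noise", {
  g <- simulate_genome(1, 600e3, 10, gc_profile = 0.45, seed = 5)
  sim <- simulate_pileups(g$reference, g$annotation, grc_model(0.364),
                          depth_soma = 15, error_rate = 1e-3, seed = 6)
  res <- call_grc_windows(sim$germline_pileup, sim$soma_pileup,
                          sim$reference, g$annotation)
  expect_equal(sum(res$windows$amplified), 0L)
  expect_equal(res$n_soma_excess, 0L)
  expect_length(res$genes, 0L)
})

test_that("expression tables honour tissue probabilities and exclusions", {
  all_testis <- simulate_expression_table(
    100, tissue_probs = c(testis = 1), seed = 1, frac_unexpressed = 0.1)
  bg <- build_background(all_testis)
  expect_true(all(bg$max_tissue == "testis"))
  expect_equal(nrow(bg), 90L)

  # arg-max counts follow the panel probabilities (binomial check)
  et <- simulate_expression_table(7918, seed = 3, frac_unexpressed = 0)
  bg <- build_background(et)
  k <- sum(bg$max_tissue == "testis")
  p <- 1376 / 7918
  expect_lt(abs(k - 7918 * p), 3 * sqrt(7918 * p * (1 - p)))

  empty <- simulate_expression_table(0)
  expect_equal(nrow(empty), 0L)
})

test_that("simulated gene trees have one alt tip and the full ref panel", {
  ladder <- default_species_ladder()
  ref_tips <- c(ladder$estrildids, ladder$outer_oscines, ladder$outgroup)
  for (s in 1:5) {
    tr <- simulate_gene_tree(insertion_branch = s, seed = s)
    expect_equal(sum(tr$tip.label == "alt"), 1L)
    expect_true(all(ref_tips %in% tr$tip.label))
  }
  expect_error(simulate_gene_tree(insertion_branch = 7), "unknown stratum")

  # stratum 1: alt sister to the clade of all oscine ref tips
  t1 <- simulate_gene_tree(insertion_branch = 1, seed = 1)
  sis <- ape::extract.clade(t1, ape::getMRCA(t1, c("alt", ladder$focal)))
  expect_setequal(setdiff(sis$tip.label, "alt"),
                  c(ladder$estrildids, ladder$outer_oscines))
  # stratum 5: alt sister to the focal subspecies tip only
  t5 <- simulate_gene_tree(insertion_branch = 5, seed = 1)
  sis <- ape::extract.clade(t5, ape::getMRCA(t5, c("alt", ladder$focal)))
  expect_setequal(sis$tip.label, c("alt", ladder$focal))
})

test_that("grc_model validates its invariants", {
  expect_error(grc_model(0.7), "grc_fraction")
  expect_error(grc_model(0.3, data.frame(gene_id = "g", copies = 0L,
                                         p_div = 0.01)), "copies")
  expect_error(grc_model(0.3, data.frame(gene_id = "g", copies = 2L,
                                         p_div = 0.25)), "p_div")
  expect_error(
    simulate_pileups(fixture_genome$reference, fixture_genome$annotation,
                     grc_model(0.3, data.frame(gene_id = "nope", copies = 2L,
                                               p_div = 0.01)), seed = 1),
    "unannotated")
})
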