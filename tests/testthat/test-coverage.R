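test_that("window tiling covers every position exactly once", {
  ref <- Biostrings::DNAStringSet(c(chrA = paste(rep("ACGT", ceiling(12345 / 4)),
                                                 collapse = "")))
  ref <- Biostrings::subseq(ref, 1, 12345)
  p <- uniform_pileup(ref, 10L)
  w <- window_depths(p, p, ref, 5000L)
  expect_equal(w$start, c(0L, 5000L, 10000L))
  expect_equal(w$end, c(5000L, 10000L, 12345L))
  expect_equal(sum(w$size), 12345L)
  expect_true(all(w$depth_germ == 10))
  expect_true(all(w$depth_soma == 10))
})

test_that("depth normalisation rescales by the soma/germline total ratio", {
  ref <- fixture_genome$reference
  p10 <- uniform_pileup(ref, 10L)
  p20 <- uniform_pileup(ref, 20L)
  w <- window_depths(p20, p10, ref, 5000L)   # germ sequenced 2x deeper
  wn <- depth_normalise(w)
  expect_equal(attr(wn, "norm_factor"), 0.5)
  expect_true(all(abs(wn$depth_germ - 10) < 1e-12))

  weq <- depth_normalise(window_depths(p10, p10, ref, 5000L))
  expect_equal(weq$depth_germ, w$depth_soma)

  w0 <- w
  w0$depth_soma <- 0
  expect_error(depth_normalise(w0), "zero total depth")
})

test_that("slope correction recovers a global germline excess exactly", {
  ref <- fixture_genome$reference
  soma <- fixture_sim$soma_pileup
  germ3 <- soma
  for (b in c("A", "C", "G", "T")) germ3[[b]] <- soma[[b]] * 3L
  w <- window_depths(germ3, soma, ref, 5000L)
  # skip library normalisation to isolate the slope step
  fit <- remove_outliers_and_fit(w)
  expect_equal(fit$slope, 3, tolerance = 1e-10)
  expect_lt(max(abs(fit$windows$depth_germ - fit$windows$depth_soma)), 1e-8)

  wc <- w
  wc$depth_soma <- 7
  expect_error(remove_outliers_and_fit(wc), "constant")
  expect_error(remove_outliers_and_fit(w[1:50, ]), "100 windows")
})

test_that("slope-corrected tissues are tightly correlated outside GRC windows", {
  res <- call_grc_windows(fixture_sim$germline_pileup, fixture_sim$soma_pileup,
                          fixture_genome$reference, fixture_genome$annotation)
  w <- res$windows[!res$windows$amplified & !res$windows$outlier_removed, ]
  expect_gt(stats::cor(w$depth_germ, w$depth_soma), 0.95)
})

test_that("amplification calling applies threshold, GC and block rules", {
  # constructed windows: flat 1:1 background plus targeted deviations
  n <- 200
  w <- data.frame(chrom = "chr1", start = (seq_len(n) - 1L) * 5000L,
                  end = seq_len(n) * 5000L, size = 5000L,
                  depth_germ = 20, depth_soma = 20, gc = 0.45,
                  outlier_removed = FALSE, low_coverage = FALSE,
                  gc_fail = FALSE, log2_ratio = NA_real_, amplified = FALSE)
  w$depth_germ[50] <- 80    # exactly 4-fold: log2 = 2, inclusive threshold
  w$depth_germ[70] <- 200   # 10-fold but GC out of bounds
  w$gc[70] <- 0.25
  w$depth_germ[80:81] <- 100  # adjacent called windows -> one 10 kb block
  res <- call_amplified(w)
  expect_true(res$windows$amplified[50])
  expect_false(res$windows$amplified[70])
  expect_true(res$windows$gc_fail[70])
  expect_true(all(res$windows$amplified[80:81]))
  blk <- res$blocks[res$blocks$start == 80 * 5000 - 5000, ]
  expect_equal(blk$n_windows, 2L)
  expect_equal(blk$end - blk$start, 10000L)
  expect_true(blk$is_block)
  singleton <- res$blocks[res$blocks$n_windows == 1L, ]
  expect_true(all(!singleton$is_block))
  expect_equal(res$n_soma_excess, 0L)
})

test_that("calling is invariant to global library rescaling", {
  germ <- fixture_sim$germline_pileup
  soma3 <- fixture_sim$soma_pileup
  for (b in c("A", "C", "G", "T")) soma3[[b]] <- soma3[[b]] * 3L
  base <- call_grc_windows(germ, fixture_sim$soma_pileup,
                           fixture_genome$reference, fixture_genome$annotation)
  scaled <- call_grc_windows(germ, soma3,
                             fixture_genome$reference, fixture_genome$annotation)
  expect_identical(base$windows$amplified, scaled$windows$amplified)
  expect_identical(base$genes, scaled$genes)
})

test_that("simulated GRC genes are recovered through window overlap", {
  res <- call_grc_windows(fixture_sim$germline_pileup, fixture_sim$soma_pileup,
                          fixture_genome$reference, fixture_genome$annotation)
  expect_setequal(res$genes, fixture_grc$genes$gene_id)
  expect_equal(res$n_soma_excess, 0L)
})

test_that("gene-block intersection respects half-open coordinates", {
  blocks <- data.frame(chrom = "chr1", start = 150L, end = 5150L)
  ann <- data.frame(chrom = "chr1",
                    start = c(100L, 5150L), end = c(200L, 5300L),
                    gene_id = c("inside", "abutting"))
  expect_equal(intersect_genes(blocks, ann), "inside")
  expect_equal(intersect_genes(blocks[0, ], ann), character())
})
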