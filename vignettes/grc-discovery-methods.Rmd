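---
title: "Detecting a germline-restricted chromosome: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting a germline-restricted chromosome: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grcscan)
```

## The detection problem

A germline-restricted chromosome (GRC) is present in germline cells but
eliminated from the soma. Its genes are amplified, diverged copies of genes
on the regular A chromosomes, so when germline reads are mapped onto a
*somatic* reference assembly, two signals betray GRC-linked loci at their
A-chromosomal paralogs:

- **dosage**: with `f` GRCs per haploid A-genome set in the sequenced
  germline tissue and `c` GRC copies of a gene, the expected germline/soma
  depth ratio over that gene is `1 + f·c` (one A copy plus `f·c` GRC
  copies per haploid equivalent);
- **divergence**: substitutions private to the GRC paralog appear as
  germline-read alleles never seen in soma reads of the same individual.

Everything in this package is built around recovering those two signals
with conservative thresholds and symmetric negative controls, then
layering copy-number, expression-enrichment and phylogenetic-dating
analyses on the recovered gene set.

## Coverage-ratio amplification calling

Mean depth per tissue is computed in fixed windows (5 kb for calling; 1 kb
is available for fine-scale reporting) together with reference GC content.
The correction cascade is:

1. **Library normalisation** — germline window depths are multiplied by
   the soma/germline total-depth ratio, making calling invariant to
   sequencing effort.
2. **Outlier removal and slope correction** — germline windows above the
   germline mean + 2 SD are excluded from a least-squares fit of germline
   on soma depth, and *all* germline depths are divided by the fitted
   slope. The exclusion applies to the fit only: the excluded windows are
   precisely the amplified ones the fit must not be dragged by, and they
   remain fully eligible for calling. We use a zero-intercept fit because
   the two depths are proportional under the null of no amplification; a
   free intercept would let a handful of residual amplified windows tilt
   both coefficients.
3. **Centering** — the log2 germline/soma ratio distribution is centred on
   the *mode* of a histogram with 0.05-wide bins (bins centred on
   multiples of 0.05, so a perfectly balanced background centres at
   exactly 0). The mode rather than the mean or median is used so that an
   abundant amplified tail cannot shift the 1:1 peak.
4. **Filters and threshold** — windows in the lowest 5th percentile of
   germline depth (or with zero soma depth — no pseudo-counts are used)
   are flagged low-coverage; windows with GC outside 30–60% are flagged,
   a range outside which read mapping is expected to be composition-biased.
   Unflagged windows with centred log2 ratio **≥ 2** (i.e. at least
   4-fold; the threshold is inclusive) are called amplified, and adjacent
   called windows merge into blocks, distinguishing blocks of ≥ 10 kb from
   singletons.
5. **Negative control** — the identical procedure with tissue roles
   swapped counts soma-excess windows; on genuine GRC data this count is
   near zero, confirming the cut-off is conservative.

A gene is coverage-detected when any annotated interval overlaps any
called window (0-based half-open intervals; abutting features do not
overlap).

## Germline-specific SNVs

A site/allele is called when the alternate base has at least `min_germ`
(default 10) supporting germline reads, zero supporting soma reads, and
soma site depth of at least `min_soma_depth` (default 10). Two readings of
"10-read coverage" are possible — allele-supporting reads or total site
depth — and both are implemented behind the `mode` switch; the default is
allele support, since site depth alone would call single-read sequencing
errors at well-covered sites. Soma sites below the depth minimum are
skipped rather than treated as confirming absence. Indels are out of
scope; each alternate allele of a multi-allelic site is evaluated
independently.

Per-sample call sets intersect across germline replicates (same locus and
alternate allele in every sample). Genes with ≥ 5 intersected SNVs, or in
the coverage-amplified set, form the **high-confidence** union. Ref/alt
consensus pairs substitute called bases into the reference gene body, and
transcription of a call is verified in RNA pileups when the site has
≥ 100 RNA reads and an alt/ref read ratio strictly above 1%.

The soma-swap negative control reruns the whole rule with tissues
exchanged and is expected to return zero.

## Copy number and cytogenetic corrections

Copies per haploid genome follow
`copies = mean depth × genome size / library bases`: the second factor is
the reciprocal of the library's expected single-copy depth. For soma
libraries the genome size is the assembly size; for germline libraries
`f × GRC size` is added (`germline_genome_size()`). The cytogenetic
inputs are `f = 2G/(4G + 2S)` from counts of FISH-positive (tetraploid,
two GRCs) and FISH-negative (diploid) cells, and GRC size = synaptonemal
length ratio × reference chromosome size (1.07 × 156.41 Mb ≈ 167.36 Mb).

One published parameterisation states a germline genome size of 1329 Mb
alongside an assembly of 1223 Mb and 0.364 GRCs of 167.3 Mb, yet
1223 + 0.364 × 167.3 = 1283.9. The formula is implemented as written and
both values can be supplied directly; the discrepancy (consistent with a
digit transposition, since 0.634 × 167.3 would give 1329) is documented
here rather than resolved.

Transcripts whose per-position depth has a coefficient of variation above
0.5 (for example, partially amplified paralogs) are split by 2-means on
depth before estimation, with contiguity enforced by absorbing runs
shorter than 50 bp into their neighbours — a deliberately simple reading
of an under-specified "split high/low regions" rule; breakpoint precision
is only guaranteed to the smoothing-run scale.

## Expression enrichment

The background is the set of annotated genes expressed in at least one
tissue of a 10-tissue panel (5 tissues per sex), each labelled by its
arg-max tissue; exact ties are broken by fixed column order. The test
draws `n` genes without replacement `n_reps = 10,000` times and compares
the observed testis-max and ovary-max counts against the null draws
(one-tailed enrichment), and the "other" category against the lower tail
(one-tailed underrepresentation). Both the raw replicate fraction and the
`(r+1)/(n_reps+1)` convention are reported — the raw fraction matches the
historical definition, the +1 form cannot return an impossible p = 0. The
query genes are not removed from the sampling pool (the natural reading of
sampling "from the list"). An exact hypergeometric tail computed by direct
summation of log-binomial terms serves as the independent oracle: at
(N = 7918, K = 1376, n = 65, k = 22) the tail is 9.66e-4, and the
randomisation p agrees within Monte-Carlo error. A Bonferroni column for a
user-stated family size is optional and off by default.

## Evolutionary strata from gene trees

Each gene tree contains ref tips (A-chromosomal consensus per species),
one alt (GRC) lineage, and is rooted on the deepest sampled lineage.
The divergence set `D` — species descended from the most recent common
ancestor of the alt clade and the focal-species ref tip, minus alt —
determines the stratum: focal subspecies only → S5; within the zebra finch
species pair → S4; a *proper subset* of the sampled estrildids → S3;
*all* sampled estrildids → S2 (estrildid stem); any non-estrildid oscine
→ S1 (songbird stem). The S2/S3 rule (complete vs proper-subset estrildid
divergence set) is one consistent reading of how to separate stem from
within-radiation insertions under incomplete taxon sampling. Assignment is
topology-only; branch lengths are ignored. Trees whose alt tips are not
monophyletic, and trees with bootstrap support below 50 at the alt
attachment node, are reported unassigned rather than forced into a
stratum.

## What the simulator emulates — and what it does not

`simulate_genome()`/`simulate_pileups()` generate: GC composition that is
uniform or a linear gradient (1 kb tiles), non-overlapping 5 kb gene
models placed by default on a 5 kb grid (so an amplified gene spans whole
calling windows, mirroring the multi-kilobase scale of real amplified
blocks; arbitrary placement via `align_genes = FALSE`), Poisson
per-position depths, GRC dosage `1 + f·c` with divergence sites drawn
uniformly in gene bodies (count = `round(p_div × length)`), uniform
sequencing errors over the three non-template bases, and a shared
per-kilobase gamma depth-bias factor (mean 1, sd 0.05) emulating
mappability/composition effects — identical between tissues, so it gives
the tight inter-tissue window correlation of real paired libraries while
cancelling exactly in coverage ratios. Replicate individuals can share one
divergence truth (`divergence=`), as a population sharing one GRC
haplotype would. Truth tables (model, divergence sites, library bases,
effective genome sizes) are serialised alongside.

Defaults follow the study conditions: `f = 0.364`, GRC size 167.3 Mb,
per-gene copy numbers spanning 2–308, divergence rate 0.01/site, 15–20×
depth, error rate 1e-3.

Not emulated: read-level fragments and insert sizes, alignment and
mapping-quality artefacts, repeats and mappability structure, indels,
linked-read barcodes, and GC-dependent *depth* bias coupled to the
simulated GC track (the GC filter is exercised by composition alone, the
depth bias by an independent factor). Passing tests therefore demonstrate
the correctness of the statistical cascade on its stated model, not
robustness to alignment artefacts in real libraries.

## Problem sizes and numerical choices

The test-suite simulations use one 600 kb chromosome with 30 genes for
module tests and one 2 Mb chromosome with 200 genes (20 GRC-linked,
15× depth) for the end-to-end recovery checks; copy-number recovery uses
c ∈ {2, 8, 50, 308} at 20×, enrichment 10,000 draws on a 7918-gene
background, and strata 250 clean trees (50 per stratum). These sizes give
sampling error comfortably inside the stated tolerances (5% on depth
means, 10% on copy number, 3 Monte-Carlo SE on p-values) while keeping a
full run of suite plus acceptance script in a few minutes.

Degenerate inputs are handled explicitly: zero total depth or constant
soma depth abort normalisation/fitting; all-filtered window sets return an
empty call set with a warning; a zero-depth ratio is undefined and the
window excluded rather than pseudo-counted; empty GRC models are valid and
propagate to empty call sets and clean controls.

## Known limitations

- Calling operates per chromosome on pileups in memory; whole vertebrate
  genomes at full depth would need chunked ingestion.
- The 2-means transcript split assumes two depth regimes; more complex
  profiles would need proper segmentation (HMM/CBS), which is out of
  scope.
- Stratum assignment trusts the input topology apart from the bootstrap
  gate; it does not attempt to rescue poorly resolved trees.
- The coverage model contains no mappability track; in real data,
  low-mappability regions must be handled by the GC and low-coverage
  filters alone.
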