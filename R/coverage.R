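#' Window coverage from paired pileups
#'
#' Tiles every chromosome of the reference into fixed-size windows (terminal
#' windows may be shorter) and computes mean per-position read depth for each
#' tissue plus reference GC content per window. Every reference position is
#' assigned to exactly one window; positions absent from a pileup contribute
#' zero depth.
#'
#' @param germ_pileup,soma_pileup Pileup data.frames
#'   (`chrom`, `pos0`, `ref`, `A`, `C`, `G`, `T`) on the same reference.
#' @param reference [Biostrings::DNAStringSet] naming the chromosomes.
#' @param window_size Window size in bp. 5 kb is used for amplification
#'   calling; 1 kb for fine-scale reporting.
#' @return data.frame of windows: `chrom`, `start`, `end`, `size`,
#'   `depth_germ`, `depth_soma`, `gc`, filter flags (`outlier_removed`,
#'   `low_coverage`, `gc_fail`), `log2_ratio`, `amplified`.
#' @export
window_depths <- function(germ_pileup, soma_pileup, reference,
                          window_size = 5000L) {
  stopifnot(window_size >= 100)
  out <- vector("list", length(reference))
  for (i in seq_along(reference)) {
    chrom <- names(reference)[i]
    L <- Biostrings::width(reference)[i]
    if (L == 0) next
    starts <- seq.int(0L, L - 1L, by = window_size)
    ends <- pmin(starts + window_size, L)
    n_win <- length(starts)

    win_sum <- function(pileup) {
      p <- pileup[pileup$chrom == chrom, , drop = FALSE]
      depth <- p$A + p$C + p$G + p$T
      idx <- p$pos0 %/% window_size + 1L
      sums <- numeric(n_win)
      if (nrow(p)) {
        agg <- rowsum(depth, idx)
        sums[as.integer(rownames(agg))] <- agg[, 1L]
      }
      sums
    }
    v <- Biostrings::Views(reference[[i]], start = starts + 1L, end = ends)
    freq <- Biostrings::letterFrequency(v, letters = c("GC", "AT"))
    gc <- freq[, "G|C"] / pmax(rowSums(freq), 1L)

    out[[i]] <- data.frame(
      chrom = chrom, start = starts, end = ends, size = ends - starts,
      depth_germ = win_sum(germ_pileup) / (ends - starts),
      depth_soma = win_sum(soma_pileup) / (ends - starts),
      gc = gc)
  }
  w <- do.call(rbind, out)
  rownames(w) <- NULL
  w$outlier_removed <- FALSE
  w$low_coverage <- FALSE
  w$gc_fail <- FALSE
  w$log2_ratio <- NA_real_
  w$amplified <- FALSE
  w
}

#' Library-depth normalisation of germline windows
#'
#' Rescales germline window depths by the soma/germline total-depth ratio so
#' the two libraries are comparable regardless of sequencing effort. Totals
#' are depth-times-width sums over all windows.
#'
#' @param windows Window data.frame from [window_depths()].
#' @return The windows with `depth_germ` rescaled; the factor is stored in
#'   `attr(, "norm_factor")`.
#' @export
depth_normalise <- function(windows) {
  tot_soma <- sum(windows$depth_soma * windows$size)
  tot_germ <- sum(windows$depth_germ * windows$size)
  if (tot_soma <= 0 || tot_germ <= 0)
    stop("zero total depth in one of the tissues")
  fac <- tot_soma / tot_germ
  windows$depth_germ <- windows$depth_germ * fac
  attr(windows, "norm_factor") <- fac
  windows
}

#' Outlier removal and slope correction of germline depths
#'
#' Germline windows above the germline mean depth plus two standard
#' deviations are flagged `outlier_removed` and excluded from a zero-intercept
#' least-squares fit of germline depth on soma depth; all germline depths are
#' then divided by the fitted slope. The flag records exclusion from the fit
#' only: highly amplified windows are exactly the ones the fit must not see,
#' but they remain eligible for amplification calling.
#'
#' @param windows Normalised window data.frame (>= 100 windows).
#' @return list with `windows` (slope-corrected) and `slope`.
#' @export
remove_outliers_and_fit <- function(windows) {
  if (nrow(windows) < 100)
    stop("at least 100 windows are required for the coverage fit")
  if (stats::var(windows$depth_soma) == 0)
    stop("soma depth is constant; slope undefined")
  thr <- mean(windows$depth_germ) + 2 * stats::sd(windows$depth_germ)
  windows$outlier_removed <- windows$depth_germ > thr
  keep <- !windows$outlier_removed
  fit <- stats::lm(depth_germ ~ 0 + depth_soma, data = windows[keep, ])
  slope <- unname(stats::coef(fit)[1L])
  if (!is.finite(slope) || slope <= 0)
    stop("degenerate slope in coverage fit")
  windows$depth_germ <- windows$depth_germ / slope
  list(windows = windows, slope = slope)
}

# Centred log2 ratio + amplification calls for one orientation.
# Returns list(log2_ratio, low_coverage, amplified_pre_gc).
.call_one_way <- function(d_num, d_den, cutoff_log2, low_pct) {
  low <- d_num < stats::quantile(d_num, low_pct / 100) | d_den <= 0
  ratio <- ifelse(low, NA_real_, d_num / d_den)
  lr <- log2(ratio)
  ok <- is.finite(lr)
  if (!any(ok)) return(list(log2_ratio = lr, low_coverage = low,
                            amplified = rep(FALSE, length(lr))))
  # centre on the mode of the histogram (bin width 0.05, bins centred on
  # multiples of 0.05): the 1:1 peak, robust to an abundant amplified tail
  bins <- table(round(lr[ok] / 0.05))
  centre <- as.numeric(names(bins)[which.max(bins)]) * 0.05
  lr <- lr - centre
  list(log2_ratio = lr, low_coverage = low,
       amplified = ok & lr >= cutoff_log2)
}

#' Call GRC-amplified windows and merge blocks
#'
#' Applies the filter cascade to normalised, slope-corrected windows: windows
#' in the lowest `low_pct` percentile of germline depth (or with zero soma
#' depth) are flagged `low_coverage`; the log2 germline/soma ratio
#' distribution is centred on its histogram mode (bin width 0.05), i.e. on
#' the 1:1 peak; windows with GC outside `gc_bounds` are flagged `gc_fail`;
#' remaining windows with centred log2 ratio at or above `cutoff_log2` are
#' called amplified. Adjacent called windows merge into blocks; a block of at
#' least 10 kb is distinguished from singletons. The symmetric soma-excess
#' negative control repeats the procedure with the tissues swapped and
#' reports the number of soma-excess windows.
#'
#' @param windows Window data.frame after [depth_normalise()] and
#'   [remove_outliers_and_fit()].
#' @param cutoff_log2 Calling threshold on the centred log2 ratio
#'   (default 2, i.e. 4-fold; inclusive).
#' @param gc_bounds Admissible GC range (default `c(0.30, 0.60)`).
#' @param low_pct Low-coverage percentile on germline depth (default 5).
#' @return list with `windows` (flags, `log2_ratio`, `amplified` filled),
#'   `blocks` (data.frame `chrom`, `start`, `end`, `n_windows`, `is_block`)
#'   and `n_soma_excess`.
#' @export
call_amplified <- function(windows, cutoff_log2 = 2,
                           gc_bounds = c(0.30, 0.60), low_pct = 5) {
  fwd <- .call_one_way(windows$depth_germ, windows$depth_soma,
                       cutoff_log2, low_pct)
  windows$low_coverage <- fwd$low_coverage
  windows$log2_ratio <- fwd$log2_ratio
  windows$gc_fail <- windows$gc < gc_bounds[1] | windows$gc > gc_bounds[2]
  windows$amplified <- fwd$amplified & !windows$gc_fail & !windows$low_coverage
  if (!any(!windows$low_coverage & !windows$gc_fail))
    warning("all windows filtered; empty call set")

  rev <- .call_one_way(windows$depth_soma, windows$depth_germ,
                       cutoff_log2, low_pct)
  n_soma_excess <- sum(rev$amplified & !windows$gc_fail)

  list(windows = windows, blocks = merge_blocks(windows),
       n_soma_excess = n_soma_excess)
}

#' Merge adjacent amplified windows into blocks
#'
#' @param windows Window data.frame with an `amplified` column.
#' @param min_block_bp Minimum span for a merged run to count as a block
#'   rather than a singleton (default 10 kb).
#' @return data.frame `chrom`, `start`, `end`, `n_windows`, `is_block`.
#' @export
merge_blocks <- function(windows, min_block_bp = 10000L) {
  amp <- windows[windows$amplified, , drop = FALSE]
  if (!nrow(amp))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_windows = integer(),
                      is_block = logical()))
  amp <- amp[order(amp$chrom, amp$start), , drop = FALSE]
  new_run <- c(TRUE, amp$chrom[-1L] != amp$chrom[-nrow(amp)] |
                     amp$start[-1L] != amp$end[-nrow(amp)])
  run <- cumsum(new_run)
  blocks <- data.frame(
    chrom = tapply(amp$chrom, run, `[`, 1L),
    start = as.integer(tapply(amp$start, run, min)),
    end = as.integer(tapply(amp$end, run, max)),
    n_windows = as.integer(tabulate(run)))
  blocks$is_block <- (blocks$end - blocks$start) >= min_block_bp
  rownames(blocks) <- NULL
  blocks
}

#' Genes overlapping amplified regions
#'
#' A gene is listed (once) if any of its annotated interval overlaps any
#' called region; intervals are 0-based half-open, so abutting features do
#' not overlap.
#'
#' @param blocks data.frame with `chrom`, `start`, `end` (called blocks or
#'   amplified windows).
#' @param annotation Gene annotation data.frame
#'   (`chrom`, `start`, `end`, `gene_id`).
#' @return Character vector of gene ids in annotation order.
#' @export
intersect_genes <- function(blocks, annotation) {
  if (!nrow(blocks) || !nrow(annotation)) return(character())
  gr_b <- GenomicRanges::GRanges(blocks$chrom,
                                 IRanges::IRanges(blocks$start + 1L, blocks$end))
  gr_a <- GenomicRanges::GRanges(annotation$chrom,
                                 IRanges::IRanges(annotation$start + 1L,
                                                  annotation$end))
  hits <- GenomicRanges::findOverlaps(gr_a, gr_b)
  unique(annotation$gene_id[S4Vectors::queryHits(hits)])
}

#' Full coverage-ratio amplification cascade
#'
#' Convenience wrapper running [window_depths()], [depth_normalise()],
#' [remove_outliers_and_fit()], [call_amplified()] and [intersect_genes()].
#'
#' @inheritParams window_depths
#' @inheritParams call_amplified
#' @param annotation Gene annotation data.frame.
#' @return list: `windows`, `blocks`, `n_soma_excess`, `slope`, `genes`
#'   (amplified gene ids).
#' @export
call_grc_windows <- function(germ_pileup, soma_pileup, reference, annotation,
                             window_size = 5000L, cutoff_log2 = 2,
                             gc_bounds = c(0.30, 0.60), low_pct = 5) {
  w <- window_depths(germ_pileup, soma_pileup, reference, window_size)
  w <- depth_normalise(w)
  fit <- remove_outliers_and_fit(w)
  calls <- call_amplified(fit$windows, cutoff_log2, gc_bounds, low_pct)
  calls$slope <- fit$slope
  calls$genes <- intersect_genes(calls$blocks, annotation)
  calls
}
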