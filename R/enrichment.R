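#' Build the expression background with tissue-of-max labels
#'
#' Filters an expression table to genes expressed in at least one tissue
#' (unexpressed genes are excluded from the background), optionally
#' intersects with an annotation universe, and labels each gene by its
#' arg-max tissue. Ties are broken by the fixed order of the tissue columns.
#'
#' @param expr_table data.frame with `gene_id` and one numeric expression
#'   column per tissue.
#' @param universe Optional character vector of annotated gene ids; only
#'   genes present in both lists are kept.
#' @return data.frame `gene_id`, `max_tissue`.
#' @export
build_background <- function(expr_table, universe = NULL) {
  tissue_cols <- setdiff(names(expr_table), "gene_id")
  mat <- as.matrix(expr_table[, tissue_cols, drop = FALSE])
  expressed <- rowSums(mat > 0) > 0
  keep <- expressed
  if (!is.null(universe)) keep <- keep & expr_table$gene_id %in% universe
  mat <- mat[keep, , drop = FALSE]
  data.frame(gene_id = expr_table$gene_id[keep],
             max_tissue = tissue_cols[max.col(mat, ties.method = "first")])
}

#' Randomisation test for gonad-expression enrichment
#'
#' Tests whether a query gene set contains more testis-maximal and
#' ovary-maximal genes than expected by chance: `n_reps` random draws of
#' `length(query_ids)` genes without replacement from the background, the
#' counts of gonad-maximal genes in each draw forming the null. One-tailed
#' enrichment p-values for testis and ovary are the fraction of replicates
#' with a count at or above the observed one; a one-tailed
#' underrepresentation p-value for the remaining ("other") category uses
#' counts at or below the observed. Both the raw fraction `p_raw` and the
#' `(r+1)/(n_reps+1)` convention `p_plus1` (which cannot be zero) are
#' reported; an optional Bonferroni column multiplies `p_raw` by `n_tests`.
#'
#' @param background data.frame from [build_background()].
#' @param query_ids Character vector of query gene ids, a subset of the
#'   background.
#' @param n_reps Number of random draws (default 10000).
#' @param seed Integer seed.
#' @param testis_label,ovary_label Tissue labels of the gonad categories.
#' @param n_tests Optional family size for a Bonferroni column.
#' @return Object of class `enrichment_result`: list with `n`, `N`, `K`
#'   (named category sizes), `observed` (named counts), `n_reps`, `seed`,
#'   `p` (data.frame `category`, `alternative`, `p_raw`, `p_plus1`, and
#'   `p_bonferroni` when `n_tests` is given) and `null_quantiles`.
#' @export
randomisation_test <- function(background, query_ids, n_reps = 10000L,
                               seed = 1L, testis_label = "testis",
                               ovary_label = "ovary", n_tests = NULL) {
  if (!all(query_ids %in% background$gene_id))
    stop("query contains genes absent from the background")
  n <- length(query_ids)
  N <- nrow(background)
  if (n > N) stop("query larger than background")
  cat3 <- function(lab) {
    ifelse(lab == testis_label, "testis",
           ifelse(lab == ovary_label, "ovary", "other"))
  }
  bg_cat <- cat3(background$max_tissue)
  obs_cat <- cat3(background$max_tissue[match(query_ids, background$gene_id)])
  observed <- c(testis = sum(obs_cat == "testis"),
                ovary = sum(obs_cat == "ovary"),
                other = sum(obs_cat == "other"))
  K <- c(testis = sum(bg_cat == "testis"),
         ovary = sum(bg_cat == "ovary"),
         other = sum(bg_cat == "other"))

  set.seed(seed)
  is_t <- bg_cat == "testis"
  is_o <- bg_cat == "ovary"
  null_t <- null_o <- integer(n_reps)
  for (r in seq_len(n_reps)) {
    idx <- sample.int(N, n)
    null_t[r] <- sum(is_t[idx])
    null_o[r] <- sum(is_o[idx])
  }
  null_other <- n - null_t - null_o

  r_t <- sum(null_t >= observed["testis"])
  r_o <- sum(null_o >= observed["ovary"])
  r_u <- sum(null_other <= observed["other"])
  p <- data.frame(
    category = c("testis", "ovary", "other"),
    alternative = c("enrichment", "enrichment", "underrepresentation"),
    p_raw = c(r_t, r_o, r_u) / n_reps,
    p_plus1 = (c(r_t, r_o, r_u) + 1) / (n_reps + 1))
  if (!is.null(n_tests))
    p$p_bonferroni <- pmin(1, p$p_raw * n_tests)

  structure(list(
    n = n, N = N, K = K, observed = observed, n_reps = n_reps, seed = seed,
    p = p,
    null_quantiles = list(
      testis = stats::quantile(null_t, c(0.025, 0.5, 0.975)),
      ovary = stats::quantile(null_o, c(0.025, 0.5, 0.975)),
      other = stats::quantile(null_other, c(0.025, 0.5, 0.975)))),
    class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Gonad-expression enrichment: n =", x$n, "of N =", x$N,
      "background genes;", x$n_reps, "draws\n")
  cat("Category sizes:", paste(names(x$K), x$K, sep = "=", collapse = ", "),
      "\nObserved:", paste(names(x$observed), x$observed, sep = "=",
                           collapse = ", "), "\n")
  print(x$p, row.names = FALSE)
  invisible(x)
}

#' Exact hypergeometric upper-tail oracle
#'
#' Closed-form reference for the randomisation test: `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)` (population `N`, `K` successes, draw `n`),
#' computed by direct summation of exact log-binomial terms.
#'
#' @param N Population size.
#' @param K Number of successes in the population.
#' @param n Draw size (without replacement).
#' @param k Observed success count.
#' @return `P(X >= k)`.
#' @examples
#' hypergeom_oracle(10, 5, 1, 1)  # 0.5
#' @export
hypergeom_oracle <- function(N, K, n, k) {
  stopifnot(N >= 1, K >= 0, K <= N, n >= 0, n <= N, k >= 0)
  hi <- min(n, K)
  if (k > hi) return(0)
  j <- max(k, max(0, n - (N - K))):hi
  sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}
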