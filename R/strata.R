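#' Root a gene tree on its deepest sampled lineage
#'
#' Places the outgroup (the deepest sampled lineage, for the default ladder
#' a corvid) as sister to all other tips. A tree already rooted on the
#' outgroup is returned unchanged.
#'
#' @param tree An [ape] `phylo`.
#' @param outgroup Outgroup tip label.
#' @return A rooted `phylo`.
#' @export
root_tree <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label)
    stop("outgroup '", outgroup, "' not in tree")
  if (ape::is.rooted(tree) && ape::is.monophyletic(tree, outgroup)) {
    og_node <- match(outgroup, tree$tip.label)
    root_children <- tree$edge[tree$edge[, 1] == ape::Ntip(tree) + 1L, 2]
    if (og_node %in% root_children) return(tree)
  }
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' Assign an evolutionary stratum from a rooted gene tree
#'
#' Determines when a gene copied onto the GRC from the placement of its
#' 'alt' (GRC-derived) lineage relative to the ref tips of the species
#' ladder. The divergence set `D` is the set of ref species descended from
#' the most recent common ancestor of the alt clade and the focal-species
#' ref tip. The stratum is the smallest ladder level consistent with `D`:
#' `D` = focal subspecies only gives stratum 5; `D` within the zebra finch
#' species pair gives stratum 4; `D` a proper subset of the estrildids gives
#' stratum 3 (divergence within the estrildid radiation); `D` equal to all
#' sampled estrildids gives stratum 2 (estrildid stem); `D` reaching any
#' non-estrildid oscine gives stratum 1 (songbird stem). Assignment is
#' topology-only and ignores branch lengths.
#'
#' Trees whose alt tips are not monophyletic, and trees whose bootstrap
#' support at the alt attachment node is below `min_bootstrap`, are returned
#' unassigned (`stratum = NA`).
#'
#' @param tree Rooted `phylo` containing one or more alt tips (matched by
#'   `alt_pattern`) and ref tips labelled by species.
#' @param ladder Species ladder, see [default_species_ladder()].
#' @param alt_pattern Regular expression matching alt tip labels
#'   (default `"^alt"`).
#' @param min_bootstrap Minimum support at the attachment node (default 50);
#'   applied when the tree carries numeric node labels.
#' @param gene_id Optional gene identifier carried into the result.
#' @return data.frame `gene_id`, `stratum` (integer or NA),
#'   `divergence_set` (comma-separated), `bootstrap_ok`.
#' @export
assign_stratum <- function(tree, ladder = default_species_ladder(),
                           alt_pattern = "^alt", min_bootstrap = 50,
                           gene_id = NA_character_) {
  alt_tips <- grep(alt_pattern, tree$tip.label, value = TRUE)
  if (!length(alt_tips)) stop("no alt tip matching '", alt_pattern, "'")
  if (!ladder$focal %in% tree$tip.label)
    stop("focal ref tip '", ladder$focal, "' missing from tree")
  res <- function(stratum, d, ok) data.frame(
    gene_id = gene_id, stratum = stratum,
    divergence_set = paste(sort(d), collapse = ","), bootstrap_ok = ok)

  if (length(alt_tips) > 1L && !ape::is.monophyletic(tree, alt_tips))
    return(res(NA_integer_, character(), TRUE))

  mrca <- ape::getMRCA(tree, c(alt_tips, ladder$focal))
  d <- setdiff(ape::extract.clade(tree, mrca)$tip.label, alt_tips)

  # attachment-node support: the MRCA of alt and focal is the node where the
  # alt clade attaches to the ref topology
  if (!is.null(tree$node.label)) {
    lab <- tree$node.label[mrca - ape::Ntip(tree)]
    sup <- suppressWarnings(as.numeric(lab))
    if (!is.na(sup) && sup < min_bootstrap)
      return(res(NA_integer_, d, FALSE))
  }

  est <- ladder$estrildids
  stratum <- if (all(d %in% ladder$focal)) 5L
    else if (all(d %in% ladder$zebra_finch)) 4L
    else if (all(d %in% est) && !setequal(d, est)) 3L
    else if (setequal(d, est)) 2L
    else if (any(d %in% ladder$outer_oscines)) 1L
    else NA_integer_
  res(stratum, d, TRUE)
}

#' Assign strata for a collection of gene trees
#'
#' @param trees Named list of rooted `phylo` objects (names used as gene
#'   ids) or a `multiPhylo`.
#' @inheritParams assign_stratum
#' @return data.frame with one row per tree.
#' @export
assign_strata <- function(trees, ladder = default_species_ladder(),
                          alt_pattern = "^alt", min_bootstrap = 50) {
  ids <- names(trees)
  if (is.null(ids)) ids <- sprintf("tree%03d", seq_along(trees))
  out <- do.call(rbind, lapply(seq_along(trees), function(i)
    assign_stratum(trees[[i]], ladder, alt_pattern, min_bootstrap,
                   gene_id = ids[i])))
  rownames(out) <- NULL
  out
}
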