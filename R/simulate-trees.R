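#' Default songbird species ladder
#'
#' The nested clade ladder used to date when a gene copied onto the GRC,
#' innermost to outermost: the focal Australian zebra finch subspecies
#' (stratum 5), plus the Timor subspecies (stratum 4), plus the other sampled
#' estrildid finches (stratum 3; divergence within estrildids), the estrildid
#' stem (stratum 2), and the songbird stem spanning the non-estrildid oscines
#' with a corvid at the root (stratum 1).
#'
#' @return list with components `focal` (focal subspecies tip), `zebra_finch`
#'   (both zebra finch subspecies), `estrildids` (all estrildid tips,
#'   including the zebra finches), `outer_oscines` (non-estrildid oscines)
#'   and `outgroup` (deepest sampled lineage).
#' @export
default_species_ladder <- function() {
  zf <- c("Taeniopygia_guttata_castanotis", "Taeniopygia_guttata_guttata")
  other_est <- c("Poephila_acuticauda", "Stizoptera_bichenovii",
                 "Lonchura_striata", "Lonchura_castaneothorax",
                 "Uraeginthus_granatina")
  list(focal = zf[1],
       zebra_finch = zf,
       estrildids = c(zf, other_est),
       outer_oscines = c("Serinus_canaria", "Geospiza_fortis",
                         "Zonotrichia_albicollis"),
       outgroup = "Corvus_cornix")
}

#' Read a species ladder from YAML or JSON
#'
#' @param path File with keys `focal`, `zebra_finch`, `estrildids`,
#'   `outer_oscines`, `outgroup`.
#' @return A species-ladder list as in [default_species_ladder()].
#' @export
read_species_ladder <- function(path) {
  ladder <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  req <- c("focal", "zebra_finch", "estrildids", "outer_oscines", "outgroup")
  if (!all(req %in% names(ladder)))
    stop("species ladder must define: ", paste(req, collapse = ", "))
  ladder
}

#' Species tree implied by a ladder
#'
#' Builds the ladder's rooted reference topology: outgroup sister to all
#' oscines; non-estrildid oscines sister to the estrildid clade; within
#' estrildids a nested ladder ending in the two zebra finch subspecies.
#' All branch lengths are 1.
#'
#' @param ladder A species ladder, see [default_species_ladder()].
#' @return A rooted [ape] `phylo` object.
#' @export
species_tree <- function(ladder = default_species_ladder()) {
  zf <- paste0("(", ladder$zebra_finch[2], ":1,", ladder$focal, ":1):1")
  inner <- zf
  other_est <- setdiff(ladder$estrildids, ladder$zebra_finch)
  # pair up remaining estrildids from the inside out
  half <- ceiling(length(other_est) / 2)
  near <- other_est[seq_len(half)]
  far <- setdiff(other_est, near)
  if (length(near))
    inner <- paste0("((", paste0(near, ":1", collapse = ","), "):1,", inner, "):1")
  if (length(far))
    inner <- paste0("((", paste0(far, ":1", collapse = ","), "):1,", inner, "):1")
  osc <- paste0("(", paste0(ladder$outer_oscines, ":1", collapse = ","), "):1")
  txt <- paste0("(", ladder$outgroup, ":1,(", osc, ",", inner, "):1);")
  ape::read.tree(text = txt)
}

# tips whose MRCA defines the alt attachment clade for each stratum
.stratum_clade <- function(ladder, stratum) {
  other_est <- setdiff(ladder$estrildids, ladder$zebra_finch)
  half <- ceiling(length(other_est) / 2)
  switch(as.character(stratum),
    "5" = ladder$focal,
    "4" = ladder$zebra_finch,
    "3" = c(other_est[seq_len(half)], ladder$zebra_finch),
    "2" = ladder$estrildids,
    "1" = c(ladder$outer_oscines, ladder$estrildids),
    stop("unknown stratum index: ", stratum))
}

#' Simulate a rooted gene tree with a GRC ('alt') lineage
#'
#' Starts from the ladder's species tree of A-chromosomal ('ref') consensus
#' tips and attaches a single GRC-derived 'alt' tip as sister to the clade
#' whose stem corresponds to the requested evolutionary stratum: stratum 5
#' attaches to the focal subspecies tip, stratum 4 to the zebra finch
#' species pair, stratum 3 within the estrildid radiation, stratum 2 to the
#' estrildid stem and stratum 1 to the songbird stem. Internal nodes carry
#' bootstrap-style support labels; the support at the alt attachment node is
#' set by `attach_support` so that the low-support rejection rule can be
#' exercised.
#'
#' @param ladder Species ladder, see [default_species_ladder()].
#' @param insertion_branch Stratum index in 1..5.
#' @param seed Integer seed (drives the support-label draws).
#' @param attach_support Bootstrap support at the alt attachment node
#'   (default 100).
#' @param alt_label Tip label of the GRC lineage (default `"alt"`).
#' @return A rooted `phylo` with one alt tip, all ref tips, and node labels.
#' @export
simulate_gene_tree <- function(ladder = default_species_ladder(),
                               insertion_branch, seed = 1L,
                               attach_support = 100, alt_label = "alt") {
  if (!insertion_branch %in% 1:5)
    stop("unknown stratum index: ", insertion_branch)
  set.seed(seed)
  tree <- species_tree(ladder)
  clade <- .stratum_clade(ladder, insertion_branch)
  where <- if (length(clade) == 1L) match(clade, tree$tip.label)
           else ape::getMRCA(tree, clade)
  tree <- phytools::bind.tip(tree, alt_label, edge.length = 0.5,
                             where = where, position = 0.5)
  n_node <- tree$Nnode
  labs <- as.character(sample(90:100, n_node, replace = TRUE))
  tree$node.label <- labs
  # root support is conventionally absent
  tree$node.label[1L] <- ""
  attach_node <- ape::getMRCA(tree, c(alt_label, clade))
  tree$node.label[attach_node - ape::Ntip(tree)] <- as.character(attach_support)
  tree
}
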