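# Ortholog classification by species overlap
#
# Without a species tree, duplications are recognised directly on the gene
# tree: two leaves diverged by a duplication when the subtrees they belong
# to under their last common ancestor share at least one species, and by a
# speciation otherwise.  On a multifurcation the test is applied to the
# pair of child subtrees containing the two leaves, so an unresolved node
# mixing several focal-species genes with one reference gene relates each
# focal gene to the reference gene without making any of them one-to-one.

#' Classify ortholog relations between a focal and a reference species
#'
#' For every focal-species leaf, collects the reference-species leaves
#' whose last common ancestor with it is a speciation under the
#' species-overlap criterion, and assigns a relation class:
#' `one2one` (a single reference ortholog which has no other focal
#' ortholog), `one2many` (one side of the pairing has several genes),
#' `many2many` (both sides do), or `none` (no reference ortholog).
#' Run [collapse_weak_branches()] first so that poorly supported
#' resolution does not masquerade as duplication structure.
#'
#' @param tree A `gene_tree`.
#' @param focal_species Species string of the focal (grapevine) leaves.
#' @param reference_species Species string of the reference leaves.
#' @return Data frame with one row per focal leaf: `vitis_gene`,
#'   `reference_genes` (list column of character vectors), `relation_class`.
#' @examples
#' gt <- read_gene_tree("((Vitis|v1,Arabidopsis|a1)95,Vitis|v2);",
#'                      delim = "|")
#' infer_orthology(gt, "Vitis", "Arabidopsis")
#' @export
infer_orthology <- function(tree, focal_species, reference_species) {
  stopifnot(inherits(tree, "gene_tree"))
  leaves <- tree$leaves
  focal_tips <- which(leaves$species == focal_species)
  ref_tips <- which(leaves$species == reference_species)
  if (length(focal_tips) == 0L)
    stop("tree contains no leaf of the focal species")

  phy <- tree$phylo
  ntip <- ape::Ntip(phy)
  parent <- integer(ntip + phy$Nnode)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  root <- ntip + 1L

  # species set under every node
  species_under <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(ntip)) species_under[[i]] <- leaves$species[i]
  # process internal nodes by decreasing depth (children before parents)
  depth <- integer(ntip + phy$Nnode)
  depth[root] <- 0L
  pre <- root
  repeat {
    nxt <- phy$edge[phy$edge[, 1] %in% pre, 2]
    nxt <- nxt[nxt > ntip]
    if (!length(nxt)) break
    depth[nxt] <- depth[parent[nxt]] + 1L
    pre <- nxt
  }
  internals <- (ntip + 1L):(ntip + phy$Nnode)
  for (nd in internals[order(depth[internals], decreasing = TRUE)]) {
    ch <- phy$edge[phy$edge[, 1] == nd, 2]
    species_under[[nd]] <- unique(unlist(species_under[ch]))
  }

  ancestor_path <- function(tip) {
    path <- tip
    nd <- tip
    while (nd != root) { nd <- parent[nd]; path <- c(path, nd) }
    path
  }
  paths <- lapply(seq_len(ntip), ancestor_path)

  # TRUE when tips a and b are separated by a speciation at their LCA
  is_ortholog_pair <- function(a, b) {
    pa <- paths[[a]]; pb <- paths[[b]]
    common <- intersect(pa, pb)
    lca <- common[which.min(match(common, pa))]
    ca <- pa[match(lca, pa) - 1L]   # child of lca on a's side
    cb <- pb[match(lca, pb) - 1L]
    length(intersect(species_under[[ca]], species_under[[cb]])) == 0L
  }

  ortho <- matrix(FALSE, nrow = length(focal_tips), ncol = length(ref_tips))
  for (i in seq_along(focal_tips))
    for (j in seq_along(ref_tips))
      ortho[i, j] <- is_ortholog_pair(focal_tips[i], ref_tips[j])

  back_counts <- colSums(ortho)  # focal orthologs per reference gene
  res <- lapply(seq_along(focal_tips), function(i) {
    refs <- leaves$gene_id[ref_tips[ortho[i, ]]]
    n_ref <- length(refs)
    back <- if (n_ref) max(back_counts[ortho[i, ]]) else 0L
    cls <- if (n_ref == 0L) "none"
      else if (n_ref == 1L && back == 1L) "one2one"
      else if (n_ref > 1L && back > 1L) "many2many"
      else "one2many"
    list(gene = leaves$gene_id[focal_tips[i]], refs = refs, cls = cls)
  })
  out <- data.frame(
    vitis_gene = vapply(res, `[[`, character(1), "gene"),
    relation_class = vapply(res, `[[`, character(1), "cls"),
    stringsAsFactors = FALSE)
  out$reference_genes <- lapply(res, `[[`, "refs")
  out[c("vitis_gene", "reference_genes", "relation_class")]
}
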