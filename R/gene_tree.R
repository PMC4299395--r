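# Support-labelled gene trees
#
# A gene_tree wraps an ape "phylo" whose internal node labels carry branch
# supports (bootstrap percentages, 0-100) and whose tip labels encode leaf
# metadata as delimiter-separated fields:
#
#   species<delim>gene_id[<delim>symbol[<delim>P]]
#
# where a trailing "P" marks a gene named after a mutant phenotype.

#' Read a gene tree from newick
#'
#' Accepts supports either as plain internal node labels (`(a,b)95`) or as
#' `[&support=95]` comments after the closing parenthesis; any other
#' bracket comments are stripped.  Tip labels are split on `delim` into
#' species, gene id, optional existing symbol and an optional `P` flag
#' marking a phenotype-derived name.  A tip label without the delimiter is
#' used as both species and gene id.
#'
#' @param x Path to a newick file, or a newick string (recognised by a
#'   parenthesis).
#' @param delim Field delimiter inside tip labels (default `"|"`).
#' @return An object of class `gene_tree`: a list with `phylo` (the ape
#'   tree) and `leaves` (data frame: `label`, `species`, `gene_id`,
#'   `symbol`, `phenotype_named`).
#' @export
read_gene_tree <- function(x, delim = "|") {
  text <- if (length(x) == 1L && grepl("\\(", x)) x else {
    paste(readLines(x, warn = FALSE), collapse = "")
  }
  # promote support comments to node labels, then drop remaining comments
  text <- gsub("\\)\\[&support=([0-9.eE+-]+)\\]", ")\\1", text)
  text <- gsub("\\[[^][]*\\]", "", text)
  phy <- ape::read.tree(text = text)
  if (is.null(phy)) stop("could not parse newick input")
  gene_tree(phy, delim = delim)
}

#' Wrap an ape phylo as a gene tree
#'
#' @param phy A rooted `phylo`; internal node labels are read as supports.
#' @param delim Tip-label field delimiter.
#' @return A `gene_tree`.
#' @export
gene_tree <- function(phy, delim = "|") {
  stopifnot(inherits(phy, "phylo"))
  leaves <- .parse_tip_labels(phy$tip.label, delim)
  structure(list(phylo = phy, leaves = leaves, delim = delim),
            class = "gene_tree")
}

.parse_tip_labels <- function(labels, delim) {
  parts <- strsplit(labels, delim, fixed = TRUE)
  df <- do.call(rbind, lapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    data.frame(
      label = labels[i],
      species = p[1],
      gene_id = if (length(p) >= 2L && nzchar(p[2])) p[2] else p[1],
      symbol = if (length(p) >= 3L && nzchar(p[3])) p[3] else NA_character_,
      phenotype_named = length(p) >= 4L && toupper(p[4]) == "P",
      stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene ids among tree leaves")
  df
}

#' @export
print.gene_tree <- function(x, ...) {
  cat(sprintf("<gene_tree> %d leaves (%s), %d internal nodes\n",
              nrow(x$leaves),
              paste(unique(x$leaves$species), collapse = ", "),
              x$phylo$Nnode))
  invisible(x)
}

# numeric supports per internal node (index 1 = root); NA where absent
.node_supports <- function(phy) {
  lab <- phy$node.label
  if (is.null(lab)) return(rep(NA_real_, phy$Nnode))
  suppressWarnings(as.numeric(lab))
}

# children list indexed by node id (tips 1..n, internals n+1..)
.children_of <- function(phy) {
  n_nodes <- ape::Ntip(phy) + phy$Nnode
  kids <- vector("list", n_nodes)
  for (i in seq_len(nrow(phy$edge)))
    kids[[phy$edge[i, 1]]] <- c(kids[[phy$edge[i, 1]]], phy$edge[i, 2])
  kids
}

#' Collapse poorly supported branches
#'
#' Contracts every internal branch whose support is strictly below the
#' threshold, promoting the node's children into its parent and forming
#' polytomies; branches at or above the threshold, branches without a
#' support value, and leaves are never touched.  The default of 70 percent
#' reflects the convention that bootstrap values below 70 imply a
#' potentially misleading hierarchy.
#'
#' @param tree A `gene_tree` (or bare `phylo`).
#' @param support_threshold Retention threshold in percent (default 70);
#'   supports `< support_threshold` are collapsed, `>=` retained.
#' @return A `gene_tree` with the same leaves.  Idempotent.
#' @examples
#' gt <- read_gene_tree("((a,b)65,(c,d)80);")
#' collapse_weak_branches(gt)
#' @export
collapse_weak_branches <- function(tree, support_threshold = 70) {
  bare <- inherits(tree, "phylo")
  gt <- if (bare) gene_tree(tree) else tree
  stopifnot(inherits(gt, "gene_tree"))
  phy <- gt$phylo
  ntip <- ape::Ntip(phy)
  root <- ntip + 1L
  sup <- .node_supports(phy)

  internal <- ntip + seq_len(phy$Nnode)
  bad <- internal[internal != root & !is.na(sup[internal - ntip]) &
                    sup[internal - ntip] < support_threshold]
  if (length(bad) == 0L) return(if (bare) phy else gt)

  kids <- .children_of(phy)
  parent <- integer(ntip + phy$Nnode)
  parent[phy$edge[, 2]] <- phy$edge[, 1]

  surviving_ancestor <- function(node) {
    while (node %in% bad) node <- parent[node]
    node
  }
  # contracted children lists for surviving internal nodes
  new_kids <- list()
  for (node in setdiff(internal, bad)) {
    out <- integer()
    stack <- kids[[node]]
    while (length(stack)) {
      ch <- stack[[1]]; stack <- stack[-1]
      if (ch %in% bad) stack <- c(kids[[ch]], stack)
      else out <- c(out, ch)
    }
    new_kids[[as.character(node)]] <- out
  }

  # rebuild phylo: tips keep their numbers, internals renumbered in preorder
  n_internal_new <- phy$Nnode - length(bad)
  node_label <- character(n_internal_new)
  next_id <- ntip
  rows <- list()
  assign_ids <- function(old) {
    next_id <<- next_id + 1L
    new <- next_id
    node_label[new - ntip] <<- if (is.null(phy$node.label)) ""
      else phy$node.label[old - ntip]
    for (ch in new_kids[[as.character(old)]]) {
      ch_new <- if (ch <= ntip) ch else assign_ids(ch)
      rows[[length(rows) + 1L]] <<- c(new, ch_new)
    }
    new
  }
  assign_ids(root)
  edge <- do.call(rbind, rows)
  storage.mode(edge) <- "integer"

  new_phy <- list(edge = edge, tip.label = phy$tip.label,
                  Nnode = n_internal_new, node.label = node_label)
  class(new_phy) <- "phylo"
  attr(new_phy, "order") <- NULL
  new_phy <- ape::reorder.phylo(new_phy, "cladewise")
  if (bare) new_phy else gene_tree(new_phy, delim = gt$delim)
}

#' Write a gene tree to newick
#'
#' @param tree A `gene_tree`.
#' @param file Optional path; when `NULL` the newick string is returned.
#' @return The newick string, invisibly when written to a file.
#' @export
write_gene_tree <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "gene_tree"))
  txt <- ape::write.tree(tree$phylo)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}
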