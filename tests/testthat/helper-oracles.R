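# Shared fixtures and independent oracles.
#
# Oracles deliberately use different machinery than the implementation:
# orthology is re-derived per leaf pair with phangorn::Descendants and
# ape::getMRCA; collapse correctness is checked on clade sets; identifier
# ordering against a plain lexicographic six-tuple comparator.

# ---- random valid locus identifiers ---------------------------------------

rand_locus_ids <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    ot <- sample(names(object_type_codes()), 1)
    variant <- NULL
    if (runif(1) < 0.4) {
      lp <- paste(sample(letters, sample(0:3, 1), replace = TRUE),
                  collapse = "")
      dp <- if (ot %in% c("t", "p") && runif(1) < 0.6)
        as.character(sample(1:99, 1)) else ""
      v <- paste0(lp, dp)
      variant <- if (nzchar(v)) v else "a"
    }
    locus_id(sample(c("VITVI", "VITVBR"), 1), sample(0:19, 1), ot,
             sample(1:99999, 1), variant = variant,
             version = if (runif(1) < 0.3) sample(1:9, 1) else NULL)
  })
}

# lexicographic comparator on the six-tuple, independent of .locus_key
oracle_id_order <- function(ids) {
  tup <- function(id) list(
    id$chromosome, id$numeric_code, id$object_type, id$taxon,
    if (is.null(id$variant)) "" else id$variant,
    if (is.null(id$version)) 0L else id$version)
  cmp <- function(a, b) {
    ta <- tup(a); tb <- tup(b)
    for (k in seq_along(ta)) {
      if (ta[[k]] < tb[[k]]) return(TRUE)
      if (ta[[k]] > tb[[k]]) return(FALSE)
    }
    FALSE
  }
  # insertion sort with the oracle comparator
  out <- list()
  for (id in ids) {
    pos <- length(out) + 1L
    for (k in seq_along(out)) if (cmp(id, out[[k]])) { pos <- k; break }
    out <- append(out, list(id), after = pos - 1L)
  }
  out
}

# ---- orthology oracle ------------------------------------------------------

# per-pair species-overlap labeling using phangorn/ape machinery
oracle_ortholog_matrix <- function(phy, species) {
  ntip <- ape::Ntip(phy)
  tips_under <- function(nd) {
    if (nd <= ntip) nd else phangorn::Descendants(phy, nd, "tips")[[1]]
  }
  orth <- matrix(FALSE, ntip, ntip)
  for (i in seq_len(ntip - 1L)) for (j in (i + 1L):ntip) {
    mrca <- ape::getMRCA(phy, c(i, j))
    ch <- phy$edge[phy$edge[, 1] == mrca, 2]
    ci <- ch[vapply(ch, function(c) i %in% tips_under(c), logical(1))]
    cj <- ch[vapply(ch, function(c) j %in% tips_under(c), logical(1))]
    disjoint <- length(intersect(species[tips_under(ci)],
                                 species[tips_under(cj)])) == 0L
    orth[i, j] <- orth[j, i] <- disjoint
  }
  orth
}

oracle_relations <- function(gt, focal, reference) {
  phy <- gt$phylo
  species <- gt$leaves$species
  orth <- oracle_ortholog_matrix(phy, species)
  f <- which(species == focal)
  r <- which(species == reference)
  sub <- orth[f, r, drop = FALSE]
  back <- colSums(sub)
  data.frame(
    vitis_gene = gt$leaves$gene_id[f],
    relation_class = vapply(seq_along(f), function(i) {
      refs <- which(sub[i, ])
      if (length(refs) == 0L) return("none")
      b <- max(back[refs])
      if (length(refs) == 1L && b == 1L) "one2one"
      else if (length(refs) > 1L && b > 1L) "many2many"
      else "one2many"
    }, character(1)),
    stringsAsFactors = FALSE)
}

# ---- exhaustive colored-tree enumeration -----------------------------------

# every rooted binary tree shape with n leaves colored over two species,
# up to leaf identity; returned as newick strings with unique gene ids
colored_trees <- local({
  memo <- list()
  gen <- function(n) {
    key <- as.character(n)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- if (n == 1L) c("F", "R") else {
      acc <- character()
      for (i in seq_len(n %/% 2L)) {
        A <- gen(i); B <- gen(n - i)
        if (i < n - i) {
          for (a in A) for (b in B)
            acc <- c(acc, paste0("(", a, ",", b, ")"))
        } else {
          for (ai in seq_along(A)) for (bi in ai:length(A))
            acc <- c(acc, paste0("(", A[ai], ",", A[bi], ")"))
        }
      }
      acc
    }
    memo[[key]] <<- out
    out
  }
  gen
})

label_colored_newick <- function(shape) {
  chars <- strsplit(shape, "", fixed = TRUE)[[1]]
  cnt <- 0L
  lab <- vapply(chars, function(ch) {
    if (ch %in% c("F", "R")) {
      cnt <<- cnt + 1L
      sprintf("%s|g%d|", ch, cnt)
    } else ch
  }, character(1), USE.NAMES = FALSE)
  paste0(paste(lab, collapse = ""), ";")
}

# ---- collapse oracle -------------------------------------------------------

# clade tip-label sets of every internal node, paired with its support
clade_sets <- function(phy) {
  ntip <- ape::Ntip(phy)
  sup <- suppressWarnings(as.numeric(phy$node.label))
  if (is.null(phy$node.label)) sup <- rep(NA_real_, phy$Nnode)
  lapply(seq_len(phy$Nnode), function(k) {
    tips <- phangorn::Descendants(phy, ntip + k, "tips")[[1]]
    list(tips = sort(phy$tip.label[tips]), support = sup[k])
  })
}

# the collapsed tree must contain exactly the root plus the original
# clades whose support is >= threshold or absent
expect_collapse_matches_oracle <- function(orig, collapsed, threshold) {
  co <- clade_sets(orig)
  keep <- vapply(seq_along(co), function(k)
    k == 1L || is.na(co[[k]]$support) || co[[k]]$support >= threshold,
    logical(1))
  want <- lapply(co[keep], `[[`, "tips")
  got <- lapply(clade_sets(collapsed), `[[`, "tips")
  expect_setequal(vapply(want, paste, character(1), collapse = "/"),
                  vapply(got, paste, character(1), collapse = "/"))
}

# ---- random support-labelled trees -----------------------------------------

random_support_tree <- function(seed, n_tips = 8L) {
  set.seed(seed)
  phy <- ape::rtree(n_tips, rooted = TRUE)
  phy$node.label <- c("", as.character(sample(40:100, phy$Nnode - 1L,
                                              replace = TRUE)))
  phy$tip.label <- sprintf("S%d|t%d|", sample(1:3, n_tips, replace = TRUE),
                           seq_len(n_tips))
  gene_tree(phy)
}

# ---- random registry lifecycle ---------------------------------------------

# run a random sequence of lifecycle operations; returns the registry and
# the multiset of identifiers handed out
random_lifecycle <- function(seed, n_ops = 25L) {
  set.seed(seed)
  reg <- registry_new()
  issued <- character()
  for (k in seq_len(n_ops)) {
    active <- registry_ids(reg, "active")
    op <- sample(c("create", "merge", "split", "relocate", "bump"), 1,
                 prob = c(0.45, 0.15, 0.15, 0.15, 0.10))
    if (op == "create" || length(active) == 0L) {
      id <- create_gene(reg, sample(0:19, 1))
      issued <- c(issued, format_locus_id(id))
    } else if (op == "merge") {
      a <- parse_locus_id(sample(active, 1))
      partners <- Filter(function(x) {
        p <- parse_locus_id(x)
        p$chromosome == a$chromosome && p$object_type == a$object_type &&
          format_locus_id(p) != format_locus_id(a)
      }, active)
      if (length(partners))
        merge_genes(reg, a, sample(partners, 1))
    } else if (op == "split") {
      ids <- split_gene(reg, sample(active, 1), n_new = sample(1:2, 1))
      issued <- c(issued, vapply(ids, format_locus_id, character(1)))
    } else if (op == "relocate") {
      id <- parse_locus_id(sample(active, 1))
      target <- sample(setdiff(0:19, id$chromosome), 1)
      new_id <- relocate_gene(reg, id, target)
      issued <- c(issued, format_locus_id(new_id))
    } else {
      bump_version(reg, sample(active, 1))
    }
  }
  list(registry = reg, issued = issued)
}

# ---- curation helpers ------------------------------------------------------

rand_bundle <- function(seed) {
  set.seed(seed)
  hit <- if (runif(1) < 0.8) homology_hit(
    subject_name = "HOM1", subject_species = "Solanum_lycopersicum",
    is_vitis = runif(1) < 0.3, is_characterized = runif(1) < 0.5,
    e_value = 10^runif(1, -40, 0),
    percent_identity = runif(1, 0, 100),
    aligned_length = sample(0:300, 1),
    whole_sequence_identity = runif(1, 0, 100)) else NULL
  evidence_bundle(
    transcript_evidence = runif(1) < 0.6,
    protein_evidence = runif(1) < 0.3,
    pseudogene_evidence = runif(1) < 0.15,
    functional_evidence = sample(c("none", "in_silico", "some_experimental"),
                                 1, prob = c(0.6, 0.25, 0.15)),
    domain_hits = if (runif(1) < 0.4) "kinase" else character(),
    homology_hits = hit)
}

level_rank <- function(level) {
  match(level, c("hypothetical", "expressed", "domain_containing",
                 "similar_to", "putative", "probable", "named", "uncertain"))
}
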