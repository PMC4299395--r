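# Family symbol proposal
#
# A gene symbol is a family root of two to five letters plus a locus
# designator of one to three digits, optionally followed by a lowercase
# differentiation letter (EIL3, SUC28, CCD1a).  When the root itself ends
# with a digit, the letter "L" (-like) is inserted between root and
# designator (ERD6 -> ERD6L2).  The species prefix (Vvi for V. vinifera)
# is a display convention only and never part of the stored symbol.
#
# Naming rules, applied in order:
#   R1 a grapevine mutant-phenotype name supplied by the curator wins; the
#      family-format name is registered as a synonym
#   R2 a one2one ortholog of a reference gene whose symbol fits the family
#      format adopts that symbol
#   R3 a one2one ortholog of an off-root (e.g. phenotype-named) reference
#      gene takes root + next available designator; the off-root name
#      becomes a synonym
#   R4 several focal genes unresolved against a single reference gene take
#      that gene's designator plus letters a, b, ... in traversal order
#   R5 otherwise (one2many over several genes, many2many, none): root +
#      next available designator, counted over both species
#   R6 root ending in a digit inserts "L" before the designator
#   R7 with no reference-species family members, genes are numbered by
#      tree traversal order, never by chromosome position

.naming_error <- function(subclass, message) {
  stop(structure(
    class = c(subclass, "naming_error", "error", "condition"),
    list(message = message, call = NULL)))
}

#' Create a family registry
#'
#' Records, per family, the symbols already in use in each species so that
#' fresh designators can be allocated above every number used in both the
#' focal and the reference species.
#'
#' @param family_root Symbol root (e.g. `"EIL"`, `"SUC"`, `"ERD6"`).
#' @param used Optional data frame of existing symbols: columns `species`,
#'   `symbol`.  Symbols are parsed against the root; off-root symbols
#'   (e.g. `EIN3` in an `EIL` family) are kept as phenotype/off-root names
#'   and do not occupy designators.
#' @param insert_like_letter Whether to insert `"L"` between root and
#'   designator; defaults to `TRUE` exactly when the root ends with a
#'   digit, and may be overridden for families whose community chose
#'   otherwise.
#' @return An object of class `family_registry` with fields `family_root`,
#'   `used` (data frame `species`, `designator`, `letter`, `symbol`),
#'   `off_root` (data frame `species`, `symbol`), `insert_like_letter`.
#' @examples
#' family_registry("EIL", used = data.frame(
#'   species = "Arabidopsis_thaliana",
#'   symbol = c("EIN3", "EIL1", "EIL2", "SLIM1")))
#' @export
family_registry <- function(family_root, used = NULL,
                            insert_like_letter = NULL) {
  stopifnot(is.character(family_root), nzchar(family_root))
  ends_digit <- grepl("[0-9]$", family_root)
  if (is.null(insert_like_letter)) insert_like_letter <- ends_digit
  fam <- structure(
    list(family_root = family_root,
         root_ends_with_digit = ends_digit,
         insert_like_letter = insert_like_letter,
         used = data.frame(species = character(), designator = integer(),
                           letter = character(), symbol = character(),
                           stringsAsFactors = FALSE),
         off_root = data.frame(species = character(), symbol = character(),
                               stringsAsFactors = FALSE)),
    class = "family_registry")
  if (!is.null(used)) {
    stopifnot(all(c("species", "symbol") %in% names(used)))
    for (i in seq_len(nrow(used)))
      fam <- family_register_symbol(fam, used$species[i], used$symbol[i])
  }
  fam
}

#' @export
print.family_registry <- function(x, ...) {
  cat(sprintf("<family_registry> root %s%s: %d symbols in use, %d off-root\n",
              x$family_root, if (x$insert_like_letter) "(L)" else "",
              nrow(x$used), nrow(x$off_root)))
  invisible(x)
}

# parse a symbol against the family root; NULL when it does not conform
.parse_family_symbol <- function(symbol, fam) {
  if (is.null(symbol) || is.na(symbol)) return(NULL)
  root <- fam$family_root
  like <- if (fam$insert_like_letter) "L?" else ""
  pat <- paste0("^", root, "(", like, ")([0-9]{1,3})([a-z]?)$")
  m <- regmatches(symbol, regexec(pat, symbol, ignore.case = FALSE))[[1]]
  if (length(m) == 0L) return(NULL)
  list(designator = as.integer(m[3]), letter = m[4])
}

#' Register a symbol in a family registry
#'
#' @param fam A [family_registry()].
#' @param species Species the symbol belongs to.
#' @param symbol The symbol text.
#' @return The updated `family_registry` (functional update).
#' @export
family_register_symbol <- function(fam, species, symbol) {
  stopifnot(inherits(fam, "family_registry"))
  p <- .parse_family_symbol(symbol, fam)
  if (is.null(p)) {
    fam$off_root <- rbind(fam$off_root, data.frame(
      species = species, symbol = symbol, stringsAsFactors = FALSE))
  } else {
    if (any(fam$used$symbol == symbol & fam$used$species == species))
      .naming_error("naming_collision_error",
                    sprintf("symbol %s already registered for %s", symbol, species))
    fam$used <- rbind(fam$used, data.frame(
      species = species, designator = p$designator, letter = p$letter,
      symbol = symbol, stringsAsFactors = FALSE))
  }
  fam
}

#' Next available locus designator in a family
#'
#' One more than the highest designator used in any of the species in
#' scope; 1 when none is used.  Designators above 999 exceed the
#' three-digit format and raise a capacity error.
#'
#' @param family A [family_registry()].
#' @param species_scope Character vector of species to consider; `NULL`
#'   (default) considers every species in the registry.
#' @return Integer designator.
#' @examples
#' fam <- family_registry("EIL", used = data.frame(
#'   species = "Arabidopsis_thaliana", symbol = c("EIL1", "EIL2")))
#' next_available_designator(fam)   # 3
#' @export
next_available_designator <- function(family, species_scope = NULL) {
  stopifnot(inherits(family, "family_registry"))
  used <- family$used
  if (!is.null(species_scope))
    used <- used[used$species %in% species_scope, , drop = FALSE]
  nxt <- if (nrow(used) == 0L) 1L else max(used$designator) + 1L
  if (nxt > 999L)
    .naming_error("naming_capacity_error",
                  "designator would exceed the three-digit format (999)")
  nxt
}

# compose root(+L)(designator)(letter)
.compose_symbol <- function(fam, designator, letter = "") {
  paste0(fam$family_root, if (fam$insert_like_letter) "L" else "",
         designator, letter)
}

# next free differentiation letter for a designator
.next_letter <- function(fam, designator) {
  taken <- fam$used$letter[fam$used$designator == designator &
                             nzchar(fam$used$letter)]
  for (l in letters) if (!l %in% taken) return(l)
  .naming_error("naming_capacity_error",
                sprintf("no differentiation letter left for designator %d",
                        designator))
}

#' Validate a gene symbol against the format convention
#'
#' Checks the 2--5-letter root, the 1--3-digit designator, and the
#' prohibition of an embedded grapevine species prefix (`vv`/`Vv` collide
#' with *Vibrio vulnificus*; `Vvi` is reserved for display in running
#' text, never stored in the symbol).
#'
#' @param symbol Symbol text.
#' @return Character vector of violations; empty when the symbol conforms.
#' @examples
#' validate_symbol("ADH1")          # clean
#' validate_symbol("TRANSPORT1234") # two violations
#' @export
validate_symbol <- function(symbol) {
  stopifnot(is.character(symbol), nzchar(symbol))
  v <- character()
  if (grepl("^vv", tolower(symbol)))
    v <- c(v, "prefix: symbols must not embed the species prefix vv/Vv/Vvi")
  m <- regmatches(symbol,
                  regexec("^([A-Za-z][A-Za-z0-9]*?)([0-9]+)?([a-z])?$",
                          symbol))[[1]]
  if (length(m) == 0L)
    return(c(v, sprintf("shape: '%s' is not root+designator[+letter]", symbol)))
  root <- m[2]; digits <- m[3]
  n_letters <- nchar(gsub("[^A-Za-z]", "", root))
  if (n_letters < 2L)
    v <- c(v, sprintf("root: '%s' has fewer than 2 letters", root))
  if (n_letters > 5L)
    v <- c(v, sprintf("root: '%s' has more than 5 letters", root))
  if (nzchar(digits) && nchar(digits) > 3L)
    v <- c(v, sprintf("designator: '%s' has more than 3 digits", digits))
  v
}

.new_synonym_rows <- function(names, kind = "symbol", notes = NULL) {
  if (length(names) == 0L) return(data.frame(
    name = character(), kind = character(), note = character(),
    stringsAsFactors = FALSE))
  if (is.null(notes)) notes <- rep("none", length(names))
  data.frame(name = names, kind = kind, note = notes,
             stringsAsFactors = FALSE)
}

#' Propose a symbol for one focal gene
#'
#' Applies the naming rules (R1--R7, see the package vignette) to a single
#' gene given its ortholog relation and the family registry.  Displaced
#' prior names are returned as synonyms to register; format violations of
#' the resulting symbol are attached to the proposal rather than raised,
#' since a curator-supplied phenotype name is kept even when it breaks the
#' length convention.
#'
#' @param family A [family_registry()].
#' @param gene_id Focal gene identifier (must be a leaf of `tree`).
#' @param relation One row of [infer_orthology()] output for this gene
#'   (data frame with `vitis_gene`, `reference_genes`, `relation_class`).
#' @param tree The `gene_tree` the relation came from.
#' @param options List: `phenotype_name` (curator-supplied mutant
#'   phenotype name, triggers R1), `letter` (explicit differentiation
#'   letter for R4), `prior_names` (named character vector
#'   name -> note for historical names to carry over as synonyms),
#'   `display_prefix` (e.g. `"Vvi"`, rendering only).
#' @return An object of class `symbol_proposal`: `gene_id`, `symbol`,
#'   `full_name`, `synonyms_to_register` (data frame `name`, `kind`,
#'   `note`), `display_prefix`, `rationale` (rule ids fired, in order),
#'   `violations`.
#' @export
propose_symbol <- function(family, gene_id, relation, tree,
                           options = list()) {
  stopifnot(inherits(family, "family_registry"),
            inherits(tree, "gene_tree"))
  leaf <- tree$leaves[tree$leaves$gene_id == gene_id, , drop = FALSE]
  if (nrow(leaf) != 1L)
    .naming_error("naming_unknown_gene_error",
                  sprintf("gene '%s' is not a leaf of the tree", gene_id))
  if (!is.data.frame(relation) || nrow(relation) != 1L ||
      relation$vitis_gene != gene_id)
    .naming_error("naming_relation_error",
                  sprintf("relation row does not describe gene '%s'", gene_id))

  rationale <- character()
  synonyms <- .new_synonym_rows(character())
  refs <- relation$reference_genes[[1]]
  cls <- relation$relation_class
  ref_symbol <- function(rg) {
    s <- tree$leaves$symbol[tree$leaves$gene_id == rg]
    if (length(s) == 1L) s else NA_character_
  }

  symbol <- NULL
  if (!is.null(options$phenotype_name)) {
    # R1: grapevine mutant phenotype name wins
    symbol <- options$phenotype_name
    rationale <- c(rationale, "R1")
    alt <- .compose_symbol(family, next_available_designator(family))
    synonyms <- rbind(synonyms, .new_synonym_rows(alt))
  } else if (cls == "one2one") {
    rsym <- ref_symbol(refs[[1]])
    rp <- .parse_family_symbol(rsym, family)
    if (!is.null(rp)) {
      # R2: adopt the reference symbol when its designator is free here
      taken <- any(family$used$species == leaf$species &
                     family$used$designator == rp$designator &
                     family$used$letter == rp$letter)
      if (!taken) {
        symbol <- .compose_symbol(family, rp$designator, rp$letter)
        rationale <- c(rationale, "R2")
      } else {
        symbol <- .compose_symbol(family, next_available_designator(family))
        rationale <- c(rationale, "R2-collision", "R5")
      }
    } else {
      # R3: off-root reference name becomes a synonym
      symbol <- .compose_symbol(family, next_available_designator(family))
      rationale <- c(rationale, "R3")
      if (!is.na(rsym)) synonyms <- rbind(synonyms, .new_synonym_rows(rsym))
    }
  } else if (cls == "one2many" && length(refs) == 1L &&
             !is.null(.parse_family_symbol(ref_symbol(refs[[1]]), family))) {
    # R4: shared single reference ortholog -> its designator + letter
    rp <- .parse_family_symbol(ref_symbol(refs[[1]]), family)
    letter <- options$letter %||% .next_letter(family, rp$designator)
    symbol <- .compose_symbol(family, rp$designator, letter)
    rationale <- c(rationale, "R4")
  } else {
    # R5 (and R7 when the reference species has no family member)
    symbol <- .compose_symbol(family, next_available_designator(family))
    rationale <- c(rationale,
                   if (nrow(family$used) == 0L && cls == "none") "R7" else "R5")
  }
  if (family$insert_like_letter) rationale <- c(rationale, "R6")

  # displaced prior names become synonyms
  prior <- options$prior_names
  if (!is.null(prior))
    synonyms <- rbind(synonyms,
                      .new_synonym_rows(names(prior), notes = unname(prior)))
  if (!is.na(leaf$symbol) && leaf$symbol != symbol &&
      !leaf$symbol %in% synonyms$name)
    synonyms <- rbind(synonyms, .new_synonym_rows(leaf$symbol))

  if (any(family$used$species == leaf$species &
            family$used$symbol == symbol))
    .naming_error("naming_collision_error",
                  sprintf("proposed symbol %s already in use within the family",
                          symbol))

  structure(
    list(gene_id = gene_id, symbol = symbol,
         full_name = options$full_name %||% NA_character_,
         synonyms_to_register = synonyms,
         display_prefix = options$display_prefix %||% NULL,
         rationale = rationale,
         violations = validate_symbol(symbol)),
    class = "symbol_proposal")
}

#' @export
print.symbol_proposal <- function(x, ...) {
  cat(sprintf("<symbol_proposal> %s -> %s%s [%s]%s\n", x$gene_id,
              x$display_prefix %||% "", x$symbol,
              paste(x$rationale, collapse = ","),
              if (nrow(x$synonyms_to_register))
                paste0(" synonyms: ",
                       paste(x$synonyms_to_register$name, collapse = ", "))
              else ""))
  invisible(x)
}

#' Render a proposal's display symbol
#'
#' @param proposal A `symbol_proposal`.
#' @param prefix Display prefix (default the proposal's own, e.g. `"Vvi"`).
#' @return The prefixed symbol for use in running text.
#' @export
display_symbol <- function(proposal, prefix = NULL) {
  stopifnot(inherits(proposal, "symbol_proposal"))
  paste0(prefix %||% proposal$display_prefix %||% "", proposal$symbol)
}

# which focal leaves still need a proposal?
# - no symbol, or a symbol that does not fit the family format, or
# - a letterless symbol on a gene that sits in a shared-reference group
#   needing differentiation letters
.needs_proposal <- function(fam, leaf_symbol, in_letter_group) {
  p <- .parse_family_symbol(leaf_symbol, fam)
  if (is.null(p)) return(TRUE)
  in_letter_group && !nzchar(p$letter)
}

#' Name every unnamed gene of a family
#'
#' Walks the focal-species leaves in tree traversal order (the order the
#' tips appear in the tree) and proposes a symbol for every leaf that has
#' no symbol, carries a symbol outside the family format, or needs a
#' differentiation letter because several focal genes share a single
#' reference ortholog.  Conforming symbols are kept untouched.  The family
#' registry is updated after each proposal, so designators never collide
#' and letters are assigned a, b, c ... in traversal order.
#'
#' @param family A [family_registry()]; existing focal symbols present on
#'   the tree leaves are registered automatically.
#' @param tree A collapsed `gene_tree`.
#' @param relations Output of [infer_orthology()] on `tree`.
#' @param focal_species Focal species string (default the species of the
#'   first relation's gene).
#' @param options Per-gene options: a named list keyed by gene id, each
#'   entry as in [propose_symbol()].
#' @return List of `symbol_proposal` objects, one per renamed gene, in
#'   traversal order.  Deterministic for identical inputs.
#' @export
apply_family_naming <- function(family, tree, relations,
                                focal_species = NULL, options = list()) {
  stopifnot(inherits(family, "family_registry"), inherits(tree, "gene_tree"))
  leaves <- tree$leaves
  if (is.null(focal_species))
    focal_species <- leaves$species[match(relations$vitis_gene[1],
                                          leaves$gene_id)]

  # register existing leaf symbols so they occupy designators
  for (i in seq_len(nrow(leaves))) {
    if (!is.na(leaves$symbol[i]) &&
        !any(family$used$symbol == leaves$symbol[i] &
               family$used$species == leaves$species[i]) &&
        !any(family$off_root$symbol == leaves$symbol[i] &
               family$off_root$species == leaves$species[i]))
      family <- family_register_symbol(family, leaves$species[i],
                                       leaves$symbol[i])
  }

  # shared-reference groups needing differentiation letters (R4)
  single_ref <- vapply(seq_len(nrow(relations)), function(i)
    relations$relation_class[i] == "one2many" &&
      length(relations$reference_genes[[i]]) == 1L, logical(1))
  shared_ref <- unlist(lapply(which(single_ref), function(i)
    relations$reference_genes[[i]]))
  letter_groups <- names(table(shared_ref))[table(shared_ref) >= 2L]
  in_group <- vapply(seq_len(nrow(relations)), function(i)
    single_ref[i] && relations$reference_genes[[i]] %in% letter_groups,
    logical(1))
  names(in_group) <- relations$vitis_gene

  # focal tips in traversal order
  tip_order <- tree$phylo$edge[tree$phylo$edge[, 2] <= ape::Ntip(tree$phylo), 2]
  focal_order <- leaves$gene_id[tip_order][leaves$species[tip_order] ==
                                             focal_species]

  proposals <- list()
  for (g in focal_order) {
    leaf_symbol <- leaves$symbol[leaves$gene_id == g]
    grp <- isTRUE(in_group[[g]])
    if (!.needs_proposal(family, leaf_symbol, grp)) next
    rel <- relations[relations$vitis_gene == g, , drop = FALSE]
    # a gene being renamed releases its own letterless symbol first
    if (!is.na(leaf_symbol)) {
      drop <- family$used$symbol == leaf_symbol &
        family$used$species == focal_species
      family$used <- family$used[!drop, , drop = FALSE]
    }
    pr <- propose_symbol(family, g, rel, tree, options = options[[g]] %||% list())
    proposals[[length(proposals) + 1L]] <- pr
    family <- family_register_symbol(family, focal_species, pr$symbol)
  }

  symbols <- vapply(proposals, `[[`, character(1), "symbol")
  if (anyDuplicated(symbols))
    .naming_error("naming_collision_error",
                  "duplicate symbols emitted within one family run")
  proposals
}
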