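# Worked scenarios and randomized instances
#
# The scenario trees are synthetic encodings of the published worked
# examples: their topologies reproduce the stated relations (a one2one
# EIN3 ortholog, a pair equidistant from EIL2, an orphan sucrose
# transporter, hexose transporters renamed under the STP root, ERD6-like
# numbering with the inserted L, a duplicated CCD1 pair, a stilbene
# synthase family with no Arabidopsis member), not re-estimated gene
# phylogenies.  They are regenerated in code; nothing is downloaded.

.VV <- "Vitis_vinifera"
.AT <- "Arabidopsis_thaliana"

.scenario <- function(name, newick, family, focal = .VV, reference = .AT,
                      options = list(), expected_proposals = NULL,
                      expected_kept = character()) {
  structure(list(name = name,
                 tree = read_gene_tree(newick),
                 family = family,
                 focal_species = focal, reference_species = reference,
                 options = options,
                 expected_proposals = expected_proposals,
                 expected_kept = expected_kept),
            class = "naming_scenario")
}

#' @export
print.naming_scenario <- function(x, ...) {
  cat(sprintf("<naming_scenario> %s: %d leaves, root %s\n", x$name,
              nrow(x$tree$leaves), x$family$family_root))
  invisible(x)
}

#' Run a scenario through the naming engine
#'
#' Collapses the scenario tree, infers ortholog relations and applies the
#' family naming rules.
#'
#' @param sc A scenario from [build_paper_scenarios()].
#' @param support_threshold Collapse threshold (default 70).
#' @return List of `symbol_proposal` objects.
#' @export
run_scenario <- function(sc, support_threshold = 70) {
  stopifnot(inherits(sc, "naming_scenario"))
  tree <- collapse_weak_branches(sc$tree, support_threshold)
  rel <- infer_orthology(tree, sc$focal_species, sc$reference_species)
  apply_family_naming(sc$family, tree, rel,
                      focal_species = sc$focal_species,
                      options = sc$options)
}

#' Build the worked naming scenarios
#'
#' Six reproducible scenarios covering the canonical naming situations:
#' `EIL` (a one2one ortholog of the phenotype-named EIN3, a pair
#' equidistant from EIL2, and a gene equidistant from several family
#' members), `SUC` (an orphan sucrose transporter numbered above both
#' species), `STP` (hexose transporters renamed from the historical HT
#' symbols to the Arabidopsis STP root), `ERD6` (root ending in a digit,
#' inserting the letter L), `CCD` (a duplicated CCD1 pair differentiated
#' by letters, with obsolete NCED synonyms), and `STS` (a family absent
#' from Arabidopsis, numbered by tree traversal rather than chromosome
#' position).
#'
#' @return Named list of scenario objects.
#' @examples
#' sc <- build_paper_scenarios()$EIL
#' run_scenario(sc)
#' @export
build_paper_scenarios <- function() {
  L <- function(species, gene, symbol = "", flag = "")
    paste(species, gene, symbol, flag, sep = "|")

  scenarios <- list()

  # --- EIL: uncharacterized members and members with diverse names -------
  eil_newick <- paste0(
    "((", L(.VV, "VIT06s0009g01380"), ":1,", L(.AT, "AT3G20770", "EIN3", "P"),
    ":1)95:1,(", L(.VV, "VIT11s0016g00640"), ":1,", L(.VV, "VIT16s0100g00570"),
    ":1,", L(.AT, "AT5G21120", "EIL2"), ":1)88:1,(",
    L(.VV, "VIT00s0357g00120"), ":1,", L(.AT, "AT4G35770", "SLIM1", "P"),
    ":1,", L(.AT, "AT2G27050", "EIL1"), ":1,", L(.AT, "AT5G65100"), ":1,",
    L(.AT, "AT5G10120"), ":1)80:1);")
  scenarios$EIL <- .scenario(
    "EIL", eil_newick,
    family_registry("EIL", used = data.frame(
      species = .AT, symbol = c("EIN3", "EIL1", "EIL2", "SLIM1"),
      stringsAsFactors = FALSE)),
    expected_proposals = data.frame(
      gene_id = c("VIT06s0009g01380", "VIT11s0016g00640",
                  "VIT16s0100g00570", "VIT00s0357g00120"),
      symbol = c("EIL3", "EIL2a", "EIL2b", "EIL4"),
      synonyms = c("EIN3", "", "", ""),
      stringsAsFactors = FALSE))

  # --- SUC: historical names inconsistent with the family root -----------
  suc_newick <- paste0(
    "((", L(.VV, "VIT18s0076g00250", "SUT2"), ":1,(",
    L(.VV, "VIT11s0016g00470", "SUC11"), ":1,",
    L(.AT, "AT1G71880", "SUC1"), ":1)85:1)90:1,(",
    L(.AT, "AT1G22710", "SUC2"), ":1,", L(.AT, "AT2G02860", "SUC3"),
    ":1)75:1);")
  scenarios$SUC <- .scenario(
    "SUC", suc_newick,
    family_registry("SUC", used = data.frame(
      species = c(rep(.AT, 9L), rep(.VV, 2L)),
      symbol = c(paste0("SUC", 1:9), "SUC12", "SUC27"),
      stringsAsFactors = FALSE)),
    options = list(VIT11s0016g00470 = list(
      prior_names = c(SUT1 = "none"))),
    expected_proposals = data.frame(
      gene_id = "VIT18s0076g00250", symbol = "SUC28", synonyms = "SUT2",
      stringsAsFactors = FALSE),
    expected_kept = c(VIT11s0016g00470 = "SUC11"))

  # --- STP: hexose transporters re-rooted from the HT symbols ------------
  stp_newick <- paste0(
    "((", L(.VV, "VIT05s0020g03140", "HT1"), ":1,",
    L(.AT, "AT1G11260", "STP1"), ":1)99:1,((",
    L(.VV, "VIT11s0149g00050", "HT3"), ":1,",
    L(.AT, "AT4G02310", "STP13"), ":1)92:1,",
    L(.VV, "VIT03s0038g01320", "HT24"), ":1)78:1);")
  scenarios$STP <- .scenario(
    "STP", stp_newick,
    family_registry("STP"),
    expected_proposals = data.frame(
      gene_id = c("VIT05s0020g03140", "VIT11s0149g00050", "VIT03s0038g01320"),
      symbol = c("STP1", "STP13", "STP14"),
      synonyms = c("HT1", "HT3", "HT24"),
      stringsAsFactors = FALSE))

  # --- ERD6: root ends with a digit, insert the letter L -----------------
  erd6_newick <- paste0(
    "((", L(.VV, "VIT03s0017g01980"), ":1,",
    L(.AT, "AT1G08930", "ERD6L2"), ":1)96:1,(",
    L(.VV, "VIT05s0062g00340"), ":1,(",
    L(.AT, "AT1G08920", "ERD6L1"), ":1,",
    L(.AT, "AT3G05400", "ERD6L3"), ":1)71:1)83:1);")
  scenarios$ERD6 <- .scenario(
    "ERD6", erd6_newick,
    family_registry("ERD6"),
    expected_proposals = data.frame(
      gene_id = c("VIT03s0017g01980", "VIT05s0062g00340"),
      symbol = c("ERD6L2", "ERD6L4"),
      synonyms = c("", ""),
      stringsAsFactors = FALSE))

  # --- CCD: a duplicated CCD1 pair, obsolete NCED synonyms, CCD8b --------
  ccd_newick <- paste0(
    "((", L(.VV, "VIT13s0064g00810", "CCD1"), ":1,",
    L(.VV, "VIT13s0064g00840"), ":1,",
    L(.AT, "AT3G63520", "CCD1"), ":1)81:1,",
    L(.VV, "VIT04s0008g03510", "CCD8b"), ":1,(",
    L(.AT, "AT4G32810", "CCD8"), ":1,",
    L(.AT, "AT2G44990", "CCD7"), ":1)90:1);")
  scenarios$CCD <- .scenario(
    "CCD", ccd_newick,
    family_registry("CCD", used = data.frame(
      species = .AT, symbol = c("CCD4"), stringsAsFactors = FALSE)),
    options = list(VIT13s0064g00810 = list(
      prior_names = c(NCED1 = "obsolete"))),
    expected_proposals = data.frame(
      gene_id = c("VIT13s0064g00810", "VIT13s0064g00840"),
      symbol = c("CCD1a", "CCD1b"),
      synonyms = c("NCED1;CCD1", ""),
      stringsAsFactors = FALSE),
    expected_kept = c(VIT04s0008g03510 = "CCD8b"))

  # --- STS: no Arabidopsis member; numbering by traversal, not position --
  sts_newick <- paste0(
    "((", L(.VV, "VIT16s0100g00750"), ":1,", L(.VV, "VIT10s0042g00920"),
    ":1)88:1,(", L(.VV, "VIT16s0100g00770"), ":1,",
    L(.VV, "VIT10s0042g00860"), ":1)91:1);")
  scenarios$STS <- .scenario(
    "STS", sts_newick, family_registry("STS"),
    expected_proposals = data.frame(
      gene_id = c("VIT16s0100g00750", "VIT10s0042g00920",
                  "VIT16s0100g00770", "VIT10s0042g00860"),
      symbol = paste0("STS", 1:4),
      synonyms = c("", "", "", ""),
      stringsAsFactors = FALSE))

  scenarios
}

#' Generate a random gene-family scenario
#'
#' Builds a reproducible gene tree over a focal and a reference species by
#' assembling ortholog pairs (cherries of one focal and one reference
#' gene), surplus single-species genes when the counts differ, and, at the
#' given rate, focal-side duplications that turn a cherry into a
#' one2many relation.  Ancestral joins between ortholog groups are ancient
#' duplications.  Supports are drawn uniformly on 50--100, so some
#' branches fall below the usual 70 percent collapse threshold, as in real
#' bootstrap trees.  Pure function of the seed.
#'
#' @param seed Integer seed.
#' @param n_focal Number of focal-species genes (>= 1).
#' @param n_reference Number of reference-species genes (>= 1).
#' @param duplication_rate Probability that an ortholog pair carries a
#'   recent focal-side duplication.
#' @return A scenario object (without expected proposals); reference genes
#'   carry family-format symbols `FAM1`, `FAM2`, ...
#' @export
random_family <- function(seed, n_focal, n_reference,
                          duplication_rate = 0.2) {
  stopifnot(n_focal >= 1L, n_reference >= 1L,
            duplication_rate >= 0, duplication_rate <= 1)
  rng <- .seeded_rng(seed)
  sup <- function() round(rng$unif(1, 50, 100))

  n_pairs <- min(n_focal, n_reference)
  focal_left <- n_focal
  ref_left <- n_reference
  fi <- 0L; ri <- 0L
  fleaf <- function() {
    fi <<- fi + 1L; focal_left <<- focal_left - 1L
    sprintf("%s|Vg%03d|", .VV, fi)
  }
  rleaf <- function() {
    ri <<- ri + 1L; ref_left <<- ref_left - 1L
    sprintf("%s|Ag%03d|FAM%d", .AT, ri, ri)
  }
  groups <- character()
  for (k in seq_len(n_pairs)) {
    # a duplication consumes an extra focal leaf; keep one per later pair
    dup <- focal_left >= (n_pairs - k) + 2L &&
      rng$unif(1) < duplication_rate
    fpart <- if (dup) sprintf("(%s:1,%s:1)%d:1", fleaf(), fleaf(), sup())
      else paste0(fleaf(), ":1")
    groups <- c(groups, sprintf("(%s,%s:1)%d:1", fpart, rleaf(), sup()))
  }
  while (focal_left > 0L) groups <- c(groups, paste0(fleaf(), ":1"))
  while (ref_left > 0L) groups <- c(groups, paste0(rleaf(), ":1"))

  # join ortholog groups by a random ladder of ancient duplications
  while (length(groups) > 1L) {
    i <- 1L + floor(rng$unif(1, 0, length(groups) - 1e-9))
    j <- 1L + floor(rng$unif(1, 0, length(groups) - 1 - 1e-9))
    rest <- groups[-i]
    merged <- sprintf("(%s,%s)%d:1", groups[i], rest[j], sup())
    groups <- c(rest[-j], merged)
  }
  newick <- paste0(sub(":1$", "", groups), ";")

  fam <- family_registry("FAM", used = data.frame(
    species = .AT, symbol = paste0("FAM", seq_len(ri)),
    stringsAsFactors = FALSE))
  .scenario(sprintf("random-%d", seed), newick, fam)
}

#' Generate a random registry via lifecycle operations
#'
#' Populates an empty registry with [create_gene()] calls, so every
#' lifecycle invariant holds by construction.
#'
#' @param seed Integer seed (reserved for future stochastic object types;
#'   generation is currently deterministic given the counts).
#' @param genes_per_chromosome Integer vector of length 20: genes to
#'   create on chromosomes 00--19 (each <= 99999).
#' @return A `gene_registry`.
#' @export
random_registry <- function(seed, genes_per_chromosome) {
  stopifnot(length(genes_per_chromosome) == 20L,
            all(genes_per_chromosome >= 0L),
            all(genes_per_chromosome <= 99999L))
  reg <- registry_new()
  for (chr in 0:19)
    for (i in seq_len(genes_per_chromosome[chr + 1L]))
      create_gene(reg, chr, actor = "generator")
  reg
}

# small self-contained linear congruential generator so fixture generation
# never disturbs (or depends on) the global RNG state
.seeded_rng <- function(seed) {
  state <- (as.numeric(seed) %% 2147483647)
  if (state <= 0) state <- state + 2147483646
  nxt <- function() {
    state <<- (16807 * state) %% 2147483647
    state / 2147483647
  }
  list(unif = function(n, min = 0, max = 1) {
    vapply(seq_len(n), function(i) min + (max - min) * nxt(), numeric(1))
  })
}

#' Write scenarios to a directory
#'
#' Serialises each scenario as a newick file, a TSV family registry and a
#' JSON file of expected proposals.
#'
#' @param dir Target directory.
#' @param scenarios Scenario list (default [build_paper_scenarios()]).
#' @return `dir`, invisibly.
#' @export
write_scenarios <- function(dir, scenarios = build_paper_scenarios()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (sc in scenarios) {
    base <- file.path(dir, sc$name)
    write_gene_tree(sc$tree, paste0(base, ".nwk"))
    fam <- rbind(sc$family$used[c("species", "symbol")], sc$family$off_root)
    fam <- data.frame(root = rep(sc$family$family_root, nrow(fam)), fam,
                      stringsAsFactors = FALSE)
    utils::write.table(fam, paste0(base, ".family.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(sc$expected_proposals))
      jsonlite::write_json(sc$expected_proposals,
                           paste0(base, ".expected.json"))
  }
  invisible(dir)
}
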