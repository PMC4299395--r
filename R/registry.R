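# Event-sourced gene registry
#
# The registry is a mutable environment holding gene records, per-chromosome
# numeric-code counters and an append-only event log.  Every mutation goes
# through a single event-application function, so replaying the log from an
# empty registry reproduces the state exactly, and identifiers are never
# reused: counters only ever advance.

.event_types <- c("create", "merge", "split", "relocate", "structural_edit",
                  "rename", "synonym_added", "variant_added", "retire")

.registry_error <- function(subclass, message) {
  stop(structure(
    class = c(subclass, "registry_error", "error", "condition"),
    list(message = message, call = NULL)))
}

.empty_synonyms <- function() {
  data.frame(name = character(), kind = character(), note = character(),
             note_text = character(), reference = character(),
             stringsAsFactors = FALSE)
}

#' Create an empty gene registry
#'
#' The registry keys records by the bare identifier (taxon, chromosome,
#' object type, numeric code) and keeps one numeric-code counter per
#' chromosome, shared across all object types.  Counters may be seeded to
#' reflect codes already issued by an earlier annotation release; they can
#' never decrease afterwards.
#'
#' @param taxon Taxon code for identifiers issued by this registry
#'   (default `"VITVI"`).
#' @param counters Optional integer vector of length 20 (chromosomes 00-19)
#'   giving the highest numeric code already issued per chromosome.
#' @return A mutable object of class `gene_registry`.
#' @examples
#' reg <- registry_new()
#' create_gene(reg, chromosome = 18)
#' @export
registry_new <- function(taxon = "VITVI", counters = NULL) {
  if (is.null(counters)) counters <- integer(20L)
  stopifnot(length(counters) == 20L, all(counters >= 0L), all(counters <= 99999L))
  reg <- new.env(parent = emptyenv())
  reg$taxon <- toupper(taxon)
  reg$records <- list()
  reg$events <- list()
  reg$counters <- as.integer(counters)
  reg$base_counters <- as.integer(counters)
  class(reg) <- "gene_registry"
  reg
}

#' @export
print.gene_registry <- function(x, ...) {
  n_active <- sum(vapply(x$records, function(r) r$status == "active", logical(1)))
  cat(sprintf("<gene_registry> taxon %s: %d records (%d active), %d events\n",
              x$taxon, length(x$records), n_active, length(x$events)))
  invisible(x)
}

# bare registry key for a locus id (variant/version stripped)
.reg_key <- function(id) {
  if (is.character(id)) id <- parse_locus_id(id)
  format_locus_id(locus_id(id$taxon, id$chromosome, id$object_type,
                           id$numeric_code))
}

.get_record <- function(reg, id, allow_retired = FALSE, op = "operation") {
  key <- .reg_key(id)
  rec <- reg$records[[key]]
  if (is.null(rec))
    .registry_error("registry_unknown_id_error",
                    sprintf("%s: unknown locus ID %s", op, key))
  if (!allow_retired && rec$status != "active")
    .registry_error("registry_retired_id_error",
                    sprintf("%s: locus ID %s is retired", op, key))
  rec
}

# ---- event application -----------------------------------------------------
# The single place where registry state changes.  Operations validate
# preconditions, construct an event, and hand it here; replay feeds stored
# events through the same code path.

.apply_event <- function(reg, event) {
  stopifnot(event$event_type %in% .event_types)
  event$sequence_number <- length(reg$events) + 1L
  p <- event$payload
  switch(event$event_type,
    create = {
      key <- p$id
      id <- parse_locus_id(key)
      reg$counters[id$chromosome + 1L] <-
        max(reg$counters[id$chromosome + 1L], id$numeric_code)
      reg$records[[key]] <- list(
        locus_id = id, status = "active", version = 1L,
        symbol = NULL, full_name = NULL, curation_label = NULL,
        synonyms = .empty_synonyms(), variants = character(),
        successor = NULL)
    },
    merge = {
      surv <- reg$records[[p$survivor]]
      disc <- reg$records[[p$discarded]]
      disc$status <- "retired"
      disc$successor <- p$survivor
      surv$version <- surv$version + 1L
      surv$synonyms <- rbind(surv$synonyms, data.frame(
        name = p$discarded, kind = "locus_id", note = "none",
        note_text = "retired by merge", reference = NA_character_,
        stringsAsFactors = FALSE))
      reg$records[[p$discarded]] <- disc
      reg$records[[p$survivor]] <- surv
    },
    split = {
      orig <- reg$records[[p$id]]
      orig$version <- orig$version + 1L
      reg$records[[p$id]] <- orig
      for (key in p$new_ids) {
        id <- parse_locus_id(key)
        reg$counters[id$chromosome + 1L] <-
          max(reg$counters[id$chromosome + 1L], id$numeric_code)
        reg$records[[key]] <- list(
          locus_id = id, status = "active", version = 1L,
          symbol = NULL, full_name = NULL, curation_label = NULL,
          synonyms = .empty_synonyms(), variants = character(),
          successor = NULL)
      }
    },
    relocate = {
      old <- reg$records[[p$old_id]]
      new_id <- parse_locus_id(p$new_id)
      reg$counters[new_id$chromosome + 1L] <-
        max(reg$counters[new_id$chromosome + 1L], new_id$numeric_code)
      old$status <- "retired"
      old$successor <- p$new_id
      reg$records[[p$old_id]] <- old
      reg$records[[p$new_id]] <- list(
        locus_id = new_id, status = "active", version = 1L,
        symbol = old$symbol, full_name = old$full_name,
        curation_label = old$curation_label,
        synonyms = rbind(old$synonyms, data.frame(
          name = p$old_id, kind = "locus_id", note = "obsolete",
          note_text = "relocated from this locus ID", reference = NA_character_,
          stringsAsFactors = FALSE)),
        variants = old$variants, successor = NULL)
    },
    structural_edit = {
      rec <- reg$records[[p$id]]
      rec$version <- rec$version + 1L
      reg$records[[p$id]] <- rec
    },
    rename = {
      rec <- reg$records[[p$id]]
      rec$symbol <- p$symbol
      if (!is.null(p$full_name)) rec$full_name <- p$full_name
      reg$records[[p$id]] <- rec
    },
    synonym_added = {
      rec <- reg$records[[p$id]]
      rec$synonyms <- rbind(rec$synonyms, data.frame(
        name = p$name, kind = p$kind, note = p$note,
        note_text = p$note_text, reference = p$reference,
        stringsAsFactors = FALSE))
      reg$records[[p$id]] <- rec
    },
    variant_added = {
      rec <- reg$records[[p$id]]
      rec$variants <- c(rec$variants, p$token)
      reg$records[[p$id]] <- rec
    },
    retire = {
      rec <- reg$records[[p$id]]
      rec$status <- "retired"
      reg$records[[p$id]] <- rec
    })
  reg$events[[event$sequence_number]] <- event
  invisible(event)
}

.make_event <- function(event_type, subjects, payload, actor) {
  list(event_type = event_type, subjects = as.character(subjects),
       payload = payload, actor = actor)
}

# ---- lifecycle operations --------------------------------------------------

#' Assign a new locus identifier
#'
#' Issues the next available numeric code on the chromosome (counter + 1;
#' increments are always +1, leaving no gaps) and creates an active record
#' at version 1.  Each chromosome holds up to 99,999 codes shared across
#' all object types.
#'
#' @param reg A [registry_new()] registry (modified in place).
#' @param chromosome Integer 0--19.
#' @param object_type Object-type token (default `"g"`).
#' @param actor Curator name recorded on the event.
#' @return The newly assigned [locus_id()].
#' @export
create_gene <- function(reg, chromosome, object_type = "g",
                        actor = "curator") {
  stopifnot(inherits(reg, "gene_registry"))
  chromosome <- as.integer(chromosome)
  if (chromosome < 0L || chromosome > 19L)
    .registry_error("registry_chromosome_error",
                    sprintf("chromosome %d outside range 00-19", chromosome))
  if (!object_type %in% names(object_type_codes()))
    .registry_error("registry_object_type_error",
                    sprintf("unknown object-type token '%s'", object_type))
  ctr <- reg$counters[chromosome + 1L]
  if (ctr >= 99999L)
    .registry_error("registry_capacity_error",
                    sprintf("chromosome %02d has exhausted its 99,999 numeric codes",
                            chromosome))
  id <- locus_id(reg$taxon, chromosome, object_type, ctr + 1L)
  key <- format_locus_id(id)
  .apply_event(reg, .make_event("create", key, list(id = key), actor))
  id
}

#' Merge two gene models
#'
#' One identifier survives, the other is discarded: the discarded record is
#' retired with the survivor as successor, the discarded identifier becomes
#' a `locus_id` synonym of the survivor, and the survivor's version is
#' bumped.  Discarded codes are never reissued.  Both genes must be active
#' and on the same chromosome with the same object type; cross-chromosome
#' merges require a prior relocation.
#'
#' @param reg Registry (modified in place).
#' @param survivor,discarded [locus_id()] objects or identifier strings.
#' @param actor Curator name.
#' @return The survivor's updated record, invisibly.
#' @export
merge_genes <- function(reg, survivor, discarded, actor = "curator") {
  stopifnot(inherits(reg, "gene_registry"))
  ks <- .reg_key(survivor); kd <- .reg_key(discarded)
  if (ks == kd)
    .registry_error("registry_self_merge_error",
                    sprintf("cannot merge %s with itself", ks))
  rs <- .get_record(reg, ks, op = "merge")
  rd <- .get_record(reg, kd, op = "merge")
  if (rs$locus_id$chromosome != rd$locus_id$chromosome)
    .registry_error("registry_cross_chromosome_error",
                    sprintf("cross-chromosome merge %s + %s; relocate first", ks, kd))
  if (rs$locus_id$object_type != rd$locus_id$object_type)
    .registry_error("registry_object_type_error",
                    sprintf("merge of differing object types %s + %s", ks, kd))
  .apply_event(reg, .make_event("merge", c(ks, kd),
                                list(survivor = ks, discarded = kd), actor))
  invisible(reg$records[[ks]])
}

#' Split a gene model
#'
#' The original gene keeps its identifier at version + 1 (its structure
#' changed); each additional model receives a fresh identifier allocated
#' with [create_gene()] semantics on the same chromosome.
#'
#' @param reg Registry (modified in place).
#' @param id Active [locus_id()] or identifier string.
#' @param n_new Number of additional gene models (>= 1).
#' @param actor Curator name.
#' @return List of the freshly assigned [locus_id()]s.
#' @export
split_gene <- function(reg, id, n_new = 1L, actor = "curator") {
  stopifnot(inherits(reg, "gene_registry"), n_new >= 1L)
  key <- .reg_key(id)
  rec <- .get_record(reg, key, op = "split")
  chrom <- rec$locus_id$chromosome
  ctr <- reg$counters[chrom + 1L]
  if (ctr + n_new > 99999L)
    .registry_error("registry_capacity_error",
                    sprintf("chromosome %02d cannot issue %d further codes", chrom, n_new))
  new_ids <- lapply(seq_len(n_new), function(i)
    locus_id(reg$taxon, chrom, rec$locus_id$object_type, ctr + i))
  new_keys <- vapply(new_ids, format_locus_id, character(1))
  .apply_event(reg, .make_event("split", c(key, new_keys),
                                list(id = key, new_ids = new_keys), actor))
  new_ids
}

#' Relocate a gene to another chromosome
#'
#' Used chiefly when unanchored chromosome-00 scaffolds are placed: a new
#' identifier is issued in series on the target chromosome, the old record
#' is retired with the new identifier as successor, and the old identifier
#' is stored as a synonym of the new record.  Relocation to the same
#' chromosome is an error -- a change of scaffold orientation changes
#' nothing.
#'
#' @param reg Registry (modified in place).
#' @param id Active [locus_id()] or identifier string.
#' @param new_chromosome Target chromosome, 0--19, different from the
#'   current one.
#' @param actor Curator name.
#' @return The newly assigned [locus_id()].
#' @export
relocate_gene <- function(reg, id, new_chromosome, actor = "curator") {
  stopifnot(inherits(reg, "gene_registry"))
  key <- .reg_key(id)
  rec <- .get_record(reg, key, op = "relocate")
  new_chromosome <- as.integer(new_chromosome)
  if (new_chromosome < 0L || new_chromosome > 19L)
    .registry_error("registry_chromosome_error",
                    sprintf("chromosome %d outside range 00-19", new_chromosome))
  if (new_chromosome == rec$locus_id$chromosome)
    .registry_error("registry_same_chromosome_error",
                    sprintf("relocation of %s to its own chromosome changes nothing", key))
  ctr <- reg$counters[new_chromosome + 1L]
  if (ctr >= 99999L)
    .registry_error("registry_capacity_error",
                    sprintf("chromosome %02d has exhausted its numeric codes",
                            new_chromosome))
  new_id <- locus_id(reg$taxon, new_chromosome, rec$locus_id$object_type,
                     ctr + 1L)
  new_key <- format_locus_id(new_id)
  .apply_event(reg, .make_event("relocate", c(key, new_key),
                                list(old_id = key, new_id = new_key), actor))
  new_id
}

#' Bump a gene model's version
#'
#' Any modification of the structural annotation -- addition or deletion of
#' any number of nucleotides -- increments the version by exactly 1.
#' Version numbers render after a dot; an identifier without a version
#' suffix refers to the most recent version.
#'
#' @param reg Registry (modified in place).
#' @param id Active [locus_id()] or identifier string.
#' @param actor Curator name.
#' @return The new version number (integer).
#' @export
bump_version <- function(reg, id, actor = "curator") {
  stopifnot(inherits(reg, "gene_registry"))
  key <- .reg_key(id)
  .get_record(reg, key, op = "version bump")
  .apply_event(reg, .make_event("structural_edit", key, list(id = key), actor))
  reg$records[[key]]$version
}

#' Allocate a sequence-variant token
#'
#' Composes a variant token from an optional cultivar prefix, an allele
#' letter code and an optional splice index (e.g. allele `"a"` splice 2
#' with cultivar prefix `"tp"` gives `"tpa2"`).  Splice indices are
#' admissible only on object types `t` and `p`, and each token must be
#' unique for the locus.
#'
#' @param reg Registry (modified in place).
#' @param id Active [locus_id()] or identifier string.
#' @param allele_code Lowercase allele letter(s), e.g. `"a"`.
#' @param splice_index Optional integer splice-form index.
#' @param cultivar_prefix Optional lowercase cultivar abbreviation.
#' @param actor Curator name.
#' @return The registered variant token (character).
#' @export
allocate_variant <- function(reg, id, allele_code, splice_index = NULL,
                             cultivar_prefix = NULL, actor = "curator") {
  stopifnot(inherits(reg, "gene_registry"))
  key <- .reg_key(id)
  rec <- .get_record(reg, key, op = "variant allocation")
  if (!is.null(splice_index) && !rec$locus_id$object_type %in% .splice_types)
    .registry_error("registry_splice_error",
                    sprintf("splice index on object type '%s'; only t/p admit splice variants",
                            rec$locus_id$object_type))
  token <- paste0(if (is.null(cultivar_prefix)) "" else tolower(cultivar_prefix),
                  tolower(allele_code),
                  if (is.null(splice_index)) "" else as.integer(splice_index))
  if (!.valid_variant(token))
    .registry_error("registry_variant_error",
                    sprintf("composed variant token '%s' is malformed", token))
  if (token %in% rec$variants)
    .registry_error("registry_duplicate_variant_error",
                    sprintf("variant token '%s' already allocated on %s", token, key))
  .apply_event(reg, .make_event("variant_added", key,
                                list(id = key, token = token), actor))
  token
}

#' Record a synonym
#'
#' All previously used names of a gene -- symbols, full names, retired or
#' legacy locus identifiers -- are retained as synonyms, optionally flagged
#' `obsolete`, `incorrect` or `ambiguous` with free text and a bibliographic
#' reference.  The pair (name, kind) is unique per gene, case-insensitively
#' on the name.
#'
#' @param reg Registry (modified in place).
#' @param id Active [locus_id()] or identifier string.
#' @param name Synonym text.
#' @param kind One of `"symbol"`, `"full_name"`, `"locus_id"`, `"legacy_id"`.
#' @param note One of `"none"`, `"obsolete"`, `"incorrect"`, `"ambiguous"`.
#' @param note_text Optional free-text elaboration of the note.
#' @param reference Optional bibliographic token (doi, PubMed ID, ...).
#' @param actor Curator name.
#' @return The gene's updated record, invisibly.
#' @export
add_synonym <- function(reg, id, name,
                        kind = c("symbol", "full_name", "locus_id", "legacy_id"),
                        note = c("none", "obsolete", "incorrect", "ambiguous"),
                        note_text = "", reference = NA_character_,
                        actor = "curator") {
  stopifnot(inherits(reg, "gene_registry"), is.character(name), nzchar(name))
  kind <- match.arg(kind)
  note <- match.arg(note)
  key <- .reg_key(id)
  rec <- .get_record(reg, key, op = "synonym")
  dup <- tolower(rec$synonyms$name) == tolower(name) & rec$synonyms$kind == kind
  if (any(dup))
    .registry_error("registry_duplicate_synonym_error",
                    sprintf("synonym ('%s', %s) already present on %s", name, kind, key))
  .apply_event(reg, .make_event(
    "synonym_added", key,
    list(id = key, name = name, kind = kind, note = note,
         note_text = note_text, reference = reference), actor))
  invisible(reg$records[[key]])
}

#' Set or replace a gene's symbol and full name
#'
#' @param reg Registry (modified in place).
#' @param id Active [locus_id()] or identifier string.
#' @param symbol New symbol.
#' @param full_name Optional new full name.
#' @param actor Curator name.
#' @return The updated record, invisibly.
#' @export
rename_gene <- function(reg, id, symbol, full_name = NULL,
                        actor = "curator") {
  stopifnot(inherits(reg, "gene_registry"))
  key <- .reg_key(id)
  .get_record(reg, key, op = "rename")
  .apply_event(reg, .make_event(
    "rename", key, list(id = key, symbol = symbol, full_name = full_name),
    actor))
  invisible(reg$records[[key]])
}

#' Retrieve the event history of a locus identifier
#'
#' Events are never removed: the history of a retired identifier remains
#' retrievable, in sequence order.
#'
#' @param reg Registry.
#' @param id [locus_id()] or identifier string (active or retired).
#' @return List of events touching the identifier, in sequence order.
#' @export
get_history <- function(reg, id) {
  stopifnot(inherits(reg, "gene_registry"))
  key <- .reg_key(id)
  .get_record(reg, key, allow_retired = TRUE, op = "history")
  Filter(function(e) key %in% e$subjects, reg$events)
}

#' Look up a gene record
#'
#' @param reg Registry.
#' @param id [locus_id()] or identifier string.
#' @param follow_successors If `TRUE`, resolve retired identifiers through
#'   successor links to the current active record.
#' @return The gene record (a list).
#' @export
get_record <- function(reg, id, follow_successors = FALSE) {
  rec <- .get_record(reg, id, allow_retired = TRUE, op = "lookup")
  if (follow_successors) {
    seen <- character()
    while (rec$status == "retired" && !is.null(rec$successor)) {
      if (rec$successor %in% seen)
        .registry_error("registry_cycle_error", "successor cycle detected")
      seen <- c(seen, rec$successor)
      rec <- .get_record(reg, rec$successor, allow_retired = TRUE,
                         op = "lookup")
    }
  }
  rec
}

#' Resolve an identifier to its current active record
#'
#' Follows successor links from a possibly retired identifier; returns the
#' active identifier, or the terminal retired identifier when the lineage
#' ends in a retirement.
#'
#' @param reg Registry.
#' @param id [locus_id()] or identifier string.
#' @return A [locus_id()].
#' @export
resolve_id <- function(reg, id) {
  get_record(reg, id, follow_successors = TRUE)$locus_id
}

# ---- replay ----------------------------------------------------------------

#' Rebuild a registry by replaying an event log
#'
#' The event log is the registry's source of truth: replaying it from an
#' empty registry (with the same taxon and seed counters) reproduces the
#' state exactly.
#'
#' @param events List of events, as stored in a registry's `$events`.
#' @param taxon Taxon code of the original registry.
#' @param base_counters The original registry's seed counters.
#' @return A `gene_registry` equal in state to the one that produced the log.
#' @export
replay_events <- function(events, taxon = "VITVI",
                          base_counters = integer(20L)) {
  reg <- registry_new(taxon, counters = base_counters)
  for (e in events) .apply_event(reg, e)
  reg
}

#' Snapshot a registry's state for comparison
#'
#' Returns the registry's complete state (records, counters, events) as an
#' ordinary list, suitable for equality testing between a live registry and
#' a replayed one.
#'
#' @param reg Registry.
#' @return A list with elements `taxon`, `records`, `counters`, `events`.
#' @export
registry_state <- function(reg) {
  stopifnot(inherits(reg, "gene_registry"))
  list(taxon = reg$taxon,
       records = reg$records[order(names(reg$records))],
       counters = reg$counters,
       events = reg$events)
}

#' All identifiers ever issued by a registry
#'
#' @param reg Registry.
#' @param status `"all"`, `"active"` or `"retired"`.
#' @return Character vector of identifier strings.
#' @export
registry_ids <- function(reg, status = c("all", "active", "retired")) {
  status <- match.arg(status)
  keys <- names(reg$records)
  if (status == "all") return(keys)
  keep <- vapply(reg$records, function(r) r$status == status, logical(1))
  keys[keep]
}
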