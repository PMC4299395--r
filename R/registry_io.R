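# Registry persistence
#
# A registry directory holds:
#   meta.json     - taxon, seed counters, schema version
#   events.jsonl  - the append-only event log, one JSON object per line
#   registry.tsv  - projection: one row per record
#   synonyms.tsv  - projection: one row per synonym
# The event log is authoritative; the TSV files are human/tool-facing
# projections rebuilt on every write.  Reading replays events.jsonl.

#' Write a registry to a directory
#'
#' @param reg A `gene_registry`.
#' @param dir Target directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_registry <- function(reg, dir) {
  stopifnot(inherits(reg, "gene_registry"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  meta <- list(schema = 1L, taxon = reg$taxon,
               base_counters = reg$base_counters)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)

  lines <- vapply(reg$events, function(e) {
    jsonlite::toJSON(list(schema = 1L,
                          sequence_number = e$sequence_number,
                          event_type = e$event_type,
                          subjects = e$subjects,
                          payload = e$payload,
                          actor = e$actor),
                     auto_unbox = TRUE, null = "null")
  }, character(1))
  writeLines(lines, file.path(dir, "events.jsonl"))

  recs <- reg$records
  reg_df <- data.frame(
    id = names(recs),
    status = vapply(recs, `[[`, character(1), "status"),
    version = vapply(recs, `[[`, integer(1), "version"),
    symbol = vapply(recs, function(r) r$symbol %||% NA_character_, character(1)),
    full_name = vapply(recs, function(r) r$full_name %||% NA_character_, character(1)),
    curation_label = vapply(recs, function(r) {
      if (is.null(r$curation_label)) NA_character_ else r$curation_label$level
    }, character(1)),
    successor = vapply(recs, function(r) r$successor %||% NA_character_, character(1)),
    variants = vapply(recs, function(r) paste(r$variants, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  reg_df <- reg_df[order(reg_df$id), , drop = FALSE]
  utils::write.table(reg_df, file.path(dir, "registry.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")

  syn_rows <- lapply(names(recs), function(key) {
    s <- recs[[key]]$synonyms
    if (nrow(s) == 0L) return(NULL)
    cbind(data.frame(id = key, stringsAsFactors = FALSE), s)
  })
  syn_df <- do.call(rbind, syn_rows)
  if (is.null(syn_df))
    syn_df <- cbind(data.frame(id = character(), stringsAsFactors = FALSE),
                    .empty_synonyms())
  utils::write.table(syn_df, file.path(dir, "synonyms.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(dir)
}

#' Read a registry from a directory
#'
#' Replays `events.jsonl` from an empty registry seeded with the stored
#' taxon and counters.
#'
#' @param dir Directory written by [write_registry()].
#' @return A `gene_registry`.
#' @export
read_registry <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  events_path <- file.path(dir, "events.jsonl")
  if (!file.exists(meta_path) || !file.exists(events_path))
    .registry_error("registry_io_error",
                    sprintf("'%s' is not a registry directory", dir))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  lines <- readLines(events_path)
  lines <- lines[nzchar(lines)]
  events <- lapply(lines, function(ln) {
    e <- jsonlite::fromJSON(ln, simplifyVector = TRUE, simplifyDataFrame = FALSE)
    list(event_type = e$event_type,
         subjects = unlist(e$subjects),
         payload = lapply(e$payload, function(x)
           if (length(x) > 1L) unlist(x) else x),
         actor = e$actor)
  })
  replay_events(events, taxon = meta$taxon,
                base_counters = as.integer(unlist(meta$base_counters)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
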