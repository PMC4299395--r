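# Locus-identifier grammar
#
# A locus identifier is the concatenation of six elements:
#   taxon code | chromosome | object type | numeric code | -variant | .version
# e.g. "Vitvi18g12230" or "Vitvi05t00480-tpa2.3".

#' Admissible object-type codes
#'
#' The eleven one- or two-letter tokens describing the molecular entity a
#' locus identifier refers to: `g` gene, `t` protein-coding transcript,
#' `p` protein, `nc` non-coding, `tr` tRNA, `te` transposable element,
#' `rr` rRNA, `mi` miRNA, `ps` pseudogene, `si` siRNA, `sn` snRNA.
#' Splice-variant digits are admissible only on `t` and `p`.
#'
#' @return Named character vector mapping each token to its description.
#' @export
object_type_codes <- function() {
  c(g  = "gene",
    t  = "protein coding transcript",
    p  = "protein",
    nc = "non-coding",
    tr = "transfer RNA",
    te = "transposable element",
    rr = "ribosomal RNA",
    mi = "microRNA",
    ps = "pseudogene",
    si = "small interfering RNA",
    sn = "small nuclear RNA")
}

# object types on which a splice digit is admissible
.splice_types <- c("t", "p")

.locus_error <- function(subclass, message) {
  stop(structure(
    class = c(subclass, "locus_parse_error", "error", "condition"),
    list(message = message, call = NULL)))
}

.valid_taxon <- function(taxon) {
  n <- nchar(taxon)
  n >= 5L && n <= 6L && grepl("^VIT[A-Z]{2,3}$", toupper(taxon))
}

# variant token: lowercase letters then an optional digit run, never empty
.valid_variant <- function(v) grepl("^[a-z]*[0-9]*$", v) && nzchar(v)

# does the variant carry a splice digit run?
.variant_has_splice_digit <- function(v) grepl("[0-9]$", v)

#' Construct a locus identifier
#'
#' Builds a structured locus identifier from its six elements.  Structural
#' element types are checked here; rule-level checks (splice digits on
#' non-transcript objects, out-of-range fields) are reported by
#' [validate_locus_id()].
#'
#' @param taxon Taxon code (5--6 letters, `VIT` + species code, e.g.
#'   `"VITVI"`); stored uppercase.
#' @param chromosome Integer chromosome number, 0--19 (0 is the unanchored
#'   scaffold bin rendered as `"00"`).
#' @param object_type One of [object_type_codes()].
#' @param numeric_code Integer 1--99999, rendered as five digits.
#' @param variant Optional variant token (lowercase letters then an optional
#'   digit run, e.g. `"a2"`, `"tpb4"`), or `NULL` if absent.
#' @param version Optional integer version (>= 1), or `NULL`; an absent
#'   version means "most recent".
#' @return An object of class `locus_id`.
#' @examples
#' locus_id("VITVI", 18, "g", 12230)
#' @export
locus_id <- function(taxon, chromosome, object_type, numeric_code,
                     variant = NULL, version = NULL) {
  stopifnot(is.character(taxon), length(taxon) == 1L)
  id <- structure(
    list(taxon        = toupper(taxon),
         chromosome   = as.integer(chromosome),
         object_type  = as.character(object_type),
         numeric_code = as.integer(numeric_code),
         variant      = if (!is.null(variant) && !is.na(variant))
                          as.character(variant) else NULL,
         version      = if (!is.null(version) && !is.na(version))
                          as.integer(version) else NULL),
    class = "locus_id")
  id
}

#' Parse a locus identifier string
#'
#' Parses an identifier in the structured grammar (e.g. `"Vitvi18g12230"`,
#' `"Vitvi05t00480-tpa2.3"`) into its six elements.  The taxon code is
#' case-insensitive on input.  Malformed input raises a condition of class
#' `locus_parse_error` with one specific subclass naming the offending
#' element: `locus_taxon_error`, `locus_chromosome_error`,
#' `locus_object_type_error`, `locus_code_error`, `locus_variant_error`,
#' `locus_version_error`, or `locus_syntax_error` when the overall shape is
#' unrecognisable.
#'
#' @param text A single identifier string.
#' @return A [locus_id()] object.  Absent variant/version are `NULL`
#'   (an absent version means the most recent version of the gene model).
#' @examples
#' parse_locus_id("Vitvi18g12230")
#' parse_locus_id("Vitvi05t00480-tpa2.3")
#' @export
parse_locus_id <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(text))
    .locus_error("locus_syntax_error", "empty identifier string")

  m <- regexec(
    "^([A-Za-z]+)([0-9]{2})([A-Za-z]{1,2})([0-9]+)(-[A-Za-z0-9]+)?(\\.[A-Za-z0-9]+)?$",
    text)
  parts <- regmatches(text, m)[[1]]
  if (length(parts) == 0L)
    .locus_error("locus_syntax_error",
                 sprintf("'%s' does not match the locus identifier shape", text))

  taxon   <- parts[2]
  chrom   <- parts[3]
  otype   <- tolower(parts[4])
  code    <- parts[5]
  variant <- sub("^-", "", parts[6])
  version <- sub("^\\.", "", parts[7])

  if (!.valid_taxon(taxon))
    .locus_error("locus_taxon_error",
                 sprintf("malformed taxon code '%s' (expected VIT + 2-3 letters)", taxon))
  chrom_i <- as.integer(chrom)
  if (chrom_i > 19L)
    .locus_error("locus_chromosome_error",
                 sprintf("chromosome %s outside the admissible range 00-19", chrom))
  if (!otype %in% names(object_type_codes()))
    .locus_error("locus_object_type_error",
                 sprintf("unknown object-type token '%s'", otype))
  if (nchar(code) != 5L)
    .locus_error("locus_code_error",
                 sprintf("numeric code '%s' must have exactly 5 digits", code))
  code_i <- as.integer(code)
  if (code_i < 1L)
    .locus_error("locus_code_error", "numeric code must be >= 00001")
  if (nzchar(variant) && !.valid_variant(tolower(variant)))
    .locus_error("locus_variant_error",
                 sprintf("malformed variant token '%s'", variant))
  version_i <- NULL
  if (nzchar(version)) {
    if (!grepl("^[0-9]+$", version) || as.integer(version) < 1L)
      .locus_error("locus_version_error",
                   sprintf("malformed version suffix '%s' (integer >= 1 expected)", version))
    version_i <- as.integer(version)
  }

  locus_id(taxon, chrom_i, otype, code_i,
           variant = if (nzchar(variant)) tolower(variant) else NULL,
           version = version_i)
}

#' Format a locus identifier
#'
#' Renders a structured identifier as text.  The canonical style prints the
#' taxon title-case (`"Vitvi"`), the chromosome zero-padded to two digits,
#' the numeric code to five, a hyphen before the variant and a dot before
#' the version; the uppercase style differs only in printing the taxon
#' fully uppercase.
#'
#' @param id A [locus_id()].
#' @param style `"canonical"` (default) or `"uppercase"`.
#' @return The identifier string.
#' @examples
#' format_locus_id(locus_id("VITVI", 18, "g", 12230))
#' @export
format_locus_id <- function(id, style = c("canonical", "uppercase")) {
  style <- match.arg(style)
  stopifnot(inherits(id, "locus_id"))
  taxon <- if (style == "canonical") {
    paste0(substr(id$taxon, 1, 1),
           tolower(substr(id$taxon, 2, nchar(id$taxon))))
  } else toupper(id$taxon)
  out <- sprintf("%s%02d%s%05d", taxon, id$chromosome, id$object_type,
                 id$numeric_code)
  if (!is.null(id$variant)) out <- paste0(out, "-", id$variant)
  if (!is.null(id$version)) out <- paste0(out, ".", id$version)
  out
}

#' @export
format.locus_id <- function(x, ...) format_locus_id(x)

#' @export
print.locus_id <- function(x, ...) {
  cat("<locus_id> ", format_locus_id(x), "\n", sep = "")
  invisible(x)
}

#' @export
as.character.locus_id <- function(x, ...) format_locus_id(x)

#' @export
`==.locus_id` <- function(e1, e2) compare_ids(e1, e2) == "equal"

#' Validate a locus identifier against the nomenclature rules
#'
#' Checks a structurally well-formed identifier against the rule set:
#' chromosome within 00--19, numeric code within 1--99999, well-formed
#' variant token, splice digits only on object types `t`/`p`, version >= 1,
#' admissible object type and taxon shape.
#'
#' @param id A [locus_id()].
#' @return Character vector of violation messages; empty when all rules
#'   hold.  Violations are returned, never raised.
#' @examples
#' validate_locus_id(locus_id("VITVI", 18, "g", 12230, variant = "a2"))
#' @export
validate_locus_id <- function(id) {
  stopifnot(inherits(id, "locus_id"))
  v <- character()
  if (!.valid_taxon(id$taxon))
    v <- c(v, sprintf("taxon: '%s' is not VIT + 2-3 letters", id$taxon))
  if (is.na(id$chromosome) || id$chromosome < 0L || id$chromosome > 19L)
    v <- c(v, sprintf("chromosome: %s outside range 00-19", id$chromosome))
  if (!id$object_type %in% names(object_type_codes()))
    v <- c(v, sprintf("object_type: unknown token '%s'", id$object_type))
  if (is.na(id$numeric_code) || id$numeric_code < 1L || id$numeric_code > 99999L)
    v <- c(v, sprintf("numeric_code: %s outside range 1-99999", id$numeric_code))
  if (!is.null(id$variant)) {
    if (!.valid_variant(id$variant)) {
      v <- c(v, sprintf("variant: malformed token '%s'", id$variant))
    } else if (.variant_has_splice_digit(id$variant) &&
               !id$object_type %in% .splice_types) {
      v <- c(v, sprintf(
        "variant: splice digit in '%s' admissible only on object types t/p, not '%s'",
        id$variant, id$object_type))
    }
  }
  if (!is.null(id$version) && id$version < 1L)
    v <- c(v, sprintf("version: %d must be >= 1", id$version))
  v
}

#' Parse a legacy 12X-v1 locus identifier
#'
#' Parses identifiers of the earlier grapevine scheme, shaped
#' `VIT` + 2-digit chromosome + `s` + 4-digit scaffold + `g` + 5-digit gene
#' index (e.g. `"VIT06s0009g01380"`).  These identifiers are kept as
#' registry synonyms of their successors.
#'
#' @param text A single identifier string.
#' @return An object of class `legacy_locus_id` with fields `chromosome`,
#'   `scaffold_index`, `gene_index` and `raw`.
#' @examples
#' parse_legacy_id("VIT06s0009g01380")
#' @export
parse_legacy_id <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- regexec("^VIT([0-9]{2})s([0-9]{4})g([0-9]{5})$", text,
               ignore.case = TRUE)
  parts <- regmatches(text, m)[[1]]
  if (length(parts) == 0L)
    .locus_error("legacy_parse_error",
                 sprintf("'%s' does not match the legacy shape VITccsSSSSgGGGGG", text))
  chrom <- as.integer(parts[2])
  if (chrom > 19L)
    .locus_error("legacy_parse_error",
                 sprintf("legacy chromosome %02d outside range 00-19", chrom))
  structure(
    list(chromosome     = chrom,
         scaffold_index = as.integer(parts[3]),
         gene_index     = as.integer(parts[4]),
         raw            = text),
    class = "legacy_locus_id")
}

#' @export
print.legacy_locus_id <- function(x, ...) {
  cat("<legacy_locus_id> ", x$raw, "\n", sep = "")
  invisible(x)
}

# six-element sort key; chromosome / numeric code / object type dominate,
# then taxon, variant, version so that the order is total
.locus_key <- function(id) {
  sprintf("%02d|%05d|%-2s|%-6s|%-10s|%05d",
          id$chromosome, id$numeric_code, id$object_type, id$taxon,
          if (is.null(id$variant)) "" else id$variant,
          if (is.null(id$version)) 0L else id$version)
}

#' Compare two locus identifiers
#'
#' Total order over identifiers: chromosome, then numeric code, then object
#' type, then taxon, variant and version.  Two identifiers compare equal
#' only when all six elements are equal.
#'
#' @param a,b [locus_id()] objects.
#' @return One of `"before"`, `"equal"`, `"after"`.
#' @examples
#' compare_ids(parse_locus_id("Vitvi05g00010"), parse_locus_id("Vitvi18g00001"))
#' @export
compare_ids <- function(a, b) {
  stopifnot(inherits(a, "locus_id"), inherits(b, "locus_id"))
  ka <- .locus_key(a); kb <- .locus_key(b)
  if (ka < kb) "before" else if (ka > kb) "after" else "equal"
}

#' Sort a list of locus identifiers
#'
#' @param ids List of [locus_id()] objects.
#' @return The list in the total order of [compare_ids()].
#' @export
sort_locus_ids <- function(ids) {
  stopifnot(is.list(ids))
  ids[order(vapply(ids, .locus_key, character(1)))]
}

#' Parse many identifiers into a data frame
#'
#' Convenience wrapper around [parse_locus_id()] for TSV-style pipelines.
#'
#' @param texts Character vector of identifier strings.
#' @return Data frame with one row per input: `id`, `taxon`, `chromosome`,
#'   `object_type`, `numeric_code`, `variant`, `version` (`NA` when absent).
#' @export
parse_locus_ids <- function(texts) {
  rows <- lapply(texts, function(tx) {
    p <- parse_locus_id(tx)
    data.frame(id = tx, taxon = p$taxon, chromosome = p$chromosome,
               object_type = p$object_type, numeric_code = p$numeric_code,
               variant = if (is.null(p$variant)) NA_character_ else p$variant,
               version = if (is.null(p$version)) NA_integer_ else p$version,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
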