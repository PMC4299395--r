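# Confidence classification of functional annotations
#
# Every locus starts as "hypothetical protein".  Evidence of transcription,
# translation, domain content, cross-species similarity, or experimental
# characterisation moves it up a fixed precedence ladder:
#
#   uncertain (pseudogene) > named > probable > putative > similar_to
#     > domain_containing > expressed > hypothetical
#
# "translated" is an orthogonal qualifier: protein-level evidence proves
# existence, not function, so it stacks on whichever level is reached.

.curation_levels <- c("hypothetical", "expressed", "domain_containing",
                      "similar_to", "putative", "probable", "named",
                      "uncertain")

#' Default similarity and name-transfer thresholds
#'
#' The similarity criterion passes when the best hit has e-value <= 1e-20
#' (inclusive) or at least 30 percent identity over at least 80 contiguous
#' amino acids (both inclusive); direct transfer of a characterised
#' grapevine protein's name requires strictly more than 95 percent identity
#' over the whole sequence.
#'
#' @param evalue_cutoff E-value cut-off, inclusive (default `1e-20`).
#' @param min_identity Minimum percent identity of the best contiguous
#'   block, inclusive (default `30`).
#' @param min_contiguous_length Minimum contiguous alignment length in
#'   amino acids, inclusive (default `80`).
#' @param transfer_identity Exclusive lower bound on whole-sequence percent
#'   identity for direct name transfer (default `95`).
#' @return An object of class `confidence_thresholds`.
#' @export
confidence_thresholds <- function(evalue_cutoff = 1e-20,
                                  min_identity = 30,
                                  min_contiguous_length = 80,
                                  transfer_identity = 95) {
  stopifnot(evalue_cutoff > 0, min_identity > 0, min_contiguous_length > 0,
            transfer_identity > min_identity)
  structure(list(evalue_cutoff = evalue_cutoff,
                 min_identity = min_identity,
                 min_contiguous_length = min_contiguous_length,
                 transfer_identity = transfer_identity),
            class = "confidence_thresholds")
}

#' Describe a homology hit
#'
#' @param subject_name Name of the homologous protein.
#' @param subject_species Species of the subject.
#' @param is_vitis Is the subject a Vitis protein?
#' @param is_characterized Has the subject's function been experimentally
#'   characterised?
#' @param e_value Alignment e-value (> 0).
#' @param percent_identity Percent identity of the best contiguous block.
#' @param aligned_length Length of that contiguous block, in amino acids.
#' @param whole_sequence_identity Percent identity over the whole sequence.
#' @return One-row data frame.
#' @export
homology_hit <- function(subject_name, subject_species = NA_character_,
                         is_vitis = FALSE, is_characterized = FALSE,
                         e_value, percent_identity = 0,
                         aligned_length = 0L,
                         whole_sequence_identity = 0) {
  stopifnot(e_value > 0,
            percent_identity >= 0, percent_identity <= 100,
            whole_sequence_identity >= 0, whole_sequence_identity <= 100,
            aligned_length >= 0)
  data.frame(subject_name = subject_name, subject_species = subject_species,
             is_vitis = is_vitis, is_characterized = is_characterized,
             e_value = e_value, percent_identity = percent_identity,
             aligned_length = as.integer(aligned_length),
             whole_sequence_identity = whole_sequence_identity,
             stringsAsFactors = FALSE)
}

#' Bundle the evidence available for one gene
#'
#' @param transcript_evidence Proof of existence of RNA (RT-PCR, EST,
#'   RNA-seq, Northern blot, microarray, ...).
#' @param protein_evidence Evidence at the protein level (Edman sequencing,
#'   mass spectrometry, structure, interaction, antibody detection).
#' @param pseudogene_evidence Evidence that the sequence is a pseudogene.
#' @param functional_evidence `"none"`, `"in_silico"`,
#'   `"some_experimental"` or `"characterized_in_vitis"`; the last requires
#'   `functional_name`.
#' @param functional_name Name attached to the characterised function, when
#'   `functional_evidence = "characterized_in_vitis"`.
#' @param domain_hits Character vector of domain names found on the protein.
#' @param homology_hits Data frame of [homology_hit()] rows (rbind them).
#' @param go_code Optional free-text GO evidence code, recorded when
#'   functional evidence is at least `"some_experimental"`.
#' @return An object of class `evidence_bundle`.
#' @export
evidence_bundle <- function(transcript_evidence = FALSE,
                            protein_evidence = FALSE,
                            pseudogene_evidence = FALSE,
                            functional_evidence = c("none", "in_silico",
                                                    "some_experimental",
                                                    "characterized_in_vitis"),
                            functional_name = NULL,
                            domain_hits = character(),
                            homology_hits = NULL,
                            go_code = NULL) {
  functional_evidence <- match.arg(functional_evidence)
  if (functional_evidence == "characterized_in_vitis" &&
      (is.null(functional_name) || !nzchar(functional_name)))
    stop("characterized_in_vitis evidence requires a functional_name")
  structure(list(transcript_evidence = isTRUE(transcript_evidence),
                 protein_evidence = isTRUE(protein_evidence),
                 pseudogene_evidence = isTRUE(pseudogene_evidence),
                 functional_evidence = functional_evidence,
                 functional_name = functional_name,
                 domain_hits = as.character(domain_hits),
                 homology_hits = homology_hits,
                 go_code = go_code),
            class = "evidence_bundle")
}

# best hit: smallest e-value; ties by higher identity, longer alignment,
# then lexical subject name
.best_hit <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0L) return(NULL)
  o <- order(hits$e_value, -hits$percent_identity, -hits$aligned_length,
             hits$subject_name)
  hits[o[1L], , drop = FALSE]
}

.similarity_passes <- function(hit, th) {
  !is.null(hit) &&
    (hit$e_value <= th$evalue_cutoff ||
       (hit$percent_identity >= th$min_identity &&
          hit$aligned_length >= th$min_contiguous_length))
}

.transfer_hit <- function(hits, th) {
  if (is.null(hits) || nrow(hits) == 0L) return(NULL)
  ok <- hits$is_vitis & hits$is_characterized &
    hits$whole_sequence_identity > th$transfer_identity
  if (!any(ok)) return(NULL)
  cand <- hits[ok, , drop = FALSE]
  o <- order(-cand$whole_sequence_identity, cand$e_value, cand$subject_name)
  cand[o[1L], , drop = FALSE]
}

#' Classify the confidence level of a functional annotation
#'
#' Walks the evidence down a fixed precedence ladder and returns the
#' highest level supported: `uncertain` when there is pseudogene evidence;
#' `named` when the gene is experimentally characterised in Vitis or a
#' characterised grapevine protein matches at more than the transfer
#' identity over the whole sequence; `probable` with some experimental
#' functional evidence; `putative` with in-silico functional evidence;
#' `similar_to` when transcript evidence is present and the best hit meets
#' the similarity criterion (e-value or identity/length); `domain_containing`
#' when transcript evidence and a domain hit exist; `expressed` on
#' transcript evidence alone; otherwise `hypothetical`.  Protein-level
#' evidence adds the orthogonal `translated` qualifier at any level.
#'
#' @param evidence An [evidence_bundle()].
#' @param thresholds A [confidence_thresholds()] (defaults as printed).
#' @return An object of class `curation_label` with fields `level`,
#'   `payload` (the domain, homolog or transferred name; `NULL` where the
#'   level carries none), `qualifiers` (e.g. `"translated"`) and `go_code`.
#' @examples
#' classify_confidence(evidence_bundle(transcript_evidence = TRUE))
#' @export
classify_confidence <- function(evidence,
                                thresholds = confidence_thresholds()) {
  stopifnot(inherits(evidence, "evidence_bundle"),
            inherits(thresholds, "confidence_thresholds"))
  qualifiers <- character()
  if (evidence$protein_evidence) qualifiers <- "translated"

  level <- "hypothetical"; payload <- NULL
  transfer <- .transfer_hit(evidence$homology_hits, thresholds)

  if (evidence$pseudogene_evidence) {
    level <- "uncertain"
  } else if (evidence$functional_evidence == "characterized_in_vitis") {
    level <- "named"; payload <- evidence$functional_name
  } else if (!is.null(transfer)) {
    level <- "named"; payload <- transfer$subject_name
  } else if (evidence$functional_evidence == "some_experimental") {
    level <- "probable"
  } else if (evidence$functional_evidence == "in_silico") {
    level <- "putative"
  } else if (evidence$transcript_evidence &&
             .similarity_passes(.best_hit(evidence$homology_hits), thresholds)) {
    level <- "similar_to"
    payload <- .best_hit(evidence$homology_hits)$subject_name
  } else if (evidence$transcript_evidence &&
             length(evidence$domain_hits) > 0L) {
    level <- "domain_containing"
    payload <- evidence$domain_hits[[1L]]
  } else if (evidence$transcript_evidence) {
    level <- "expressed"
  }

  go_code <- NULL
  if (evidence$functional_evidence %in% c("some_experimental",
                                          "characterized_in_vitis") &&
      !is.null(evidence$go_code))
    go_code <- as.character(evidence$go_code)

  structure(list(level = level, payload = payload, qualifiers = qualifiers,
                 go_code = go_code),
            class = "curation_label")
}

#' @export
print.curation_label <- function(x, ...) {
  cat("<curation_label> ", x$level,
      if (!is.null(x$payload)) paste0(" [", x$payload, "]") else "",
      if (length(x$qualifiers)) paste0(" (+", paste(x$qualifiers, collapse = ","), ")")
      else "", "\n", sep = "")
  invisible(x)
}

#' Render the full-name prefix for a curation label
#'
#' `hypothetical` renders as "hypothetical protein", `expressed` as
#' "expressed protein", `domain_containing` as "<domain> domain containing
#' protein", `similar_to` as "similar to <homolog>", `putative`/`probable`
#' prefix the functional base name, `named` is the transferred name itself,
#' `uncertain` marks a probable pseudogene.
#'
#' @param label A `curation_label`.
#' @param base_name Functional base name, required for `putative` and
#'   `probable`.
#' @return The rendered full name (character).
#' @export
render_full_name <- function(label, base_name = NULL) {
  stopifnot(inherits(label, "curation_label"))
  need_payload <- c("domain_containing", "similar_to", "named")
  if (label$level %in% need_payload && is.null(label$payload))
    stop(sprintf("level '%s' requires a payload", label$level))
  switch(label$level,
    hypothetical = "hypothetical protein",
    expressed = "expressed protein",
    domain_containing = paste0(label$payload, " domain containing protein"),
    similar_to = paste0("similar to ", label$payload),
    named = label$payload,
    putative = {
      if (is.null(base_name)) stop("'putative' requires a base_name")
      paste("putative", base_name)
    },
    probable = {
      if (is.null(base_name)) stop("'probable' requires a base_name")
      paste("probable", base_name)
    },
    uncertain = "uncertain protein (probable pseudogene)")
}

#' Recover a classifier decision boundary by scanning
#'
#' Reclassifies a fixed evidence template while sweeping one axis over a
#' sorted grid and reports the boundary value where the classification
#' changes: for `e_value`, the largest grid value still classified
#' `similar_to`; for `identity`, the smallest grid value classified
#' `similar_to`; for `transfer_identity`, the largest grid value at which
#' direct name transfer (`named`) is still refused.
#'
#' @param axis `"e_value"`, `"identity"` or `"transfer_identity"`.
#' @param evidence_template An [evidence_bundle()] with exactly one
#'   homology hit; the scanned field of that hit is overwritten.
#' @param grid Sorted numeric grid of values to scan.
#' @param thresholds A [confidence_thresholds()].
#' @return The boundary value (numeric).
#' @examples
#' tpl <- evidence_bundle(transcript_evidence = TRUE,
#'   homology_hits = homology_hit("X", e_value = 1e-5,
#'                                percent_identity = 20, aligned_length = 100))
#' scan_threshold_boundary("identity", tpl, 10:60)
#' @export
scan_threshold_boundary <- function(axis = c("e_value", "identity",
                                             "transfer_identity"),
                                    evidence_template, grid,
                                    thresholds = confidence_thresholds()) {
  axis <- match.arg(axis)
  stopifnot(inherits(evidence_template, "evidence_bundle"),
            !is.null(evidence_template$homology_hits),
            nrow(evidence_template$homology_hits) == 1L,
            !is.unsorted(grid))
  classify_at <- function(value) {
    ev <- evidence_template
    field <- switch(axis, e_value = "e_value",
                    identity = "percent_identity",
                    transfer_identity = "whole_sequence_identity")
    ev$homology_hits[[field]][1L] <- value
    classify_confidence(ev, thresholds)$level
  }
  levels <- vapply(grid, classify_at, character(1))
  boundary <- switch(axis,
    e_value = {
      passing <- levels == "similar_to"
      if (!any(passing) || all(passing))
        stop("no classification transition found on the grid")
      max(grid[passing])
    },
    identity = {
      passing <- levels == "similar_to"
      if (!any(passing) || all(passing))
        stop("no classification transition found on the grid")
      min(grid[passing])
    },
    transfer_identity = {
      refused <- levels != "named"
      if (!any(refused) || all(refused))
        stop("no classification transition found on the grid")
      max(grid[refused])
    })
  boundary
}

#' Read an evidence table and classify every gene
#'
#' The TSV has one row per (gene, hit): columns `gene`, per-gene flags
#' `transcript_evidence`, `protein_evidence`, `pseudogene_evidence`,
#' `functional_evidence`, optional `functional_name`, `domains`
#' (comma-separated), and per-hit columns `subject_name`, `subject_species`,
#' `is_vitis`, `is_characterized`, `e_value`, `percent_identity`,
#' `aligned_length`, `whole_sequence_identity` (hit columns may be empty
#' for genes without hits).
#'
#' @param path Path to the evidence TSV.
#' @param thresholds A [confidence_thresholds()].
#' @return Data frame: `gene`, `level`, `payload`, `full_name`,
#'   `qualifiers`.
#' @export
classify_evidence_table <- function(path,
                                    thresholds = confidence_thresholds()) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot("gene" %in% names(tab))
  flag <- function(x) !is.na(x) & (x == TRUE | x == "TRUE" | x == 1 | x == "yes")
  out <- lapply(split(tab, tab$gene), function(rows) {
    first <- rows[1L, ]
    hits <- rows[!is.na(rows$subject_name) & nzchar(rows$subject_name), ,
                 drop = FALSE]
    hit_df <- if (nrow(hits)) do.call(rbind, lapply(seq_len(nrow(hits)),
      function(i) homology_hit(
        hits$subject_name[i], hits$subject_species[i] %||% NA_character_,
        flag(hits$is_vitis[i]), flag(hits$is_characterized[i]),
        hits$e_value[i], hits$percent_identity[i],
        hits$aligned_length[i], hits$whole_sequence_identity[i])))
      else NULL
    fev <- first$functional_evidence
    if (is.na(fev) || !nzchar(fev)) fev <- "none"
    fn <- first$functional_name
    if (!is.null(fn) && (is.na(fn) || !nzchar(fn))) fn <- NULL
    ev <- evidence_bundle(
      transcript_evidence = flag(first$transcript_evidence),
      protein_evidence = flag(first$protein_evidence),
      pseudogene_evidence = flag(first$pseudogene_evidence),
      functional_evidence = fev, functional_name = fn,
      domain_hits = if (!is.null(first$domains) && !is.na(first$domains) &&
                        nzchar(first$domains))
        strsplit(first$domains, ",")[[1]] else character(),
      homology_hits = hit_df)
    lab <- classify_confidence(ev, thresholds)
    data.frame(gene = first$gene, level = lab$level,
               payload = lab$payload %||% NA_character_,
               full_name = tryCatch(render_full_name(lab, base_name = fn),
                                    error = function(e) NA_character_),
               qualifiers = paste(lab$qualifiers, collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$gene), , drop = FALSE]
}

#' Read thresholds from a JSON configuration file
#'
#' @param path JSON file with any of the [confidence_thresholds()] fields;
#'   missing fields take their defaults.
#' @return A `confidence_thresholds` object.
#' @export
read_thresholds <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- confidence_thresholds()
  for (f in names(defaults)) if (!is.null(cfg[[f]])) defaults[[f]] <- cfg[[f]]
  do.call(confidence_thresholds, unclass(defaults))
}
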