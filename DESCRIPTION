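Package: vitinom
Title: Stable Locus Identifiers, Curation Levels and Phylogeny-Based
    Gene Symbols for Grapevine
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for systematic gene nomenclature in Vitis vinifera and
    related Vitis species.  Implements the structured locus-identifier
    grammar (taxon code, chromosome, object type, five-digit numeric code,
    sequence variant, version) together with its full lifecycle semantics:
    identifier assignment with +1 increments, merge, split, relocation of
    genes from the unanchored chromosome 00 bin, version bumps, allele and
    splice-variant allocation, and append-only synonym and event history in
    an event-sourced registry where identifiers are never reused.  Also
    provides a rule-based classifier that assigns a curation confidence
    level (hypothetical, expressed, domain containing, similar to, named,
    putative, probable, uncertain, translated) to a gene from an evidence
    bundle of homology hits, domain hits and expression, protein and
    pseudogene evidence, and a phylogeny-driven symbol-proposal engine that
    collapses poorly supported tree branches, classifies ortholog relations
    between grapevine and a reference species by the species-overlap
    method, and proposes family symbols and locus designators with full
    synonym bookkeeping.  A command-line entry point and reproducible
    worked-scenario fixtures are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
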