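# vitinom

Stable locus identifiers, annotation-confidence levels and
phylogeny-based gene symbols for grapevine (*Vitis vinifera*).

Community genome annotation needs names that survive curation: gene models
get merged, split and moved between chromosomes across assembly releases,
and the literature accumulates conflicting symbols for the same locus.
`vitinom` is a toolkit for curators and annotation-pipeline authors that
implements the grapevine nomenclature system end to end:

* **Locus-identifier grammar and lifecycle.**  Identifiers of the form
  `Vitvi18g12230` — taxon code, chromosome (`00`–`19`, with `00` the
  unanchored bin), object type (`g`, `t`, `p`, `nc`, `tr`, `te`, `rr`,
  `mi`, `ps`, `si`, `sn`), five-digit numeric code (up to 99,999 per
  chromosome, issued in +1 increments), optional `-variant` and
  `.version`.  An event-sourced registry provides assignment, merge,
  split, relocation, version bumps, allele/splice-variant allocation and
  synonym history; identifiers are **never reused**, and replaying the
  event log reproduces the registry exactly.
* **Confidence classification.**  An evidence bundle (expression, protein,
  pseudogene flags; domain and homology hits; functional evidence) maps
  deterministically onto the curation vocabulary *hypothetical /
  expressed / ZZZ domain containing / similar to XXX / putative /
  probable / YYY (named) / uncertain*, with *translated* as an orthogonal
  qualifier.  Similarity requires e-value ≤ 1e-20 or ≥ 30 % identity over
  ≥ 80 contiguous amino acids; direct name transfer from a characterised
  grapevine protein requires > 95 % whole-sequence identity.
* **Phylogeny-driven symbols.**  Gene trees (newick, bootstrap supports on
  internal nodes) are preprocessed by collapsing branches with support
  below 70 %; ortholog relations against a reference species
  (one2one / one2many / many2many / none) are classified by the
  species-overlap criterion; and family symbols — a 2–5-letter root plus a
  1–3-digit locus designator, with letter suffixes for unresolved pairs
  and an inserted `L` for digit-ending roots — are proposed with full
  synonym bookkeeping.

## A worked example

Parse an identifier, walk a gene through a relocation, and name the
ethylene-insensitive-like (EIL) transcription-factor family:

```r
library(vitinom)

parse_locus_id("Vitvi05t00480-tpa2.3")
#> <locus_id> Vitvi05t00480-tpa2.3
# taxon VITVI, chromosome 5, transcript 480, Tempranillo allele a splice
# form 2, model version 3

reg <- registry_new(counters = c(119L, rep(0L, 6), 1538L, rep(0L, 12)))
old <- create_gene(reg, 0)        # next code on the unanchored bin
format_locus_id(old)
#> [1] "Vitvi00g00120"
format_locus_id(relocate_gene(reg, old, 7))
#> [1] "Vitvi07g01539"
# the chromosome-00 identifier is retired, stored as a synonym of the new
# record, and will never be reissued

sc <- build_paper_scenarios()$EIL
for (pr in run_scenario(sc)) print(pr)
#> <symbol_proposal> VIT06s0009g01380 -> EIL3 [R3] synonyms: EIN3
#> <symbol_proposal> VIT11s0016g00640 -> EIL2a [R4]
#> <symbol_proposal> VIT16s0100g00570 -> EIL2b [R4]
#> <symbol_proposal> VIT00s0357g00120 -> EIL4 [R5]
```

Reading the proposals: the grapevine one2one ortholog of the
phenotype-named *Arabidopsis* gene `EIN3` takes the family root plus the
next free designator (`EIL3`, rule R3), keeping `EIN3` as a synonym; the
two genes unresolved against `EIL2` take its designator with letters
(`EIL2a`/`EIL2b`, rule R4); the gene equidistant from several members gets
the next independent number (`EIL4`, rule R5).  For display in running
text, `display_symbol(pr, "Vvi")` renders `VviEIL3` — the prefix is never
stored.

A command-line launcher with the same operations (`parse`, `create`,
`merge`, `relocate`, `classify`, `collapse`, `orthology`, `propose`, ...)
is installed at `system.file("cli", "vitinom", package = "vitinom")`.

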