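---
title: "Grapevine gene nomenclature: identifiers, confidence levels and phylogeny-based symbols"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grapevine gene nomenclature: identifiers, confidence levels and phylogeny-based symbols}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitinom)
```

# The problem

Grapevine (*Vitis vinifera*) gene annotation is a community effort: gene
models are corrected over successive assembly releases, unanchored scaffolds
move onto chromosomes, and the same gene accumulates different names across
publications.  `vitinom` implements the three pieces of machinery a stable
community nomenclature needs:

1. a **locus-identifier grammar** with full lifecycle semantics — assignment,
   merge, split, relocation, versioning, variants, synonym history — in
   which an identifier, once issued, is never reused;
2. a **confidence classifier** that turns the evidence available for a gene
   into a controlled curation-level vocabulary for its full name;
3. a **symbol-proposal engine** that names gene-family members from a
   support-labelled gene tree and the symbols already in use in grapevine
   and in a reference species (normally *Arabidopsis thaliana*).

# The locus identifier

An identifier concatenates six elements:

| element       | form                    | example        |
|---------------|-------------------------|----------------|
| taxon code    | `VIT` + species letters | `Vitvi`        |
| chromosome    | two digits, `00`–`19`   | `18`           |
| object type   | one of 11 tokens        | `g`            |
| numeric code  | five digits, `00001`–`99999` | `12230`   |
| variant       | `-` + letters + digits (optional) | `-tpa2` |
| version       | `.` + integer (optional) | `.3`          |

`Vitvi18g12230` is gene 12230 on chromosome 18; `Vitvi05t00480-tpa2.3` is
version 3 of splice form 2 of allele *a* (cultivar Tempranillo, `tp`) of
transcript 480 on chromosome 5.  Chromosome `00` is the bin of scaffolds not
yet anchored on chromosomes 1–19.  The object-type tokens are `g`, `t`, `p`,
`nc`, `tr`, `te`, `rr`, `mi`, `ps`, `si`, `sn`; splice-variant digits are
meaningful only on transcripts and proteins (`t`, `p`), which the validator
enforces.  An omitted version always means the most recent gene model.

Parsing is case-insensitive on the taxon code and canonical output is
title-case (`Vitvi…`), matching how the identifier is printed in the
nomenclature's own tables; an `uppercase` style is available.  Each
malformed element raises a distinct error class so that pipelines can
report precisely what is wrong.

Two points in the grammar were genuinely open and are resolved here as
follows:

* **Letter-only allele variants on any object type.**  Only *splice* digits
  are restricted to `t`/`p`; a bare allele letter (`-a`) is admitted on any
  object type, including `g`.
* **Non-vinifera taxon codes** follow the `VIT` + 2–3 letter shape
  (`VITVBR` for *V. berlandieri*); codes outside that shape are rejected.

# The registry: event-sourced lifecycle

`registry_new()` creates a registry keyed by the bare identifier, with one
numeric-code counter per chromosome **shared across all object types** (the
five-digit space is per chromosome, up to 99,999).  Every mutation —
`create_gene()`, `merge_genes()`, `split_gene()`, `relocate_gene()`,
`bump_version()`, `allocate_variant()`, `add_synonym()`, `rename_gene()` —
is validated, converted into an event, and applied by a single
event-application routine.  The append-only event log is therefore the
source of truth: `replay_events()` rebuilds the exact state from an empty
registry, which the test suite verifies bit-for-bit, and history is never
deleted — a retired identifier keeps its full history and resolves through
successor links to its current active record.

Lifecycle semantics, in brief:

* **Assignment** issues counter + 1 on the chromosome; increments are
  always exactly +1, leaving no gaps, so codes stop reflecting physical
  order after edits — by design, identifiers are not positional.
* **Merge** keeps one identifier (the survivor is caller-specified; the
  paper-facing convention of preferring the lower code is left to the
  caller or CLI), retires the other with a successor link, stores it as a
  `locus_id` synonym of the survivor, and bumps the survivor's version.
  Cross-chromosome merges are refused; relocate first.  Discarded codes
  are never reissued.
* **Split** keeps the original identifier at version + 1 and allocates
  fresh identifiers only for the additional models.
* **Relocation** (typically chromosome 00 → a real chromosome) issues the
  next code in series on the target chromosome, retires the old record and
  stores the old identifier as a synonym.  The new record restarts at
  version 1; the old record's history stays attached to the retired
  identifier.  Relocation to the same chromosome is an error, because a
  scaffold-orientation change alone changes nothing.
* **Versions** increment by exactly 1 on any structural edit.
* **Variants** compose cultivar prefix + allele letters + splice index
  (`tp` + `a` + `2` → `tpa2`) and must be unique per locus.
* **Synonyms** are unique per gene on (name, kind), case-insensitively,
  with the controlled note vocabulary `obsolete` / `incorrect` /
  `ambiguous` plus free text and an optional bibliographic reference.  The
  same ambiguous name may legitimately sit on several genes, each carrying
  the note.

A registry persists as a directory: `events.jsonl` (authoritative),
`meta.json` (taxon and seed counters), and the human-facing projections
`registry.tsv` and `synonyms.tsv`.  Reading replays the event log.

# Confidence classification

Every locus starts as *hypothetical protein*.  Evidence moves it up a fixed
precedence ladder, from weakest to strongest:

`hypothetical` < `expressed` < `domain_containing` < `similar_to`
< `putative` < `probable` < `named`, with `uncertain` (pseudogene evidence)
overriding everything and `translated` stacking as an orthogonal qualifier —
protein-level evidence proves a protein exists, not what it does.

The similarity criterion passes when the best hit (smallest e-value; ties
broken by identity, alignment length, then subject name) satisfies

* e-value ≤ **1e-20** (inclusive), **or**
* ≥ **30 %** identity over ≥ **80** contiguous amino acids (both inclusive).

Direct transfer of a characterised grapevine protein's name (`named`)
requires strictly **> 95 %** identity over the whole sequence, or explicit
experimental characterisation in *Vitis*.  `putative` requires in-silico
functional evidence and `probable` at least some experimental evidence;
neither is inferred from homology alone.  Two further choices the source
material leaves implicit are made explicit here: `similar_to` and
`domain_containing` both require transcript evidence first (similarity is
described as the step *after* expression is proven), and the precedence
order above is a reconstruction of the published decision tree from the
level definitions, since the tree's exact branch topology is only shown
graphically.

`scan_threshold_boundary()` recovers the active thresholds behaviourally by
sweeping one axis of a fixed evidence template; the tests use it to confirm
the boundaries sit exactly at the documented values, including for
non-default threshold configurations (a round-trip property).

# Phylogeny-based symbols

**Collapse.** `collapse_weak_branches()` contracts every internal branch
whose bootstrap support is strictly below 70 % (the default), because
weaker values imply a potentially misleading hierarchy; support exactly 70
is retained.  Branches without a support value (e.g. the root) are never
touched, leaves are never removed, and the operation is idempotent.  The
implementation rebuilds the tree from contracted child lists; tests check
it against an independent clade-set oracle and against
`phangorn::pruneTree`.

**Orthology.**  Without a species tree, `infer_orthology()` uses the
species-overlap criterion: two leaves diverged by a duplication when, at
their last common ancestor, the two child subtrees containing them share a
species.  Applying the test to the *pair of child subtrees* generalises it
to the polytomies that collapsing produces: a polytomy of two grapevine
genes and one *Arabidopsis* gene relates both grapevine genes to the
reference gene (one2many) without making either one2one.  Relation classes
follow the usual vocabulary: `one2one`, `one2many`, `many2many`, `none`.
This is an approximation to full tree reconciliation against a species
tree, which is out of scope; on the two-species trees used for naming it
is exhaustively tested against a brute-force oracle on all rooted binary
shapes with up to seven leaves.

**Symbols.**  A symbol is a 2–5-letter family root plus a 1–3-digit locus
designator, optionally followed by a lowercase differentiation letter.
Species prefixes are never stored in the symbol — `vv`/`Vv` collide with
*Vibrio vulnificus*, and `Vvi` is a display prefix applied only when
rendering (`display_symbol()`).  `propose_symbol()` applies the rules in
order:

* **R1** — a curator-supplied grapevine mutant-phenotype name wins; the
  family-format alternative is registered as a synonym.  The name is kept
  even when it violates the length convention; the violation is attached
  to the proposal rather than raised.
* **R2** — a one2one ortholog of a reference gene whose symbol fits the
  family format adopts that symbol (`HT1` → `STP1`).  If its designator is
  already occupied in grapevine the engine falls through to R5 and records
  the collision in the rationale.
* **R3** — a one2one ortholog of an off-root reference gene (`EIN3`,
  `SLIM1`) takes root + next available designator; the off-root name
  becomes a synonym (`EIL3`, synonym `EIN3`).
* **R4** — several grapevine genes unresolved against a single reference
  gene take that gene's designator plus letters `a`, `b`, … (`EIL2a`,
  `EIL2b`; `CCD1a`, `CCD1b`).
* **R5** — otherwise, root + next available designator, counted over
  *both* species (`SUC28` above grapevine `SUC27` and *Arabidopsis*
  `SUC9`).
* **R6** — a root ending in a digit inserts `L` (for *-like*) before the
  designator (`ERD6L2`); an override exists for families whose community
  chose otherwise.
* **R7** — with no reference-species member at all, genes are numbered in
  tree traversal order, never by chromosome position (the stilbene
  synthase case).

`next_available_designator()` is one more than the highest designator used
in the species in scope; off-root symbols occupy no designator (`EIN3`
does not block `EIL3`).  `apply_family_naming()` walks the focal leaves in
**the order the tips appear in the input tree** and proposes a symbol for
every leaf that has no symbol, a symbol outside the family format, or a
letterless symbol inside a group that now needs differentiation letters;
conforming symbols are kept untouched.  Since the nomenclature explicitly
attaches no meaning to which equidistant gene receives which number, input
tip order is used as the deterministic tie-break: identical inputs always
give identical output, and the order is visible to the curator in the tree
itself.  Displaced prior names — and any historical names passed through
`options$prior_names` with their notes — are returned as
`synonyms_to_register`.

# The worked scenarios

`build_paper_scenarios()` regenerates six reference scenarios entirely in
code.  The trees are *synthetic encodings of the textual statements* of the
published worked examples — the figures' full topologies are not
machine-readable — so each tree contains exactly the relations the text
asserts: the `EIL` scenario (a one2one ortholog of `EIN3` → `EIL3`; two
genes equidistant from `EIL2` → `EIL2a`/`EIL2b`; a gene equidistant from
several members → `EIL4`), `SUC` (`SUT2` with no ortholog → `SUC28`),
`STP` (`HT1`/`HT3`/`HT24` → `STP1`/`STP13`/`STP14` with `HT` synonyms),
`ERD6` (L-insertion, numbering above the reference members), `CCD`
(`CCD1a`/`CCD1b` with the obsolete `NCED1` synonym; the `CCD8b` gene kept
although no *Arabidopsis* gene belongs to its group) and `STS` (numbering
by traversal in a family absent from *Arabidopsis*).  The *Arabidopsis*
gene identifiers in these trees are illustrative AGI-style codes, not
curated mappings.

`random_family()` complements them for property testing: it assembles
ortholog cherries, surplus single-species genes, and focal-side
duplications at a configurable rate, with supports drawn uniformly on
50–100 so that a realistic fraction of branches falls below the collapse
threshold.  It is a pure function of its seed via a self-contained
generator, so fixture generation never disturbs the session RNG.
`random_registry()` builds registries exclusively through `create_gene()`,
so lifecycle invariants hold by construction.

# What the tests do and do not show

The scenario suite proves the rule engine reproduces the published worked
examples; the property suites prove the structural invariants (no
identifier reuse over 500 random lifecycle sequences, event-log replay
equality, collapse idempotence and leaf preservation on 200 random trees,
orthology–oracle agreement on all small two-species trees, classifier
monotonicity under evidence improvement).  Problem sizes — 12–50 lifecycle
operations per random run, trees of ≤ 10 leaves, exhaustive enumeration to
7 leaves — were chosen as the smallest sizes that exercise every rule
interaction; the operations are size-independent, but the suite does not
exercise genome-scale registries (tens of thousands of records), real
bootstrap trees with hundreds of leaves, or the ambiguities of real
evidence tables (conflicting hits from un-curated databases).  The
synthetic scenario trees encode the *stated* relations only; on a real
family, tree quality upstream (alignment, model, rooting) dominates the
outcome and is explicitly out of scope here — trees are inputs.

# Numerical and interface choices

* Threshold tie conventions follow the literal wording: e-value cut-off
  inclusive, identity/length inclusive, name transfer strictly exclusive;
  the collapse rule "below 70" is strict, so 70 survives.
* Best-hit ties break deterministically (identity, then length, then
  subject name) so classification is reproducible.
* Identifier ordering is total (chromosome, code, object type, then taxon,
  variant, version); equal only on all six elements.
* The CLI (`run_cli()`, launcher in `inst/cli/vitinom`) exposes parse /
  validate / convert-legacy / create / merge / split / relocate / bump /
  synonym / history / classify / collapse / orthology / propose /
  fixtures, with exit code 0 on success, 2 on rule violations and 3 on
  I/O errors.  Run-time configuration lives in function defaults and CLI
  flags; thresholds can be loaded from a JSON file.
* `stamp_gff3()` rewrites `ID=`/`Name=`/`Parent=` attributes of gene,
  mRNA and CDS features from an old → new mapping and passes every other
  byte through unchanged, so annotation files can be re-stamped without
  disturbing their structure.

# Known limitations

* Orthology is species-overlap on the input gene tree, not reconciliation
  against a species tree; with more than two species the focal/reference
  pairing is still computed, but outgroup structure is ignored.
* The registry is single-writer; there is no locking or remote backend.
* GO handling records a free-text evidence code only when functional
  evidence is at least experimental; no ontology validation is attempted.
* The legacy 12X-v1 grammar is parsed for synonym storage, but no mapping
  table between legacy and new identifiers is provided — that mapping is
  data, not grammar.
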