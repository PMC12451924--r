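---
title: "Genomic data normalization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic data normalization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genonorm)
```

## The problem

The same genetic finding can be written many ways: a variant as HGVS on a
transcript, HGVS on either build's chromosome, SPDI, or a VCF row — and an
indel in a repeat at any of several equivalent placements; an HLA result as
a fully resolved allele, a G/P group, a MAC code compressing an OR-list, or
a serologic antigen; a condition as a SNOMED, ICD-10-CM, Disease Ontology
or MedGen code. Exact-match search across records fails unless every
synonymous spelling is mapped to one designated canonical form. genonorm
implements that normalization for all three data types and a small
normalize-at-ingestion store that demonstrates the payoff: every spelling
of a variant or HLA allele finds the same patient.

## Variant canonical form

The canonical variant form is the **chromosome-level fully justified SPDI
expression**. SPDI coordinates are 0-based interbase throughout the
internals; the 1-based HGVS convention exists only at the parse/format
boundary (a substitution at HGVS position *p* is SPDI position *p* − 1).

Canonicalization proceeds in three steps:

1. **Trim.** The longest common prefix, then suffix, of the
   deleted/inserted allele pair is removed, advancing the position by the
   prefix length. A pair that cancels completely becomes a distinguished
   empty-change marker rather than an error; callers decide whether to drop
   or report it.
2. **Extent.** For a pure insertion or deletion, the variant is rolled
   base-by-base to its 5′-most and 3′-most placements; the *justification
   extent* `[left_most, right_most)` is the maximal interval over which
   every placement denotes the same mutated sequence. A substitution's
   extent is its own single base; a delins that trimming cannot reduce to a
   pure indel keeps its own span (no repeat unit to roll).
3. **Expand.** The canonical form places the variant at the extent's left
   edge, with the deleted allele equal to the full reference span of the
   extent and the inserted allele equal to that span with the change
   applied. For the published seven-T example this turns the deletion
   `NC_000007.14:117548628:T:` (left-justified) or
   `NC_000007.14:117548634:T:` (right-justified) into
   `NC_000007.14:117548628:TTTTTTT:TTTTTT`.

The operation is idempotent and placement-independent; the test suite
checks this against a brute-force oracle that enumerates every placement by
applying each candidate edit to the fixture sequence and comparing mutated
strings. Insertions expand over their extent with the same rule as
deletions. The reference treatment of insertion expansion is not published
in detail, so this choice is implementation-defined and validated only by
the internal apply-and-compare oracle.

Three deliberate policies:

* **Trust-stated-ref.** A substitution converted without sequence coverage
  trusts its stated reference allele (substitutions need no context);
  when the catalog does cover the span, the stated allele is checked and a
  disagreement is a hard error. Indel justification always requires
  coverage. `validate = "always"` upgrades missing coverage to an error.
* **N bases.** `N` is storable, but any roll step that would compare
  against an `N` raises an ambiguous-context error rather than treating it
  as a match or a mismatch.
* **HGVS emission.** Indels are emitted at the 3′-most placement per HGVS
  convention; an insertion whose allele equals the immediately 5′-adjacent
  reference span is spelled `dup`. Note the interbase arithmetic: the
  right-justified single-T deletion of the seven-T run sits at SPDI
  position 117548634, which is the base at 1-based position 117548635, so
  its HGVS spelling is `g.117548635del` — the same +1 mapping that links
  SPDI 11200235 to `g.11200236G>A`.

## Sequence context: a sparse catalog

Whole chromosomes are never stored. A `seq_catalog` holds short registered
segments (the seven-T run and a few flanking bases suffice for the worked
examples), and any slice touching an unregistered position raises a
coverage error carrying the gap — there is no silent padding. This is what
makes real-accession examples testable at desk scale: the fixture registers
16 bases of `NC_000007.14` and reproduces the published coordinates
exactly. Rolling that reaches a segment boundary fails loudly for the same
reason; fixture segments therefore carry repeat-breaking flanks.

## Transcript projection and liftover

Transcript-to-chromosome alignments are ordered, length-preserving exon
blocks (`g_end − g_start == t_end − t_start`) plus a strand and the
transcript offset of c.1. Real alignment databases also encode
mismatch/indel blocks; those are out of this data model, a recorded
limitation. Consequences:

* Exonic c. positions map linearly within a block; on the − strand the
  endpoints swap into ascending genomic order and alleles are
  reverse-complemented.
* Intronic offsets (`c.1311_1312+1`) resolve through the flanking exon
  edge, moving in strand direction. Projecting back, an intronic genomic
  position is expressed relative to the nearest exon edge; at the exact
  intron midpoint the 5′ edge wins.
* Edits spanning an exon junction are rejected with a distinct error
  rather than approximated — junction arithmetic under length-preserving
  blocks would silently misplace the edit. An exon-edge plus its adjacent
  intron is contiguous in genomic space and remains supported.

Build liftover goes **through a shared transcript**: a chromosome-level
variant is projected onto an overlapping transcript (preferring MANE, then
largest overlap, then lexicographically smallest accession — a
deterministic rule), and re-projected through that transcript's alignment
on the other build. The same transcript accession and version must be
aligned on both builds; when the builds carry different versions the other
build's fields fail with a recorded reason rather than guessing across
versions. Intergenic variants therefore cannot lift — the same-build
fields still populate and the other build reports "no transcript
alignment".

The four-field bundle `{b37SPDI, b38SPDI, b37HGVS, b38HGVS}` records a
status per field; partial failure never silently nulls a field. Toy builds
(`fixture37`/`fixture38`) slot into the same contract through their build
labels, so the whole pipeline is exercised without real-genome coordinates.

## HLA reduction

The canonical HLA form is the two-field ARD-level **lgx** reduction,
computed over a pluggable allele-group database (allele universe, G and P
group tables, serology table, MAC table). The database file is a fixture
seeded from published expansion lists, so the tests validate expansion,
reduction and formatting logic — not immunogenetic content.

Reduction semantics, per allele: `G`/`P` name the group containing every
known expansion of the allele, else the allele itself; `lgx` is the
two-field truncation of the G-group designation (of the allele itself when
ungrouped — including alleles absent from the database, which lets search
degrade gracefully); `W` and `exon` are the four- and three-field
expansions, numerically sorted; `U2` is the two-field form when that form
is unambiguous, else lgx; `S` maps through the serology table in
antigen-table order. OR-lists and MAC expansions preserve input order and
deduplicate keeping the first occurrence, matching the published output
ordering. Two documented divergences from the upstream behaviour the
published failure table notes: the `lg` marker `g` is appended to *every*
component (the published output shows `DRB1*13:36g` even though 13:36 has
no G group), and serology tokens are accepted with or without the `HLA-`
prefix, which is normalized away.

Search combines a case-insensitive substring test on the raw stored string
with lgx-component intersection; a query that fails normalization (an
epitope such as `Bw4`, a GL String) degrades to substring-only matching and
never raises.

## Terminology translation

Concept maps are functions: one source code maps to zero or one target
code per target system, enforced at load. Translation is exact-match only
— the deliberate proof-of-concept boundary; broader/narrower and pre/post-
coordination matching are out of scope and recorded as limitations. Target
systems are visited in alphabetical URI order (the reference output's
DO-before-MedGen order falls out of this, and it makes multi-target output
deterministic). Target codes are stored and returned verbatim, including
the published `DOID : 3908` internal spacing, with an optional
space-stripping toggle for interoperability. Query expansion appends the
translated code and always keeps the submitted one, so translation can
only widen a result set.

## The store

Ingestion normalizes every input and stores the raw string next to its
normalization with a per-item status; failures keep their condition class
as a taxonomy label. The matching key is the canonical SPDI, compared
across both builds' fields (the b38 field is preferred, with the b37 field
as fallback when only one side normalized). Code matching for conditions is
exact on system and code. The store is environment-backed and in-memory
with a JSON snapshot — a deliberate desk-scale choice, not a database.

## What the fixtures emulate — and what they do not

`build_fixture_suite(seed)` is a pure function of its seed: sparse segments
at published coordinates, two 700/750-base toy chromosomes differing by a
50-base offset, three toy transcripts (both strands, one non-MANE
competitor), the HLA database described above, five concept maps and two
subjects. `random_equivalence_cases(seed, n)` plants tandem repeats (unit
1–3 bases, 3–6 copies, repeat-breaking flanks) and emits each change as
SPDI at the leftmost, rightmost and a middle placement, an HGVS spelling
and a VCF anchor-base row, with placements enumerated by brute force.

These fixtures emulate the *structure* of the real problem — repeat
contexts, build offsets, strand flips, MAC compression, cross-terminology
coding — at toy scale. They do not emulate alignment indels, UTR and
noncoding coordinates, structural variants, real IMGT/HLA release content,
or the long-tail messiness of real HGVS in the wild. A green test suite
therefore certifies the normalization algebra, not concordance with any
particular external database release.

## Problem sizes and numerical choices

The default test run uses 100 seeded equivalence classes for the
congruence property, 200-case grammar round-trip loops, 25-variant
projection oracles per strand, and the fixed published examples; the whole
suite runs in well under a minute on one core. Positions are stored as R
doubles (exact for genome-scale integers), formatted without scientific
notation; seeds are small integers and every random fixture is
reproducible from them.

## Known limitations

* Length-preserving alignment blocks only; no UTR (`c.-N`/`c.*N`) grammar;
  junction-spanning edits rejected.
* Liftover only through a transcript shared by both builds.
* HGVS subset: `sub`, `del`, `ins`, `delins`, `dup` on `NM_`/`NC_`
  accessions with versions; no protein, RNA, repeat or multi-allele
  syntax; `LRG_`/`NG_` references refused by design.
* No GL Strings, epitopes, or LOINC-coded HLA observations.
* Exact-match terminology only; no hierarchy traversal.
* The external-service fallback hook for failed normalizations is a
  deliberate no-op.
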