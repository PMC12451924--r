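# genonorm

Genomic data normalization for clinical genomics search, in R.

Clinical genomic data arrives in many synonymous spellings: a variant as
transcript HGVS (`NM_001127510.3:c.145A>T`), chromosome HGVS on either
build, SPDI, or a VCF row — and an indel in a repeat at any of several
equivalent placements; an HLA result as a resolved allele, a G/P group, a
MAC code, or a serologic antigen; a condition coded in SNOMED, ICD-10-CM,
Disease Ontology or MedGen. Exact-match search breaks unless every spelling
is normalized to one canonical form at ingestion. genonorm implements that
normalization and a small query layer that demonstrates it end to end.

## Canonical forms

* **Variants** normalize to *chromosome-level fully justified SPDI* on
  both builds. SPDI positions are 0-based interbase. After trimming the
  shared allele sequence, an indel is rolled to its 5′-most and 3′-most
  placements; the canonical form spans the whole justification extent:

  ```
  left justified   NC_000007.14:117548628:T:
  right justified  NC_000007.14:117548634:T:
  fully justified  NC_000007.14:117548628:TTTTTTT:TTTTTT
  ```

  HGVS output uses the 3′-most placement (`dup` when the insertion
  restates the adjacent reference span). Transcript variants project to
  both builds' chromosomes through exon alignments; chromosome variants
  lift between builds through a shared transcript (MANE preferred).

* **HLA alleles** normalize to the two-field ARD-level `lgx` reduction,
  with `G`, `P`, `lg`, `W`, `exon`, `U2` and serology (`S`) forms exposed
  as utilities; MAC codes and OR-lists expand before reduction.

* **Condition/medication codes** translate through ConceptMaps
  (exact-match, one target code per source code per target system); query
  expansion always retains the submitted code.

## Supported variant grammar

| Syntax | Accessions | Positions | Edits |
|---|---|---|---|
| HGVS `g.` | `NC_` (versioned) | 1-based | `sub`, `del`, `ins`, `delins`, `dup` |
| HGVS `c.` | `NM_` (versioned) | 1-based CDS, intronic `+k`/`-k` | same subset |
| SPDI | any versioned id | 0-based interbase | four fields; numeric third field = length-only deletion |
| VCF row | via contig map | 1-based, anchor-base | SNV/indel alleles, comma-split |

`LRG_`/`NG_` references, protein/RNA/repeat syntax, UTR coordinates and
version-less accessions are rejected with distinct error classes; GL
Strings, epitopes and unknown MAC codes likewise on the HLA side.

## Worked example

```r
library(genonorm)
suite <- build_fixture_suite(1)   # deterministic fixtures

normalize_variant_bundle("NM_FIX1.1:c.12G>A", suite$alignments, suite$catalog)
#> <normalized_bundle> NM_FIX1.1:c.12G>A
#>   b37SPDI: NC_FX0001.37:121:G:A
#>   b38SPDI: NC_FX0001.38:171:G:A
#>   b37HGVS: NC_FX0001.37:g.122G>A
#>   b38HGVS: NC_FX0001.38:g.172G>A
```

The four fields are the canonical SPDI and right-rolled HGVS on each
build; every other spelling of this variant (either build's HGVS or SPDI,
or the VCF row) produces the identical bundle, which is what makes stored
records searchable by any spelling.

```r
fully_justify(parse_spdi("NC_000007.14:117548634:T:"), suite$catalog)
#> <spdi> NC_000007.14:117548628:TTTTTTT:TTTTTT

normalize_hla("DRB1*13:AKBAR", suite$hla_db)$lgx
#> [1] "DRB1*13:02/DRB1*13:36/DRB1*13:67/DRB1*13:96/DRB1*13:109"

translate("http://snomed.info/sct", "126949007", suite$concept_maps)[[1]]
#> $outcome
#> [1] "match found"
#> $system
#> [1] "https://disease-ontology.org/"
#> $code
#> [1] "DOID : 12689"
#> $display
#> [1] "Acoustic Neuroma"
```

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/genonorm.R normalize-variant --variant "NM_FIX1.1:c.12G>A"
Rscript inst/cli/genonorm.R normalize-hla --allele "DRB1*13:AKBAR"
Rscript inst/cli/genonorm.R translate-terminology \
    --system "http://snomed.info/sct" --code 126949007
Rscript inst/cli/genonorm.R build-fixtures --out fixtures --seed 1
```

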