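Package: genonorm
Title: Genomic Data Normalization for Clinical Genomics Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Normalizes the genetic data types that dominate clinical
    genomics queries so that synonymous representations match exactly.
    Variants written in HGVS (transcript c. or chromosome g.) or SPDI are
    trimmed, rolled and fully justified into canonical chromosome-level
    SPDI on both GRCh37 and GRCh38 via transcript exon-alignment
    projection; HLA alleles (including MAC codes and OR-lists) are reduced
    to antigen-recognition-domain normal forms (G, P, lg, lgx, W, exon,
    U2, serology); condition and medication codes are translated through
    ConceptMaps. A normalize-at-ingestion store demonstrates canonical-form
    search: every spelling of a variant or HLA allele finds the same
    patient. Sequence context comes from a sparse reference-segment
    catalog; deterministic fixture builders generate all test inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
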