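# Independent oracles, deliberately written as plain string surgery with no
# reuse of package normalization code paths.

# Apply an edit to a sequence string whose first base is at interbase
# `origin`; returns the mutated string (NULL when the deletion does not
# match the reference).
oracle_apply <- function(seqs, origin, pos, deleted, inserted) {
  i <- pos - origin
  if (i < 0 || i + nchar(deleted) > nchar(seqs)) return(NULL)
  if (substr(seqs, i + 1, i + nchar(deleted)) != deleted) return(NULL)
  paste0(substr(seqs, 1, i), inserted,
         substr(seqs, i + nchar(deleted) + 1, nchar(seqs)))
}

# Brute-force enumeration of every placement of a deletion (fixed length)
# or insertion (any rotation of the allele) that produces the same mutated
# sequence. Returns 0-based positions relative to `origin`.
oracle_del_placements <- function(seqs, origin, pos, deleted) {
  target <- oracle_apply(seqs, origin, pos, deleted, "")
  L <- nchar(deleted)
  hits <- numeric(0)
  for (q in 0:(nchar(seqs) - L)) {
    d <- substr(seqs, q + 1, q + L)
    if (identical(oracle_apply(seqs, 0, q, d, ""), target))
      hits <- c(hits, q + origin)
  }
  hits
}

oracle_ins_placements <- function(seqs, origin, pos, inserted) {
  target <- oracle_apply(seqs, origin, pos, "", inserted)
  u <- nchar(inserted)
  rots <- unique(vapply(seq_len(u), function(k)
    paste0(substr(inserted, k, u), substr(inserted, 1, k - 1)), ""))
  hits <- numeric(0)
  for (q in 0:nchar(seqs)) for (a in rots)
    if (identical(oracle_apply(seqs, 0, q, "", a), target))
      hits <- c(hits, q + origin)
  sort(unique(hits))
}

# Reverse complement without Biostrings.
oracle_revcomp <- function(x) {
  if (!nzchar(x)) return(x)
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# One shared fixture suite for the whole test session.
suite <- build_fixture_suite(1)

# Convenience: single-segment catalog at interbase origin.
mini_catalog <- function(accession, origin, bases, build = "fixture") {
  register_segment(seq_catalog(), accession, origin, bases, build = build)
}
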