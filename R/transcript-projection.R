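# Transcript-to-genome projection over exon block alignments, and the
# four-field normalization bundle. Liftover between builds goes through a
# transcript aligned to both: chromosome-level inputs are projected onto a
# transcript (preferring MANE), then re-projected onto the other build's
# chromosome. Blocks are length-preserving (no alignment indels); variants
# spanning an exon junction are rejected rather than approximated.

#' Transcript exon alignment
#'
#' Block map between one transcript and one build's chromosome. All
#' coordinates are 0-based half-open; each block satisfies
#' `g_end - g_start == t_end - t_start`. Blocks are strictly ordered and
#' contiguous in transcript coordinates, ascending in genomic coordinates on
#' the `+` strand and descending on `-`.
#'
#' @param transcript_accession `NM_`-style accession.
#' @param chromosome_accession chromosome accession of the build.
#' @param build build label (resolved to a bundle slot via its 37/38 tag).
#' @param strand `"+"` or `"-"`.
#' @param blocks data frame (or matrix) with columns
#'   `g_start, g_end, t_start, t_end`.
#' @param cds_start 0-based transcript offset of coding base c.1.
#' @param mane preference flag for transcript selection.
#' @return An object of class `transcript_alignment`.
#' @export
transcript_alignment <- function(transcript_accession, chromosome_accession,
                                 build, strand, blocks, cds_start,
                                 mane = FALSE) {
  blocks <- as.data.frame(blocks)
  stopifnot(all(c("g_start", "g_end", "t_start", "t_end") %in% names(blocks)))
  strand <- match.arg(strand, c("+", "-"))
  if (any(blocks$g_end - blocks$g_start != blocks$t_end - blocks$t_start))
    gn_validation_error("alignment blocks must be length-preserving")
  o <- order(blocks$t_start)
  blocks <- blocks[o, , drop = FALSE]
  if (any(diff(blocks$t_start) <= 0) ||
      any(blocks$t_start[-1] < blocks$t_end[-nrow(blocks)]))
    gn_validation_error("blocks must be non-overlapping and ordered in transcript coordinates")
  gs <- blocks$g_start
  if (nrow(blocks) > 1) {
    if (strand == "+" && any(diff(gs) <= 0))
      gn_validation_error("+ strand blocks must ascend in genomic coordinates")
    if (strand == "-" && any(diff(gs) >= 0))
      gn_validation_error("- strand blocks must descend in genomic coordinates")
  }
  t_len <- max(blocks$t_end)
  if (cds_start < 0 || cds_start >= t_len)
    gn_validation_error("cds_start must lie within the transcript extent")
  structure(list(transcript_accession = transcript_accession,
                 chromosome_accession = chromosome_accession,
                 build = build, strand = strand, blocks = blocks,
                 cds_start = as.numeric(cds_start), mane = isTRUE(mane),
                 t_length = t_len),
            class = "transcript_alignment")
}

#' @export
print.transcript_alignment <- function(x, ...) {
  cat(sprintf("<alignment> %s ~ %s [%s, %s strand, %d block(s), cds_start %d%s]\n",
              x$transcript_accession, x$chromosome_accession, x$build,
              x$strand, nrow(x$blocks), x$cds_start,
              if (x$mane) ", MANE" else ""))
  invisible(x)
}

# 0-based transcript offset -> 0-based genomic index
.t_to_g <- function(aln, t) {
  b <- aln$blocks
  i <- which(b$t_start <= t & t < b$t_end)
  if (!length(i)) return(NA_real_)
  if (aln$strand == "+") b$g_start[i] + (t - b$t_start[i])
  else b$g_end[i] - 1 - (t - b$t_start[i])
}

# 0-based genomic index -> 0-based transcript offset (NA when intronic)
.g_to_t <- function(aln, g) {
  b <- aln$blocks
  i <- which(b$g_start <= g & g < b$g_end)
  if (!length(i)) return(NA_real_)
  if (aln$strand == "+") b$t_start[i] + (g - b$g_start[i])
  else b$t_start[i] + (b$g_end[i] - 1 - g)
}

.g_extent <- function(aln) c(min(aln$blocks$g_start), max(aln$blocks$g_end))

#' Resolve a CDS position on a transcript alignment
#'
#' Exonic positions (offset 0) resolve to a transcript offset
#' (`cds_start + base - 1`); intronic positions resolve through the flanking
#' exon edge to a genomic index.
#'
#' @param pos a [cds_position()].
#' @param aln a [transcript_alignment()].
#' @return For exonic positions, `list(kind = "exonic", t_offset, genomic)`;
#'   for intronic, `list(kind = "intronic", anchor_t, genomic)`.
#' @export
cds_to_transcript <- function(pos, aln) {
  stopifnot(inherits(pos, "cds_position"), inherits(aln, "transcript_alignment"))
  t <- aln$cds_start + pos$base - 1
  if (t < 0 || t >= aln$t_length)
    gn_out_of_transcript(sprintf(
      "c.%s is beyond the transcript extent of %s",
      format_cds_position(pos), aln$transcript_accession))
  G <- .t_to_g(aln, t)
  if (pos$offset == 0)
    return(list(kind = "exonic", t_offset = t, genomic = G))
  g <- if (aln$strand == "+") G + pos$offset else G - pos$offset
  ext <- .g_extent(aln)
  if (g < ext[1] || g >= ext[2])
    gn_projection_gap(sprintf(
      "intronic offset of c.%s falls outside the aligned region",
      format_cds_position(pos)))
  if (!is.na(.g_to_t(aln, g)))
    gn_validation_error(sprintf(
      "c.%s does not denote an intronic position on %s",
      format_cds_position(pos), aln$transcript_accession))
  list(kind = "intronic", anchor_t = t, genomic = g)
}

# 0-based genomic index of any CDS position
.cds_to_gindex <- function(pos, aln) cds_to_transcript(pos, aln)$genomic

# 0-based genomic index -> cds_position, intronic positions expressed with
# nearest-exon offsets (ties go to the 5' exon edge)
.gindex_to_cds <- function(g, aln) {
  t <- .g_to_t(aln, g)
  if (!is.na(t)) {
    base <- t - aln$cds_start + 1
    if (base < 1)
      gn_projection_gap("position 5' of the CDS is out of the supported grammar")
    return(cds_position(base, 0))
  }
  ext <- .g_extent(aln)
  if (g < ext[1] || g >= ext[2])
    gn_projection_gap(sprintf(
      "genomic index %s is outside the aligned transcript region",
      format(g, scientific = FALSE)))
  b <- aln$blocks
  gb <- b[order(b$g_start), , drop = FALSE]
  left  <- gb[max(which(gb$g_end <= g)), ]
  right <- gb[min(which(gb$g_start > g)), ]
  if (aln$strand == "+") {
    t_up <- .g_to_t(aln, left$g_end - 1);  d_up <- g - (left$g_end - 1)
    t_dn <- .g_to_t(aln, right$g_start);   d_dn <- right$g_start - g
  } else {
    t_up <- .g_to_t(aln, right$g_start);   d_up <- right$g_start - g
    t_dn <- .g_to_t(aln, left$g_end - 1);  d_dn <- g - (left$g_end - 1)
  }
  if (d_up <= d_dn) {
    base <- t_up - aln$cds_start + 1
    off <- d_up
  } else {
    base <- t_dn - aln$cds_start + 1
    off <- -d_dn
  }
  if (base < 1)
    gn_projection_gap("position 5' of the CDS is out of the supported grammar")
  cds_position(base, off)
}

# Reject edits whose genomic footprint [lo, hi] skips across an exon
# junction: more than one exon block touched, or one block straddled on
# both sides.
.check_junction <- function(aln, lo, hi, what) {
  b <- aln$blocks
  touched <- which(b$g_start <= hi & b$g_end > lo)
  if (length(touched) > 1)
    gn_junction_unsupported(sprintf(
      "%s spans an exon junction of %s", what, aln$transcript_accession))
  if (length(touched) == 1) {
    blk <- b[touched, ]
    if (lo < blk$g_start && hi >= blk$g_end)
      gn_junction_unsupported(sprintf(
        "%s spans two introns of %s", what, aln$transcript_accession))
  }
  invisible(TRUE)
}

.revcomp <- function(x) {
  if (!nzchar(x)) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Project a transcript variant onto the genome
#'
#' Maps both endpoints through the exon alignment. On the `-` strand the
#' endpoints swap into ascending genomic order and the alleles are
#' reverse-complemented. Intronic endpoints are allowed; edits spanning an
#' exon junction raise `gn_junction_unsupported`.
#'
#' @param x a [hgvs_c_variant()].
#' @param aln a [transcript_alignment()] for the variant's transcript.
#' @return A [hgvs_g_variant()] on the alignment's chromosome.
#' @export
project_c_to_g <- function(x, aln) {
  stopifnot(inherits(x, "hgvs_c_variant"), inherits(aln, "transcript_alignment"))
  if (x$accession != aln$transcript_accession)
    gn_validation_error(sprintf("variant accession %s does not match alignment %s",
                                x$accession, aln$transcript_accession))
  g1 <- .cds_to_gindex(x$start, aln)
  g2 <- .cds_to_gindex(x$end, aln)
  lo <- min(g1, g2); hi <- max(g1, g2)
  .check_junction(aln, lo, hi, format_hgvs(x))
  neg <- aln$strand == "-"
  ref <- if (neg) .revcomp(x$ref) else x$ref
  alt <- if (neg) .revcomp(x$alt) else x$alt
  hgvs_g_variant(aln$chromosome_accession, x$kind,
                 start = lo + 1, end = hi + 1, ref = ref, alt = alt)
}

#' Project a genomic variant onto a transcript
#'
#' Inverse of [project_c_to_g()] on its image; genomic positions inside an
#' intron are expressed with nearest-exon offsets.
#'
#' @param x a [hgvs_g_variant()] on the alignment's chromosome.
#' @param aln a [transcript_alignment()].
#' @return A [hgvs_c_variant()].
#' @export
project_g_to_c <- function(x, aln) {
  stopifnot(inherits(x, "hgvs_g_variant"), inherits(aln, "transcript_alignment"))
  if (x$accession != aln$chromosome_accession)
    gn_projection_gap(sprintf("variant accession %s does not match alignment chromosome %s",
                              x$accession, aln$chromosome_accession))
  lo <- x$start - 1; hi <- x$end - 1
  .check_junction(aln, lo, hi, format_hgvs(x))
  c_lo <- .gindex_to_cds(lo, aln)
  c_hi <- .gindex_to_cds(hi, aln)
  if (aln$strand == "-") { tmp <- c_lo; c_lo <- c_hi; c_hi <- tmp }
  neg <- aln$strand == "-"
  ref <- if (neg) .revcomp(x$ref) else x$ref
  alt <- if (neg) .revcomp(x$alt) else x$alt
  hgvs_c_variant(aln$transcript_accession, x$kind,
                 start = c_lo, end = c_hi, ref = ref, alt = alt)
}

#' Alignment database
#'
#' Holds [transcript_alignment()]s indexed by transcript accession (one per
#' build) and searchable by chromosome overlap.
#'
#' @param alignments list of [transcript_alignment()]s.
#' @return An object of class `alignment_db`.
#' @export
alignment_db <- function(alignments = list()) {
  for (a in alignments) stopifnot(inherits(a, "transcript_alignment"))
  keys <- vapply(alignments, function(a)
    paste(a$transcript_accession, a$build, sep = "|"), "")
  if (anyDuplicated(keys))
    gn_validation_error("a transcript may have at most one alignment per build")
  structure(list(alignments = alignments), class = "alignment_db")
}

#' @export
print.alignment_db <- function(x, ...) {
  cat("<alignment_db> ", length(x$alignments), " alignment(s)\n", sep = "")
  invisible(x)
}

#' Alignments of one transcript, named by build label
#'
#' @param db an [alignment_db()].
#' @param accession transcript accession.
#' @return Named list of [transcript_alignment()]s (possibly empty).
#' @export
transcript_alignments <- function(db, accession) {
  hits <- Filter(function(a) a$transcript_accession == accession,
                 db$alignments)
  stats::setNames(hits, vapply(hits, function(a) a$build, ""))
}

#' Select the transcript used for liftover
#'
#' Among alignments overlapping the variant on its chromosome: prefer
#' `mane = TRUE`, then the largest genomic overlap, then the
#' lexicographically smallest transcript accession. Deterministic.
#'
#' @param x a [hgvs_g_variant()].
#' @param db an [alignment_db()].
#' @return The selected [transcript_alignment()].
#' @export
select_transcript <- function(x, db) {
  stopifnot(inherits(x, "hgvs_g_variant"))
  lo <- x$start - 1; hi <- x$end  # 0-based half-open footprint
  cand <- Filter(function(a) {
    ext <- .g_extent(a)
    a$chromosome_accession == x$accession && ext[1] < hi && lo < ext[2]
  }, db$alignments)
  if (!length(cand))
    gn_no_transcript(sprintf("no transcript alignment overlaps %s", format_hgvs(x)))
  ov <- vapply(cand, function(a) {
    ext <- .g_extent(a); min(hi, ext[2]) - max(lo, ext[1])
  }, 0)
  mane <- vapply(cand, function(a) a$mane, NA)
  acc <- vapply(cand, function(a) a$transcript_accession, "")
  cand[[order(-mane, -ov, acc)[1]]]
}

#' Read / write an alignment database (JSON)
#'
#' JSON array of records with fields `transcript_accession`,
#' `chromosome_accession`, `build`, `strand`, `cds_start`, `mane` and
#' `blocks` (array of `[g_start, g_end, t_start, t_end]`). Invariants are
#' validated on load.
#'
#' @param path JSON file path.
#' @return An [alignment_db()].
#' @export
read_alignment_db <- function(path) {
  recs <- jsonlite::read_json(path)
  alignment_db(lapply(recs, function(r) {
    blocks <- do.call(rbind, lapply(r$blocks, function(b)
      data.frame(g_start = as.numeric(b[[1]]), g_end = as.numeric(b[[2]]),
                 t_start = as.numeric(b[[3]]), t_end = as.numeric(b[[4]]))))
    transcript_alignment(r$transcript_accession, r$chromosome_accession,
                         r$build, r$strand, blocks, r$cds_start,
                         isTRUE(r$mane))
  }))
}

#' @rdname read_alignment_db
#' @param db an [alignment_db()] to serialize.
#' @export
write_alignment_db <- function(db, path) {
  recs <- lapply(db$alignments, function(a) {
    list(transcript_accession = a$transcript_accession,
         chromosome_accession = a$chromosome_accession,
         build = a$build, strand = a$strand, cds_start = a$cds_start,
         mane = a$mane,
         blocks = lapply(seq_len(nrow(a$blocks)), function(i)
           as.numeric(a$blocks[i, c("g_start", "g_end", "t_start", "t_end")])))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
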