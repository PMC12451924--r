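# Canonicalization of sequence edits. The canonical variant form is the
# chromosome-level *fully justified* SPDI expression: the position is the
# leftmost placement of the change, the deleted allele spans the entire
# interval over which the change can be equivalently placed, and the
# inserted allele is that span with the change applied. Substitutions are
# their own canonical form; indels in repeat context expand.

#' Trim shared allele sequence
#'
#' Removes the longest common prefix, then the longest common suffix, from
#' the deleted/inserted allele pair, advancing the position by the prefix
#' length. Idempotent. Complete cancellation (`ref == alt`) yields the
#' distinguished empty-change marker (see [is_identity_variant()]) rather
#' than an error.
#'
#' @param x a [spdi_variant()] with literal alleles.
#' @return The trimmed `spdi_variant`.
#' @export
trim_spdi <- function(x) {
  stopifnot(inherits(x, "spdi_variant"))
  if (!is.null(x$deleted_length))
    gn_validation_error("cannot trim a length-only deletion")
  d <- x$deleted; i <- x$inserted; pos <- x$position
  k <- 0L
  while (k < nchar(d) && k < nchar(i) &&
         substr(d, k + 1, k + 1) == substr(i, k + 1, k + 1)) k <- k + 1L
  d <- substr(d, k + 1, nchar(d)); i <- substr(i, k + 1, nchar(i))
  pos <- pos + k
  s <- 0L
  while (s < nchar(d) && s < nchar(i) &&
         substr(d, nchar(d) - s, nchar(d) - s) ==
         substr(i, nchar(i) - s, nchar(i) - s)) s <- s + 1L
  d <- substr(d, 1, nchar(d) - s); i <- substr(i, 1, nchar(i) - s)
  spdi_new <- x
  spdi_new$position <- pos; spdi_new$deleted <- d; spdi_new$inserted <- i
  spdi_new
}

# Resolve a length-only deletion against the catalog.
resolve_deletion <- function(x, catalog) {
  if (is.null(x$deleted_length)) return(x)
  d <- get_slice(catalog, x$sequence_id, x$position,
                 x$position + x$deleted_length)
  spdi_variant(x$sequence_id, x$position, d, x$inserted)
}

# Single reference base at 0-based index idx; distinct error when the base
# is N (rolling across unknown sequence is ambiguous, not a mismatch).
.roll_base <- function(catalog, acc, idx) {
  if (idx < 0)
    gn_coverage_error(sprintf("position %s is before the sequence start",
                              format(idx, scientific = FALSE)))
  b <- get_slice(catalog, acc, idx, idx + 1)
  if (b == "N")
    gn_ambiguous_context(sprintf(
      "cannot roll across N at %s:%s", acc, format(idx, scientific = FALSE)))
  b
}

# Classify a trimmed variant for rolling: "del", "ins", or NA (substitution
# and non-rollable delins keep their own span).
.roll_kind <- function(x) {
  if (nzchar(x$deleted) && !nzchar(x$inserted)) "del"
  else if (!nzchar(x$deleted) && nzchar(x$inserted)) "ins"
  else NA_character_
}

.check_deleted_matches <- function(x, catalog) {
  span <- get_slice(catalog, x$sequence_id, x$position,
                    x$position + nchar(x$deleted))
  if (span != x$deleted)
    gn_reference_disagreement(sprintf(
      "deleted allele %s disagrees with reference %s at %s:%s",
      x$deleted, span, x$sequence_id,
      format(x$position, scientific = FALSE)))
  invisible(TRUE)
}

.roll_dir <- function(x, catalog, dir) {
  x <- trim_spdi(resolve_deletion(x, catalog))
  kind <- .roll_kind(x)
  if (is.na(kind)) return(x)    # substitution / delins: own span
  allele <- if (kind == "del") x$deleted else x$inserted
  L <- nchar(allele)
  if (kind == "del") .check_deleted_matches(x, catalog)
  pos <- x$position
  repeat {
    if (dir > 0) {
      probe <- if (kind == "del") pos + L else pos
      b <- .roll_base(catalog, x$sequence_id, probe)
      if (b != substr(allele, 1, 1)) break
      allele <- paste0(substr(allele, 2, L), b)
      pos <- pos + 1
    } else {
      b <- .roll_base(catalog, x$sequence_id, pos - 1)
      if (b != substr(allele, L, L)) break
      allele <- paste0(b, substr(allele, 1, L - 1))
      pos <- pos - 1
    }
  }
  out <- x
  out$position <- pos
  if (kind == "del") out$deleted <- allele else out$inserted <- allele
  out
}

#' Roll a variant to its extreme placements
#'
#' `roll_left()`/`roll_right()` return the minimal-allele representation at
#' the 5'-most / 3'-most placement that denotes the same sequence change.
#' Substitutions and non-rollable delins are returned trimmed and unmoved.
#' Both are idempotent. Rolling requires covered sequence context and
#' refuses to roll across an `N` base (ambiguous context).
#'
#' @param x a [spdi_variant()].
#' @param catalog a [seq_catalog()] covering the rolling context.
#' @return The rolled `spdi_variant`.
#' @export
roll_left <- function(x, catalog) .roll_dir(x, catalog, -1L)

#' @rdname roll_left
#' @export
roll_right <- function(x, catalog) .roll_dir(x, catalog, +1L)

#' Justification extent of a variant
#'
#' The maximal interbase interval `[left_most, right_most)` such that every
#' placement of the change inside it denotes the same mutated sequence,
#' together with the reference bases spanning it (`repeat_context`). A
#' substitution's extent is its own single-base interval.
#'
#' @inheritParams roll_left
#' @return A list of class `justification_extent` with fields `left_most`,
#'   `right_most`, `repeat_context`.
#' @export
justification_extent <- function(x, catalog) {
  x <- trim_spdi(resolve_deletion(x, catalog))
  kind <- .roll_kind(x)
  if (is.na(kind)) {
    lm <- x$position; rm_ <- x$position + nchar(x$deleted)
  } else {
    vl <- .roll_dir(x, catalog, -1L)
    vr <- .roll_dir(x, catalog, +1L)
    lm <- vl$position
    rm_ <- if (kind == "del") vr$position + nchar(vr$deleted) else vr$position
  }
  ctx <- if (is_covered(catalog, x$sequence_id, lm, rm_))
    get_slice(catalog, x$sequence_id, lm, rm_) else NA_character_
  structure(list(left_most = lm, right_most = rm_, repeat_context = ctx),
            class = "justification_extent")
}

#' Fully justify a variant to canonical SPDI
#'
#' Canonical form: position at the extent's left edge, deleted allele equal
#' to the full reference span of the extent, inserted allele equal to that
#' span with the change applied. Idempotent, and independent of the input
#' placement: every representation of the same sequence change maps to the
#' identical canonical SPDI. Substitutions and non-rollable delins are
#' returned trimmed (their extent is their own span). Indel justification
#' requires covered context; substitutions touch no sequence.
#'
#' @inheritParams roll_left
#' @return The canonical `spdi_variant`.
#' @export
fully_justify <- function(x, catalog = NULL) {
  if (is.null(x$deleted_length)) {
    xt <- trim_spdi(x)
    if (is_identity_variant(xt)) return(xt)
    if (is.na(.roll_kind(xt))) return(xt)   # sub / delins: no catalog needed
  }
  if (is.null(catalog))
    gn_coverage_error("indel justification requires a sequence catalog")
  x <- trim_spdi(resolve_deletion(x, catalog))
  kind <- .roll_kind(x)
  vl <- .roll_dir(x, catalog, -1L)
  vr <- .roll_dir(x, catalog, +1L)
  if (kind == "del") {
    L <- nchar(x$deleted)
    lm <- vl$position; rm_ <- vr$position + L
    ctx <- get_slice(catalog, x$sequence_id, lm, rm_)
    out <- x
    out$position <- lm
    out$deleted <- ctx
    out$inserted <- substr(ctx, L + 1, nchar(ctx))
  } else {
    lm <- vl$position; rm_ <- vr$position
    ctx <- get_slice(catalog, x$sequence_id, lm, rm_)
    out <- x
    out$position <- lm
    out$deleted <- ctx
    out$inserted <- paste0(vl$inserted, ctx)
  }
  out
}

#' Convert genomic HGVS to SPDI
#'
#' 1-based HGVS positions map to 0-based interbase: a substitution at `p`
#' becomes SPDI position `p - 1`; a deletion of `[s, e]` becomes position
#' `s - 1` with the deleted span; an insertion between `s` and `s + 1`
#' becomes position `s` with an empty deleted allele; a duplication of
#' `[s, e]` is rewritten as insertion of the span after itself. The result
#' is then fully justified when it needs context. A stated reference allele
#' is checked against the catalog when covered; when the position is not
#' covered the stated allele is trusted for context-free edits
#' (substitutions) — `validate = "always"` turns that into a coverage error.
#'
#' @param x a [hgvs_g_variant()].
#' @param catalog a [seq_catalog()]; may lack coverage for substitutions.
#' @param validate `"auto"` (check when covered, trust otherwise),
#'   `"always"`, or `"never"`.
#' @param justify fully justify the result (default) or return the raw
#'   conversion.
#' @return A [spdi_variant()].
#' @export
hgvs_g_to_spdi <- function(x, catalog = NULL, validate = c("auto", "always", "never"),
                           justify = TRUE) {
  stopifnot(inherits(x, "hgvs_g_variant"))
  validate <- match.arg(validate)
  acc <- x$accession
  covered <- function(s, e) !is.null(catalog) && is_covered(catalog, acc, s, e)
  check_ref <- function(stated, s, e) {
    if (!nzchar(stated) || validate == "never") return(stated)
    if (covered(s, e)) {
      actual <- get_slice(catalog, acc, s, e)
      if (actual != stated)
        gn_reference_disagreement(sprintf(
          "stated reference %s disagrees with catalog %s at %s:g.%s",
          stated, actual, acc, format(s + 1, scientific = FALSE)))
    } else if (validate == "always") {
      gn_coverage_error(sprintf(
        "validation requested but %s:[%s,%s) is not covered", acc,
        format(s, scientific = FALSE), format(e, scientific = FALSE)))
    }
    stated
  }
  span_of <- function(stated, s, e) {
    # stated allele if given (validated), else read from catalog
    if (nzchar(stated)) {
      if (nchar(stated) != e - s)
        gn_validation_error("stated allele length disagrees with the position range")
      check_ref(stated, s, e)
    } else get_slice(catalog %||% gn_coverage_error(
      "deletion without stated allele requires a sequence catalog"),
      acc, s, e)
  }
  v <- switch(x$kind,
    sub = {
      check_ref(x$ref, x$start - 1, x$start)
      spdi_variant(acc, x$start - 1, x$ref, x$alt)
    },
    del = spdi_variant(acc, x$start - 1,
                       span_of(x$ref, x$start - 1, x$end), ""),
    ins = spdi_variant(acc, x$start, "", x$alt),
    delins = spdi_variant(acc, x$start - 1,
                          span_of(x$ref, x$start - 1, x$end), x$alt),
    dup = {
      span <- span_of(x$ref, x$start - 1, x$end)
      spdi_variant(acc, x$end, "", span)
    })
  if (justify) fully_justify(v, catalog) else trim_spdi(v)
}

#' Convert SPDI to genomic HGVS
#'
#' Classifies the trimmed edit and emits HGVS with indels at the 3'-most
#' (right-rolled) placement, per HGVS convention. An insertion whose allele
#' equals the immediately 5'-adjacent reference span is emitted as `dup`.
#' Indel placement requires covered context; substitutions do not.
#'
#' @param x a [spdi_variant()].
#' @param catalog a [seq_catalog()].
#' @return A [hgvs_g_variant()].
#' @export
spdi_to_hgvs_g <- function(x, catalog = NULL) {
  stopifnot(inherits(x, "spdi_variant"))
  if (!is.null(x$deleted_length)) x <- resolve_deletion(x, catalog %||%
    gn_coverage_error("length-only deletion requires a sequence catalog"))
  x <- trim_spdi(x)
  if (is_identity_variant(x))
    gn_validation_error("identity record has no HGVS representation")
  acc <- x$sequence_id
  dlen <- nchar(x$deleted); ilen <- nchar(x$inserted)
  if (dlen == 1L && ilen == 1L)
    return(hgvs_g_variant(acc, "sub", x$position + 1, x$position + 1,
                          x$deleted, x$inserted))
  if (dlen > 0L && ilen > 0L)
    return(hgvs_g_variant(acc, "delins", x$position + 1, x$position + dlen,
                          x$deleted, x$inserted))
  if (is.null(catalog))
    gn_coverage_error("indel placement requires a sequence catalog")
  r <- roll_right(x, catalog)
  if (dlen > 0L) {
    return(hgvs_g_variant(acc, "del", r$position + 1, r$position + dlen,
                          r$deleted, ""))
  }
  # insertion: dup when the allele restates the 5'-adjacent reference span
  p <- r$position; a <- r$inserted; L <- nchar(a)
  is_dup <- p - L >= 0 && is_covered(catalog, acc, p - L, p) &&
    get_slice(catalog, acc, p - L, p) == a
  if (is_dup)
    hgvs_g_variant(acc, "dup", p - L + 1, p, a, "")
  else
    hgvs_g_variant(acc, "ins", p, p + 1, "", a)
}

#' Convert a VCF data row to SPDI
#'
#' VCF alleles are 1-based and anchor-base style; the SPDI position is
#' `pos - 1` and the shared anchor base trims away. Symbolic alleles
#' (`<DEL>`, breakends) are unsupported.
#'
#' @param accession chromosome accession (already resolved from CHROM).
#' @param pos 1-based VCF position.
#' @param ref,alt VCF allele strings.
#' @return A trimmed [spdi_variant()] (possibly the identity marker).
#' @export
vcf_row_to_spdi <- function(accession, pos, ref, alt) {
  for (a in c(ref, alt))
    if (grepl("[<>\\[\\]]|^\\.$|\\*", a) || !grepl("^[ACGTN]+$", a))
      gn_unsupported_syntax(sprintf("unsupported VCF allele: %s", a))
  trim_spdi(spdi_variant(accession, as.numeric(pos) - 1, ref, alt))
}

#' Read a minimal VCF file
#'
#' Parses tab-separated `CHROM POS ID REF ALT` data lines (`#` comment and
#' header lines skipped) and resolves `CHROM` to an accession through a
#' contig map. Multi-allelic rows are split on the ALT comma.
#'
#' @param path VCF file path.
#' @param contig_map data frame or list of records with fields `chrom`,
#'   `accession` and optionally `build` (see [read_contig_map()]).
#' @param build restrict resolution to one build label when the map carries
#'   several.
#' @return A list of [spdi_variant()]s.
#' @export
read_vcf_variants <- function(path, contig_map, build = NULL) {
  if (is.list(contig_map) && !is.data.frame(contig_map))
    contig_map <- do.call(rbind, lapply(contig_map, as.data.frame))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 5L)
      gn_parse_error(sprintf("VCF data line has fewer than 5 fields: %s", ln))
    hit <- contig_map$chrom == f[1]
    if (!is.null(build) && "build" %in% names(contig_map))
      hit <- hit & contig_map$build == build
    if (!any(hit))
      gn_not_found(sprintf("no accession mapped for contig %s", f[1]))
    acc <- contig_map$accession[which(hit)[1]]
    for (alt in strsplit(f[5], ",", fixed = TRUE)[[1]])
      out[[length(out) + 1L]] <- vcf_row_to_spdi(acc, as.numeric(f[2]),
                                                 f[4], alt)
  }
  out
}

#' Read a contig-to-accession map
#'
#' JSON array of `{chrom, build, accession}` records.
#'
#' @param path JSON file path.
#' @return A data frame with columns `chrom`, `build`, `accession`.
#' @export
read_contig_map <- function(path) {
  jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
}
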