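# SPDI and (subset) HGVS grammars. SPDI positions are 0-based interbase;
# HGVS positions are 1-based. Whitespace is tolerated anywhere on input
# (published examples contain stray spaces) and never emitted on output.

#' SPDI variant
#'
#' Four-field sequence edit: sequence id, 0-based interbase position, deleted
#' allele, inserted allele. A numeric third field (length-only deletion) is
#' kept as `deleted_length` until resolved against sequence context.
#'
#' @param sequence_id versioned accession.
#' @param position 0-based interbase offset, `>= 0`.
#' @param deleted,inserted allele strings over `ACGT` (possibly empty).
#' @param deleted_length length of a length-only deletion, or `NULL` when the
#'   deleted allele is given literally.
#' @return An object of class `spdi_variant`.
#' @export
spdi_variant <- function(sequence_id, position, deleted = "", inserted = "",
                         deleted_length = NULL) {
  position <- as.numeric(position)
  if (is.na(position) || position < 0)
    gn_parse_error("SPDI position must be a non-negative integer")
  if (is.null(deleted_length)) {
    for (a in c(deleted, inserted))
      if (nzchar(a) && !grepl("^[ACGT]+$", a))
        gn_parse_error(sprintf("SPDI allele must be uppercase ACGT: %s", a))
  }
  structure(list(sequence_id = sequence_id, position = position,
                 deleted = deleted, inserted = inserted,
                 deleted_length = deleted_length),
            class = "spdi_variant")
}

#' @export
print.spdi_variant <- function(x, ...) {
  del <- if (!is.null(x$deleted_length)) paste0("<len ", x$deleted_length, ">")
         else x$deleted
  cat("<spdi> ", x$sequence_id, ":",
      format(x$position, scientific = FALSE), ":", del, ":", x$inserted,
      "\n", sep = "")
  invisible(x)
}

#' Test for the empty-change marker
#'
#' [trim_spdi()] reduces a variant whose deleted and inserted alleles cancel
#' completely to an identity record; callers decide whether to drop or
#' report it.
#'
#' @param x an object.
#' @return `TRUE` for an identity `spdi_variant`.
#' @export
is_identity_variant <- function(x) {
  inherits(x, "spdi_variant") && is.null(x$deleted_length) &&
    !nzchar(x$deleted) && !nzchar(x$inserted)
}

#' CDS-relative position
#'
#' 1-based coding position with an optional signed intronic offset
#' (`c.1311_1312+1del` has end base 1312 with offset +1). Offset 0 is exonic.
#'
#' @param base CDS coordinate, `>= 1`.
#' @param offset signed intronic offset.
#' @return An object of class `cds_position`.
#' @export
cds_position <- function(base, offset = 0L) {
  base <- as.numeric(base); offset <- as.numeric(offset)
  if (is.na(base) || base < 1)
    gn_parse_error("CDS base must be >= 1")
  structure(list(base = base, offset = offset), class = "cds_position")
}

# Total order on CDS positions (offsets attach 3' of their anchor when
# positive, 5' when negative).
cds_key <- function(p) p$base * 1e6 + p$offset

format_cds_position <- function(p) {
  paste0(format(p$base, scientific = FALSE),
         if (p$offset > 0) paste0("+", format(p$offset, scientific = FALSE))
         else if (p$offset < 0) format(p$offset, scientific = FALSE)
         else "")
}

#' Genomic (g.) HGVS variant
#'
#' @param accession `NC_`-style versioned accession.
#' @param kind edit kind: `"sub"`, `"del"`, `"ins"`, `"delins"` or `"dup"`.
#' @param start,end 1-based positions, `start <= end`; for `ins`,
#'   `end == start + 1` and the insertion falls between them.
#' @param ref stated reference allele (may be `""` when unstated).
#' @param alt alternate allele (may be `""`).
#' @return An object of class `hgvs_g_variant`.
#' @export
hgvs_g_variant <- function(accession, kind, start, end = start,
                           ref = "", alt = "") {
  start <- as.numeric(start); end <- as.numeric(end)
  kind <- match.arg(kind, c("sub", "del", "ins", "delins", "dup"))
  if (start < 1 || end < start)
    gn_parse_error("HGVS positions must satisfy 1 <= start <= end")
  if (kind == "sub" && (nchar(ref) != 1L || nchar(alt) != 1L))
    gn_parse_error("HGVS substitution must have single-base ref and alt")
  if (kind == "ins" && (end != start + 1 || nzchar(ref) || !nzchar(alt)))
    gn_parse_error("HGVS insertion must be between adjacent positions")
  structure(list(accession = accession, kind = kind, start = start,
                 end = end, ref = ref, alt = alt),
            class = "hgvs_g_variant")
}

#' Transcript (c.) HGVS variant
#'
#' @inheritParams hgvs_g_variant
#' @param accession `NM_`-style versioned accession.
#' @param start,end [cds_position()] endpoints ordered by transcript
#'   position.
#' @return An object of class `hgvs_c_variant`.
#' @export
hgvs_c_variant <- function(accession, kind, start, end = start,
                           ref = "", alt = "") {
  stopifnot(inherits(start, "cds_position"), inherits(end, "cds_position"))
  kind <- match.arg(kind, c("sub", "del", "ins", "delins", "dup"))
  if (cds_key(start) > cds_key(end))
    gn_parse_error("HGVS c. endpoints must be in transcript order")
  structure(list(accession = accession, kind = kind, start = start,
                 end = end, ref = ref, alt = alt),
            class = "hgvs_c_variant")
}

#' @export
print.hgvs_g_variant <- function(x, ...) {
  cat("<hgvs g.> ", format_hgvs(x), "\n", sep = ""); invisible(x)
}

#' @export
print.hgvs_c_variant <- function(x, ...) {
  cat("<hgvs c.> ", format_hgvs(x), "\n", sep = ""); invisible(x)
}

strip_ws <- function(text) gsub("[[:space:]]+", "", text)

#' Parse an SPDI string
#'
#' `"NC_000019.9:11200235:G:A"` has four colon-separated fields. The third
#' field may be an allele string or a non-negative integer (a length-only
#' deletion, kept unresolved until sequence context is available).
#'
#' @param text SPDI string; surrounding whitespace is tolerated.
#' @return A [spdi_variant()].
#' @export
parse_spdi <- function(text) {
  text <- strip_ws(text)
  # keep trailing empty fields: "ACC:5:T:" has an empty inserted allele
  fields <- strsplit(paste0(text, "\x01"), ":", fixed = TRUE)[[1]]
  fields[length(fields)] <- sub("\x01$", "", fields[length(fields)])
  if (length(fields) != 4L)
    gn_parse_error(sprintf("SPDI requires 4 colon-separated fields, got %d",
                           length(fields)))
  if (!grepl("^\\d+$", fields[2]))
    gn_parse_error(sprintf("SPDI position must be a non-negative integer: %s",
                           fields[2]))
  del <- fields[3]
  if (grepl("^\\d+$", del) && nzchar(del))
    return(spdi_variant(fields[1], fields[2], deleted = NA_character_,
                        inserted = fields[4],
                        deleted_length = as.numeric(del)))
  if (!nzchar(del) && !nzchar(fields[4]))
    gn_parse_error("SPDI deleted and inserted alleles are both empty")
  spdi_variant(fields[1], fields[2], deleted = del, inserted = fields[4])
}

#' Format an SPDI variant
#'
#' @param x a [spdi_variant()] with a literal (not length-only) deletion.
#' @return The canonical four-field string.
#' @export
format_spdi <- function(x) {
  stopifnot(inherits(x, "spdi_variant"))
  if (!is.null(x$deleted_length))
    gn_format_error("length-only deletion must be resolved against sequence before formatting")
  paste(x$sequence_id, format(x$position, scientific = FALSE),
        x$deleted, x$inserted, sep = ":")
}

# Supported HGVS edit grammar, shared by g. and c. position parsing.
# pos_re must contain no capture groups.
.parse_hgvs_edit <- function(rest, pos_re, make_pos) {
  rx <- function(pattern) {
    g <- regmatches(rest, regexec(pattern, rest))[[1]]
    if (length(g)) g else NULL
  }
  one <- paste0("^(", pos_re, ")")
  two <- paste0("^(", pos_re, ")_(", pos_re, ")")
  if (!is.null(g <- rx(paste0(two, "(del|dup)([ACGT]*)$"))))
    return(list(kind = g[4], start = make_pos(g[2]), end = make_pos(g[3]),
                ref = g[5], alt = ""))
  if (!is.null(g <- rx(paste0(two, "delins([ACGT]+)$"))))
    return(list(kind = "delins", start = make_pos(g[2]),
                end = make_pos(g[3]), ref = "", alt = g[4]))
  if (!is.null(g <- rx(paste0(two, "ins([ACGT]+)$"))))
    return(list(kind = "ins", start = make_pos(g[2]), end = make_pos(g[3]),
                ref = "", alt = g[4]))
  if (!is.null(g <- rx(paste0(one, "([ACGT])>([ACGT])$"))))
    return(list(kind = "sub", start = make_pos(g[2]), end = make_pos(g[2]),
                ref = g[3], alt = g[4]))
  if (!is.null(g <- rx(paste0(one, "(del|dup)([ACGT]*)$"))))
    return(list(kind = g[3], start = make_pos(g[2]), end = make_pos(g[2]),
                ref = g[4], alt = ""))
  if (!is.null(g <- rx(paste0(one, "delins([ACGT]+)$"))))
    return(list(kind = "delins", start = make_pos(g[2]),
                end = make_pos(g[2]), ref = "", alt = g[3]))
  if (grepl("\\[", rest) || grepl("=", rest))
    gn_unsupported_syntax(sprintf("HGVS edit syntax not supported: %s", rest))
  gn_parse_error(sprintf("cannot parse HGVS edit: %s", rest))
}

#' Parse an HGVS string (supported subset)
#'
#' Accepts chromosome-level `NC_...:g.` and transcript-level `NM_...:c.`
#' variants with edits in `{sub, del, ins, delins, dup}`. Intronic offsets
#' (`c.1311_1312+1del`) are parsed; UTR coordinates (`c.-N`, `c.*N`),
#' protein/RNA/repeat syntax, and `LRG_`/`NG_` references are rejected with
#' distinct errors. Accession versions are required.
#'
#' @param text HGVS string; whitespace tolerated.
#' @return A [hgvs_g_variant()] or [hgvs_c_variant()].
#' @export
parse_hgvs <- function(text) {
  text <- strip_ws(text)
  m <- regmatches(text, regexec("^([A-Za-z]+_[0-9A-Za-z]+(\\.\\d+)?):([a-z*])\\.(.*)$", text))[[1]]
  if (!length(m))
    gn_parse_error(sprintf("not an HGVS expression: %s", text))
  acc <- m[2]; version <- m[3]; ctype <- m[4]; rest <- m[5]
  prefix <- sub("_.*$", "_", acc)
  if (prefix %in% c("LRG_", "NG_", "NP_", "NR_", "NW_", "NT_"))
    gn_unsupported_reference(sprintf(
      "only NM_ transcript and NC_ chromosome references are supported: %s", acc))
  if (!prefix %in% c("NM_", "NC_"))
    gn_unsupported_reference(sprintf("unsupported reference accession: %s", acc))
  if (!nzchar(version))
    gn_parse_error(sprintf("accession version is required: %s", acc))
  if (ctype %in% c("p", "r"))
    gn_unsupported_syntax(sprintf("HGVS %s. syntax is not supported", ctype))
  if (ctype == "g") {
    if (prefix != "NC_")
      gn_parse_error("g. coordinates require an NC_ chromosome accession")
    e <- .parse_hgvs_edit(rest, "\\d+", as.numeric)
    return(hgvs_g_variant(acc, e$kind, e$start, e$end, e$ref, e$alt))
  }
  if (ctype == "c") {
    if (prefix != "NM_")
      gn_parse_error("c. coordinates require an NM_ transcript accession")
    if (grepl("^-|_-|^\\*|_\\*", rest))
      gn_parse_error("UTR coordinates (c.-N / c.*N) are unsupported")
    make_cds <- function(s) {
      g <- regmatches(s, regexec("^(\\d+)([+-]\\d+)?$", s))[[1]]
      cds_position(g[2], if (nzchar(g[3])) as.numeric(g[3]) else 0)
    }
    e <- .parse_hgvs_edit(rest, "\\d+(?:[+-]\\d+)?", make_cds)
    return(hgvs_c_variant(acc, e$kind, e$start, e$end, e$ref, e$alt))
  }
  gn_unsupported_syntax(sprintf("HGVS coordinate type %s. is not supported", ctype))
}

#' Format an HGVS variant
#'
#' Canonical spelling: no whitespace, uppercase alleles, bare `del`/`dup`
#' (no restated reference allele), underscore ranges only for multi-position
#' edits.
#'
#' @param x a [hgvs_g_variant()] or [hgvs_c_variant()].
#' @return The HGVS string.
#' @export
format_hgvs <- function(x) {
  if (inherits(x, "hgvs_g_variant")) {
    p1 <- format(x$start, scientific = FALSE)
    p2 <- format(x$end, scientific = FALSE)
    tag <- "g."
  } else if (inherits(x, "hgvs_c_variant")) {
    p1 <- format_cds_position(x$start)
    p2 <- format_cds_position(x$end)
    tag <- "c."
  } else stop("not an HGVS variant")
  body <- switch(x$kind,
    sub    = paste0(p1, x$ref, ">", x$alt),
    del    = if (identical(p1, p2)) paste0(p1, "del")
             else paste0(p1, "_", p2, "del"),
    dup    = if (identical(p1, p2)) paste0(p1, "dup")
             else paste0(p1, "_", p2, "dup"),
    ins    = paste0(p1, "_", p2, "ins", x$alt),
    delins = if (identical(p1, p2)) paste0(p1, "delins", x$alt)
             else paste0(p1, "_", p2, "delins", x$alt))
  paste0(x$accession, ":", tag, body)
}

#' Classify a variant string
#'
#' Dispatch for the normalization pipelines: SPDI inputs have four
#' colon-separated fields with an integer position; HGVS inputs carry a
#' `g.`/`c.` coordinate tag. Level is `"transcript"` for `NM_` accessions and
#' `"chromosome"` otherwise.
#'
#' @param text variant string.
#' @return A list with elements `syntax` (`"SPDI"`/`"HGVS"`) and `level`
#'   (`"transcript"`/`"chromosome"`).
#' @export
detect_format <- function(text) {
  s <- strip_ws(text)
  fields <- strsplit(paste0(s, "\x01"), ":", fixed = TRUE)[[1]]
  fields[length(fields)] <- sub("\x01$", "", fields[length(fields)])
  level <- if (startsWith(s, "NM_")) "transcript" else "chromosome"
  if (length(fields) == 4L && grepl("^\\d+$", fields[2]))
    return(list(syntax = "SPDI", level = level))
  if (grepl(":[a-z*]\\.", s))
    return(list(syntax = "HGVS", level = level))
  gn_parse_error(sprintf("cannot classify variant input: %s", text))
}
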