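#' Sparse reference-sequence catalog
#'
#' A `seq_catalog` stores short segments of versioned reference sequences
#' (e.g. a few dozen bases of `NC_000007.14` around a homopolymer) instead of
#' whole chromosomes. Every operation that needs sequence context reads from
#' the catalog through [get_slice()]; any access outside a registered segment
#' fails loudly with a coverage error rather than padding silently. All
#' coordinates are 0-based interbase: position `p` addresses the junction
#' before the (p+1)-th base, so the slice `[start, end)` contains
#' `end - start` bases.
#'
#' @return An empty catalog of class `seq_catalog`.
#' @seealso [register_segment()], [get_slice()], [build_of()]
#' @export
seq_catalog <- function() {
  structure(list(segments = list(), meta = list()), class = "seq_catalog")
}

#' @export
print.seq_catalog <- function(x, ...) {
  n <- length(x$segments)
  cat("<seq_catalog> ", n, " accession(s)\n", sep = "")
  for (acc in names(x$segments)) {
    seg <- x$segments[[acc]]
    cat(sprintf("  %s [%s]: %d segment(s), %d base(s)\n",
                acc, x$meta[[acc]]$build, nrow(seg), sum(nchar(seg$bases))))
  }
  invisible(x)
}

#' Register a sequence segment
#'
#' Adds `bases` to the catalog at interbase offset `start` of `accession`.
#' Segments of one accession must not overlap; `N` is storable but
#' normalization refuses to roll across it.
#'
#' @param catalog a [seq_catalog()].
#' @param accession versioned sequence id, e.g. `"NC_000007.14"`.
#' @param start 0-based interbase offset of the first base.
#' @param bases uppercase string over `A,C,G,T,N`.
#' @param build assembly label: `"GRCh37"`, `"GRCh38"` or a fixture label.
#'   Ignored (must agree) when the accession is already known.
#' @param chromosome optional chromosome name for the accession.
#' @return The updated catalog.
#' @export
register_segment <- function(catalog, accession, start, bases,
                             build = "fixture", chromosome = NA_character_) {
  stopifnot(inherits(catalog, "seq_catalog"))
  if (!is.character(bases) || length(bases) != 1L || !nzchar(bases))
    gn_validation_error("segment bases must be a non-empty string")
  if (!grepl("^[ACGTN]+$", bases))
    gn_validation_error(sprintf("segment bases must be uppercase ACGTN: %s",
                                substr(bases, 1, 20)))
  start <- as.numeric(start)
  if (is.na(start) || start < 0)
    gn_validation_error("segment start must be a non-negative interbase offset")
  end <- start + nchar(bases)

  seg <- catalog$segments[[accession]]
  if (is.null(seg)) {
    seg <- data.frame(start = numeric(), end = numeric(),
                      bases = character(), stringsAsFactors = FALSE)
    catalog$meta[[accession]] <- list(build = build, chromosome = chromosome)
  } else if (!identical(catalog$meta[[accession]]$build, build) &&
             !missing(build)) {
    gn_registration_error(sprintf(
      "accession %s already registered with build %s",
      accession, catalog$meta[[accession]]$build))
  }
  if (any(seg$start < end & start < seg$end))
    gn_registration_error(sprintf(
      "segment [%s,%s) overlaps an existing segment of %s",
      format(start, scientific = FALSE), format(end, scientific = FALSE),
      accession))
  seg <- rbind(seg, data.frame(start = start, end = end, bases = bases,
                               stringsAsFactors = FALSE))
  catalog$segments[[accession]] <- seg[order(seg$start), , drop = FALSE]
  catalog
}

#' Slice reference sequence
#'
#' Returns exactly `end - start` bases of `accession` covering the interbase
#' interval `[start, end)`. The interval may span adjacent (touching)
#' segments; any uncovered position raises a coverage error carrying the gap.
#'
#' @inheritParams register_segment
#' @param start,end 0-based interbase bounds, `start <= end`.
#' @return A base string of length `end - start` (`""` for an empty interval).
#' @export
get_slice <- function(catalog, accession, start, end) {
  stopifnot(inherits(catalog, "seq_catalog"))
  start <- as.numeric(start); end <- as.numeric(end)
  if (start > end) gn_validation_error("slice start must be <= end")
  seg <- catalog$segments[[accession]]
  if (is.null(seg))
    gn_not_found(sprintf("accession %s is not in the catalog", accession))
  if (start == end) return("")
  out <- character(0)
  at <- start
  for (i in seq_len(nrow(seg))) {
    if (at >= end) break
    if (seg$end[i] <= at) next
    if (seg$start[i] > at)
      gn_coverage_error(sprintf(
        "no sequence registered for %s at [%s,%s)", accession,
        format(at, scientific = FALSE),
        format(min(seg$start[i], end), scientific = FALSE)),
        data = list(accession = accession, gap_start = at))
    take_end <- min(end, seg$end[i])
    out <- c(out, substr(seg$bases[i], at - seg$start[i] + 1,
                         take_end - seg$start[i]))
    at <- take_end
  }
  if (at < end)
    gn_coverage_error(sprintf(
      "no sequence registered for %s at [%s,%s)", accession,
      format(at, scientific = FALSE), format(end, scientific = FALSE)),
      data = list(accession = accession, gap_start = at))
  paste(out, collapse = "")
}

# TRUE when [start, end) is fully covered, without raising.
is_covered <- function(catalog, accession, start, end) {
  !inherits(tryCatch(get_slice(catalog, accession, start, end),
                     genonorm_error = function(e) e), "condition")
}

#' Assembly label of an accession
#'
#' @inheritParams register_segment
#' @return The build label the accession was registered under.
#' @export
build_of <- function(catalog, accession) {
  stopifnot(inherits(catalog, "seq_catalog"))
  m <- catalog$meta[[accession]]
  if (is.null(m))
    gn_not_found(sprintf("accession %s is not in the catalog", accession))
  m$build
}

#' Read a sequence catalog from FASTA + JSON sidecar
#'
#' Fixture format: a FASTA file of segment sequences plus a JSON sidecar
#' mapping FASTA record id to `{accession, start, build, chromosome}`.
#' Alphabet and overlap are validated on load.
#'
#' @param fasta_path path to the FASTA file.
#' @param sidecar_path path to the JSON sidecar.
#' @return A [seq_catalog()].
#' @export
read_seq_catalog <- function(fasta_path, sidecar_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  side <- jsonlite::read_json(sidecar_path)
  catalog <- seq_catalog()
  for (id in names(seqs)) {
    rec <- side[[id]]
    if (is.null(rec))
      gn_schema_error(sprintf("FASTA record %s missing from sidecar", id))
    catalog <- register_segment(
      catalog, rec$accession, rec$start, as.character(seqs[[id]]),
      build = rec$build %||% "fixture",
      chromosome = rec$chromosome %||% NA_character_)
  }
  catalog
}

#' Write a sequence catalog as FASTA + JSON sidecar
#'
#' Inverse of [read_seq_catalog()]; used by the fixture builder.
#'
#' @param catalog a [seq_catalog()].
#' @inheritParams read_seq_catalog
#' @return Invisibly, the sidecar list.
#' @export
write_seq_catalog <- function(catalog, fasta_path, sidecar_path) {
  stopifnot(inherits(catalog, "seq_catalog"))
  recs <- list(); seqs <- character(0)
  for (acc in names(catalog$segments)) {
    seg <- catalog$segments[[acc]]
    for (i in seq_len(nrow(seg))) {
      id <- sprintf("%s|%s", acc, format(seg$start[i], scientific = FALSE))
      seqs[[id]] <- seg$bases[i]
      recs[[id]] <- list(accession = acc, start = seg$start[i],
                         build = catalog$meta[[acc]]$build,
                         chromosome = catalog$meta[[acc]]$chromosome)
    }
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fasta_path)
  jsonlite::write_json(recs, sidecar_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(recs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
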