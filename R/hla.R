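# HLA allele parsing and reduction to antigen-recognition-domain (ARD)
# normal forms over a pluggable allele-group database. The canonical form
# stored at ingestion and used for matching is the two-field ARD-level
# "lgx" reduction; G/P/lg/W/exon/U2/S are exposed as utility forms.

#' HLA allele
#'
#' @param locus locus name, e.g. `"DRB1"`, `"A"`.
#' @param fields character vector of 1-4 numeric field strings (zero padding
#'   preserved, e.g. `"02"`); the last may carry an expression suffix letter.
#' @param suffix expression suffix (`N`, `L`, `S`, `Q`, ...) or `""`.
#' @param had_prefix whether the input carried an `HLA-` prefix.
#' @param serology `TRUE` for an antigen-level token such as `DR13`.
#' @return An object of class `hla_allele`.
#' @export
hla_allele <- function(locus, fields, suffix = "", had_prefix = FALSE,
                       serology = FALSE) {
  if (!serology && length(fields) < 1L)
    gn_parse_error("HLA allele requires at least one field")
  if (nzchar(suffix) && length(fields) < 2L)
    gn_parse_error("expression suffix requires at least two fields")
  structure(list(locus = locus, fields = as.character(fields),
                 suffix = suffix, had_prefix = isTRUE(had_prefix),
                 serology = isTRUE(serology)),
            class = "hla_allele")
}

#' Format an HLA allele
#'
#' @param x an [hla_allele()].
#' @param n_fields truncate to at most this many fields (suffix dropped on
#'   truncation).
#' @return The allele string without `HLA-` prefix.
#' @export
format_hla <- function(x, n_fields = Inf) {
  stopifnot(inherits(x, "hla_allele"))
  if (x$serology) return(paste0(x$locus, x$fields[1]))
  k <- min(length(x$fields), n_fields)
  s <- paste0(x$locus, "*", paste(x$fields[seq_len(k)], collapse = ":"))
  if (k == length(x$fields)) paste0(s, x$suffix) else s
}

#' @export
print.hla_allele <- function(x, ...) {
  cat("<hla> ", format_hla(x), if (x$serology) " (serology)", "\n", sep = "")
  invisible(x)
}

#' HLA allele-group database
#'
#' The allele universe plus the grouping tables reduction needs:
#' `alleles` (fully resolved allele names, the expansion universe),
#' `g_groups` / `p_groups` (group name, ending in G / P, to member alleles),
#' `serology` (two-field allele to antigen tokens, in antigen-table order),
#' `mac` (locus-qualified code, e.g. `"DRB1*13:AKBAR"`, to completions).
#'
#' @param alleles character vector of known allele names.
#' @param g_groups,p_groups named lists of member character vectors.
#' @param serology named list: two-field allele name to antigen tokens.
#' @param mac named list: locus-qualified MAC code to completion alleles.
#' @param db_version free-text version tag.
#' @return An object of class `allele_group_db`.
#' @export
allele_group_db <- function(alleles, g_groups = list(), p_groups = list(),
                            serology = list(), mac = list(),
                            db_version = "fixture") {
  for (nm in names(g_groups)) {
    if (!grepl("G$", nm))
      gn_schema_error(sprintf("G-group name must end in G: %s", nm))
    if (!all(g_groups[[nm]] %in% alleles))
      gn_schema_error(sprintf("G-group %s has members outside the allele universe", nm))
  }
  for (nm in names(p_groups)) {
    if (!grepl("P$", nm))
      gn_schema_error(sprintf("P-group name must end in P: %s", nm))
    if (!all(p_groups[[nm]] %in% alleles))
      gn_schema_error(sprintf("P-group %s has members outside the allele universe", nm))
  }
  for (code in names(mac)) {
    locus <- sub("\\*.*$", "", code)
    if (!all(startsWith(mac[[code]], paste0(locus, "*"))))
      gn_schema_error(sprintf("MAC %s completions must share its locus", code))
  }
  structure(list(alleles = alleles, g_groups = g_groups,
                 p_groups = p_groups, serology = serology, mac = mac,
                 db_version = db_version),
            class = "allele_group_db")
}

#' Read / write an allele-group database (JSON)
#'
#' @param path JSON file with keys `alleles`, `g_groups`, `p_groups`,
#'   `serology`, `mac`, `db_version`.
#' @return An [allele_group_db()].
#' @export
read_allele_db <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  allele_group_db(alleles = j$alleles,
                  g_groups = as.list(j$g_groups),
                  p_groups = as.list(j$p_groups),
                  serology = as.list(j$serology),
                  mac = as.list(j$mac),
                  db_version = j$db_version %||% "fixture")
}

#' @rdname read_allele_db
#' @param db an [allele_group_db()] to serialize.
#' @export
write_allele_db <- function(db, path) {
  jsonlite::write_json(
    list(alleles = db$alleles, g_groups = db$g_groups,
         p_groups = db$p_groups, serology = db$serology, mac = db$mac,
         db_version = db$db_version),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

# --- parsing -----------------------------------------------------------------

.parse_hla_token <- function(tok, db) {
  tok <- gsub("[[:space:]]+", "", tok)
  had_prefix <- grepl("^HLA-", tok, ignore.case = TRUE)
  tok <- sub("^HLA-", "", tok, ignore.case = TRUE)
  if (grepl("^Bw\\d+$", tok))
    gn_unsupported_syntax(sprintf("epitope tokens are not normalized: %s", tok))
  if (!grepl("\\*", tok)) {
    m <- regmatches(tok, regexec("^([A-Za-z]+)(\\d+)$", tok))[[1]]
    if (!length(m))
      gn_parse_error(sprintf("cannot parse HLA token: %s", tok))
    return(list(hla_allele(m[2], m[3], serology = TRUE,
                           had_prefix = had_prefix)))
  }
  m <- regmatches(tok, regexec("^([A-Za-z0-9]+)\\*(.+)$", tok))[[1]]
  if (!length(m))
    gn_parse_error(sprintf("cannot parse HLA allele: %s", tok))
  locus <- m[2]
  fields <- strsplit(m[3], ":", fixed = TRUE)[[1]]
  # MAC code: an alphabetic second field compresses a list of completions
  if (length(fields) == 2L && grepl("^[A-Za-z]{2,}$", fields[2])) {
    key <- paste0(locus, "*", fields[1], ":", toupper(fields[2]))
    comp <- db$mac[[key]]
    if (is.null(comp))
      gn_unknown_mac(sprintf("unknown MAC code: %s", key))
    return(unlist(lapply(comp, .parse_hla_token, db = db),
                  recursive = FALSE))
  }
  suffix <- ""
  last <- fields[length(fields)]
  sm <- regmatches(last, regexec("^(\\d+)([A-Za-z])$", last))[[1]]
  if (length(sm)) {
    fields[length(fields)] <- sm[2]
    suffix <- toupper(sm[3])
  }
  if (!all(grepl("^\\d+$", fields)))
    gn_parse_error(sprintf("non-numeric HLA allele field in: %s", tok))
  list(hla_allele(locus, fields, suffix = suffix, had_prefix = had_prefix))
}

#' Parse an HLA input string
#'
#' Accepts a single allele (optional `HLA-` prefix, stray spaces tolerated),
#' a slash-delimited OR-list, a MAC code (alphabetic second field, expanded
#' through the database), or a serology token. Order is preserved and
#' duplicates are removed keeping the first occurrence. GL Strings and
#' epitope tokens are rejected with `gn_unsupported_syntax`; unknown MAC
#' codes with `gn_unknown_mac`.
#'
#' @param text HLA input string.
#' @param db an [allele_group_db()].
#' @return List of [hla_allele()]s.
#' @export
parse_hla_input <- function(text, db) {
  s <- gsub("[[:space:]]+", "", text)
  if (grepl("[#+^|~]", s))
    gn_unsupported_syntax("GL Strings are not parsed")
  toks <- strsplit(s, "/", fixed = TRUE)[[1]]
  if (!length(toks)) gn_parse_error("empty HLA input")
  alleles <- unlist(lapply(toks, .parse_hla_token, db = db),
                    recursive = FALSE)
  seen <- character(0); out <- list()
  for (a in alleles) {
    key <- format_hla(a)
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- a
  }
  out
}

# --- reduction ---------------------------------------------------------------

# Known alleles under an allele-name prefix ("DRB1*13:02" matches itself and
# anything below it).
.leaves <- function(name, db) {
  db$alleles[db$alleles == name | startsWith(db$alleles, paste0(name, ":"))]
}

# Numeric sort of allele names by their fields.
.sort_alleles <- function(x) {
  if (!length(x)) return(x)
  key <- vapply(x, function(s) {
    body <- sub("^[^*]+\\*", "", s)
    f <- strsplit(body, ":", fixed = TRUE)[[1]]
    paste(sprintf("%06d", as.integer(sub("[A-Za-z]$", "", f))),
          collapse = ":")
  }, "")
  x[order(key)]
}

.two_field <- function(name) {
  locus <- sub("\\*.*$", "", name)
  body <- sub("^[^*]+\\*", "", name)
  f <- strsplit(body, ":", fixed = TRUE)[[1]]
  if (length(f) <= 2L) return(name)
  paste0(locus, "*", f[1], ":", f[2])
}

.truncate_fields <- function(name, k) {
  locus <- sub("\\*.*$", "", name)
  body <- sub("^[^*]+\\*", "", name)
  f <- strsplit(body, ":", fixed = TRUE)[[1]]
  if (length(f) <= k) return(name)
  paste0(locus, "*", paste(f[seq_len(k)], collapse = ":"))
}

# Group (from a named member list) containing every known expansion of the
# allele; NULL when ungrouped, error when the allele is entirely unknown.
.containing_group <- function(name, db, groups, mandatory) {
  leaves <- .leaves(name, db)
  if (!length(leaves)) {
    if (mandatory)
      gn_unknown_allele(sprintf("allele is not in the database: %s", name))
    return(NULL)
  }
  hit <- names(groups)[vapply(groups, function(m) all(leaves %in% m), NA)]
  if (length(hit) == 1L) hit else NULL
}

.reduce_one <- function(a, mode, db) {
  if (a$serology) {
    if (mode == "S") return(paste0(a$locus, a$fields[1]))
    gn_unknown_allele(sprintf(
      "serology token %s cannot be reduced to %s", format_hla(a), mode))
  }
  name <- format_hla(a)
  bare <- format_hla(hla_allele(a$locus, a$fields))  # suffix-free lookups
  switch(mode,
    G = .containing_group(bare, db, db$g_groups, mandatory = TRUE) %||% name,
    P = .containing_group(bare, db, db$p_groups, mandatory = TRUE) %||% name,
    lgx = {
      grp <- .containing_group(bare, db, db$g_groups, mandatory = FALSE)
      if (!is.null(grp)) .two_field(sub("G$", "", grp))
      else .two_field(name)
    },
    lg = paste0(.reduce_one(a, "lgx", db), "g"),
    W = {
      leaves <- .leaves(bare, db)
      if (!length(leaves))
        gn_unknown_allele(sprintf("allele is not in the database: %s", name))
      .sort_alleles(leaves)
    },
    exon = {
      leaves <- .leaves(bare, db)
      if (!length(leaves))
        gn_unknown_allele(sprintf("allele is not in the database: %s", name))
      unique(vapply(.sort_alleles(leaves), .truncate_fields, "", k = 3L))
    },
    U2 = {
      tf <- .two_field(name)
      lgx <- .reduce_one(a, "lgx", db)
      if (identical(.two_field(tf), lgx)) tf else lgx
    },
    S = {
      lgx <- .reduce_one(a, "lgx", db)
      ant <- db$serology[[lgx]]
      if (is.null(ant))
        gn_unknown_allele(sprintf("no serology mapping for: %s", lgx))
      ant
    },
    gn_validation_error(sprintf("unknown reduction mode: %s", mode)))
}

#' Reduce HLA alleles to a normal form
#'
#' Per allele: `G`/`P` name the containing G/P group (else the allele
#' itself); `lgx` is the two-field ARD-level form (of the G-group
#' designation when grouped); `lg` appends a `g` marker to every lgx
#' component; `W` expands to all database alleles consistent with the input,
#' numerically sorted; `exon` gives the three-field expansions; `U2` the
#' two-field form when unambiguous, else lgx; `S` the serology antigens in
#' antigen-table order. Results are slash-joined with duplicates removed
#' preserving first occurrence.
#'
#' @param alleles list of [hla_allele()]s (see [parse_hla_input()]).
#' @param mode one of `"G"`, `"P"`, `"lg"`, `"lgx"`, `"W"`, `"exon"`,
#'   `"U2"`, `"S"`.
#' @param db an [allele_group_db()].
#' @return A slash-joined string.
#' @export
reduce_hla <- function(alleles, mode, db) {
  mode <- match.arg(mode, c("G", "P", "lg", "lgx", "W", "exon", "U2", "S"))
  parts <- unlist(lapply(alleles, .reduce_one, mode = mode, db = db))
  paste(parts[!duplicated(parts)], collapse = "/")
}

#' Normalize an HLA input to its canonical lgx form
#'
#' Parses (expanding MAC codes and OR-lists) and reduces to the two-field
#' ARD-level lgx string — the canonical form stored at ingestion and used
#' for matching. Idempotent.
#'
#' @inheritParams parse_hla_input
#' @return The lgx string.
#' @export
normalize_lgx <- function(text, db) {
  reduce_hla(parse_hla_input(text, db), "lgx", db)
}

#' All normal forms of an HLA input
#'
#' Utility reduction across every mode, keyed `G`, `P`, `lg`, `lgx`, `W`,
#' `exon`, `U2`, `S`.
#'
#' @inheritParams parse_hla_input
#' @return Named list of slash-joined strings.
#' @export
normalize_hla <- function(text, db) {
  alleles <- parse_hla_input(text, db)
  modes <- c("G", "P", "lg", "lgx", "W", "exon", "U2", "S")
  stats::setNames(lapply(modes, function(m) reduce_hla(alleles, m, db)),
                  modes)
}

#' Match an HLA query against a stored record
#'
#' True when the query is a case-insensitive substring of the record's raw
#' string, or when the query normalizes and its lgx components intersect
#' the record's stored lgx components. Normalization failure degrades to
#' substring-only matching; the search is total (never raises).
#'
#' @param query_text query string.
#' @param record list with elements `raw` (ingested string) and `lgx`
#'   (stored normalization, possibly `NA`).
#' @param db an [allele_group_db()].
#' @return `TRUE` or `FALSE`.
#' @export
hla_match <- function(query_text, record, db) {
  raw <- gsub("[[:space:]]+", "", record$raw %||% "")
  q <- gsub("[[:space:]]+", "", query_text)
  if (nzchar(q) && grepl(tolower(q), tolower(raw), fixed = TRUE))
    return(TRUE)
  qlgx <- tryCatch(normalize_lgx(query_text, db),
                   genonorm_error = function(e) NULL,
                   error = function(e) NULL)
  if (is.null(qlgx) || is.null(record$lgx) || is.na(record$lgx))
    return(FALSE)
  qc <- strsplit(qlgx, "/", fixed = TRUE)[[1]]
  rc <- strsplit(record$lgx, "/", fixed = TRUE)[[1]]
  length(intersect(qc, rc)) > 0
}
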