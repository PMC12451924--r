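# Normalize-at-ingestion store and the demonstrated query operations.
# Every stored entry keeps its raw form next to its normalization, and
# every query parameter goes through the same normalization as ingested
# data, so all spellings of a variant or HLA allele match the same records.
# The store is environment-backed (reference semantics, like a connection);
# a JSON snapshot provides persistence.

#' Patient/knowledge store
#'
#' @return An empty store of class `genomics_store`. Ingestion functions
#'   modify it in place (environment semantics) and return a per-item
#'   report.
#' @export
genomics_store <- function() {
  e <- new.env(parent = emptyenv())
  e$patients <- list()
  class(e) <- "genomics_store"
  e
}

#' @export
print.genomics_store <- function(x, ...) {
  cat("<genomics_store> ", length(x$patients), " subject(s)\n", sep = "")
  for (s in names(x$patients)) {
    p <- x$patients[[s]]
    cat(sprintf("  %s: %d variant(s), %d HLA entr%s\n", s,
                length(p$variants), length(p$hla),
                if (length(p$hla) == 1) "y" else "ies"))
  }
  invisible(x)
}

.ensure_subject <- function(store, subject) {
  if (is.null(store$patients[[subject]]))
    store$patients[[subject]] <- list(variants = list(), hla = list())
  invisible(store)
}

#' Ingest patient variants
#'
#' Each input string is normalized through [normalize_variant_bundle()];
#' the raw string is always stored, with a per-input status (`"ok"` or the
#' failure taxonomy label). Re-ingesting the same raw string is idempotent.
#'
#' @param store a [genomics_store()].
#' @param subject subject identifier.
#' @param inputs character vector of variant strings (HGVS or SPDI).
#' @param db an [alignment_db()].
#' @param catalog a [seq_catalog()].
#' @return Invisibly, a data frame report with columns `input`, `status`.
#' @export
ingest_patient_variants <- function(store, subject, inputs, db, catalog) {
  stopifnot(inherits(store, "genomics_store"))
  .ensure_subject(store, subject)
  report <- data.frame(input = character(0), status = character(0),
                       stringsAsFactors = FALSE)
  for (raw in inputs) {
    bundle <- tryCatch(normalize_variant_bundle(raw, db, catalog),
                       genonorm_error = function(e) e)
    if (inherits(bundle, "condition")) {
      status <- .reason(bundle)
      entry <- list(raw = raw, bundle = NULL, status = status)
    } else if (!is.na(bundle$failure)) {
      status <- bundle$failure
      entry <- list(raw = raw, bundle = bundle, status = status)
    } else {
      status <- "ok"
      entry <- list(raw = raw, bundle = bundle, status = status)
    }
    existing <- vapply(store$patients[[subject]]$variants,
                       function(x) x$raw, "")
    if (!raw %in% existing)
      store$patients[[subject]]$variants <-
        c(store$patients[[subject]]$variants, list(entry))
    report <- rbind(report, data.frame(input = raw, status = status,
                                       stringsAsFactors = FALSE))
  }
  invisible(report)
}

#' Ingest patient HLA alleles
#'
#' Analogous to [ingest_patient_variants()]; the canonical form is the lgx
#' reduction. Normalization failures store the raw string with a failure
#' status.
#'
#' @inheritParams ingest_patient_variants
#' @param inputs character vector of HLA strings.
#' @param db an [allele_group_db()].
#' @export
ingest_patient_hla <- function(store, subject, inputs, db) {
  stopifnot(inherits(store, "genomics_store"))
  .ensure_subject(store, subject)
  report <- data.frame(input = character(0), status = character(0),
                       stringsAsFactors = FALSE)
  for (raw in inputs) {
    lgx <- tryCatch(normalize_lgx(raw, db), genonorm_error = function(e) e)
    if (inherits(lgx, "condition")) {
      status <- .reason(lgx)
      entry <- list(raw = raw, lgx = NA_character_, status = status)
    } else {
      status <- "ok"
      entry <- list(raw = raw, lgx = lgx, status = status)
    }
    existing <- vapply(store$patients[[subject]]$hla, function(x) x$raw, "")
    if (!raw %in% existing)
      store$patients[[subject]]$hla <-
        c(store$patients[[subject]]$hla, list(entry))
    report <- rbind(report, data.frame(input = raw, status = status,
                                       stringsAsFactors = FALSE))
  }
  invisible(report)
}

#' Query a subject for specific variants
#'
#' Each query string is normalized like ingested data; the variant is
#' present iff its canonical SPDI (either build) intersects a stored
#' bundle's canonical SPDI. The response echoes the raw query, the
#' normalized fields, and presence; a query that fails normalization gets a
#' per-item error status while other items are still answered.
#'
#' @inheritParams ingest_patient_variants
#' @param variants character vector of query variant strings.
#' @return List of per-variant results: `raw`, `bundle` (or `NULL`),
#'   `status`, `present`.
#' @export
find_subject_specific_variants <- function(store, subject, variants, db,
                                           catalog) {
  stopifnot(inherits(store, "genomics_store"))
  p <- store$patients[[subject]]
  if (is.null(p))
    gn_not_found(sprintf("unknown subject: %s", subject))
  stored_keys <- unlist(lapply(p$variants, function(e)
    if (!is.null(e$bundle)) bundle_keys(e$bundle) else character(0)))
  lapply(variants, function(q) {
    bundle <- tryCatch(normalize_variant_bundle(q, db, catalog),
                       genonorm_error = function(e) e)
    if (inherits(bundle, "condition"))
      return(list(raw = q, bundle = NULL, status = .reason(bundle),
                  present = NA))
    keys <- bundle_keys(bundle)
    list(raw = q, bundle = bundle,
         status = if (length(keys)) "ok" else bundle$failure %||% "normalization failed",
         present = length(intersect(keys, stored_keys)) > 0)
  })
}

#' Population HLA haplotype counts
#'
#' Counts, per query haplotype string, the patients with at least one HLA
#' entry matched by [hla_match()]; optionally lists the matching subjects.
#'
#' @inheritParams ingest_patient_hla
#' @param haplotypes character vector of HLA query strings.
#' @param include_patient_list also return the subject ids.
#' @return List per haplotype: `query`, `count`, and `subjects` when
#'   requested.
#' @export
find_population_specific_haplotypes <- function(store, haplotypes,
                                                include_patient_list = FALSE,
                                                db) {
  stopifnot(inherits(store, "genomics_store"))
  lapply(haplotypes, function(q) {
    subs <- names(store$patients)[vapply(store$patients, function(p)
      any(vapply(p$hla, function(rec) hla_match(q, rec, db), NA)),
      NA)]
    out <- list(query = q, count = length(subs))
    if (include_patient_list) out$subjects <- subs
    out
  })
}

#' Knowledge entry
#'
#' A therapeutic-implication row keyed by canonical variant and coded
#' condition (optionally treatment).
#'
#' @param variant_key canonical fully justified SPDI string (preferred
#'   build); re-normalization must be the identity.
#' @param condition_system,condition_code coded condition.
#' @param treatment_system,treatment_code optional coded treatment.
#' @param implication free-text implication.
#' @return An object of class `knowledge_entry`.
#' @export
knowledge_entry <- function(variant_key, condition_system, condition_code,
                            treatment_system = NA_character_,
                            treatment_code = NA_character_,
                            implication = NA_character_) {
  structure(list(variant_key = variant_key,
                 condition = list(system = condition_system,
                                  code = as.character(condition_code)),
                 treatment = list(system = treatment_system,
                                  code = treatment_code),
                 implication = implication),
            class = "knowledge_entry")
}

#' Find therapeutic implications for a subject
#'
#' Condition codes are expanded through the concept-map registry toward
#' every target system it knows, then knowledge rows are returned whose
#' canonical variant key is present in the patient (and, when query
#' variants are given, in their canonical keys too) and whose condition is
#' in the expanded code set. A SNOMED-coded and a Disease-Ontology-coded
#' query over the same fixture therefore return identical rows.
#'
#' @inheritParams find_subject_specific_variants
#' @param knowledge list of [knowledge_entry()]s.
#' @param conditions data frame (or list) with columns `system`, `code`.
#' @param registry a [concept_map_registry()].
#' @return List of matching [knowledge_entry()]s.
#' @export
find_subject_tx_implications <- function(store, knowledge, subject,
                                         variants = NULL, conditions,
                                         registry, db, catalog) {
  stopifnot(inherits(store, "genomics_store"))
  p <- store$patients[[subject]]
  if (is.null(p))
    gn_not_found(sprintf("unknown subject: %s", subject))
  if (is.list(conditions) && !is.data.frame(conditions))
    conditions <- do.call(rbind, lapply(conditions, function(x)
      data.frame(system = x$system %||% x[[1]], code = x$code %||% x[[2]],
                 stringsAsFactors = FALSE)))
  targets <- unique(vapply(registry$maps, function(m) m$target_system, ""))
  expanded <- do.call(rbind, c(list(conditions[, c("system", "code")]),
    lapply(seq_len(nrow(conditions)), function(i)
      do.call(rbind, lapply(targets, function(tg)
        expand_query_codes(conditions$system[i], conditions$code[i],
                           registry, tg))))))
  expanded <- unique(expanded)
  patient_keys <- unlist(lapply(p$variants, function(e)
    if (!is.null(e$bundle)) bundle_keys(e$bundle) else character(0)))
  if (!is.null(variants)) {
    qkeys <- unlist(lapply(variants, function(v) {
      b <- tryCatch(normalize_variant_bundle(v, db, catalog),
                    genonorm_error = function(e) NULL)
      if (is.null(b)) character(0) else bundle_keys(b)
    }))
  } else qkeys <- NULL
  Filter(function(k) {
    cond_hit <- any(expanded$system == k$condition$system &
                    expanded$code == k$condition$code)
    var_hit <- k$variant_key %in% patient_keys &&
      (is.null(qkeys) || k$variant_key %in% qkeys)
    cond_hit && var_hit
  }, knowledge)
}

#' Snapshot / restore a store as JSON
#'
#' Raw strings, normalizations and statuses round-trip; bundles are stored
#' by their fields.
#'
#' @param store a [genomics_store()].
#' @param path JSON file path.
#' @export
write_store_snapshot <- function(store, path) {
  snap <- lapply(store$patients, function(p) list(
    variants = lapply(p$variants, function(e) list(
      raw = e$raw, status = e$status,
      fields = if (!is.null(e$bundle)) e$bundle$fields else NULL,
      field_status = if (!is.null(e$bundle)) e$bundle$status else NULL)),
    hla = p$hla))
  jsonlite::write_json(snap, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
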