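# The four-field normalized bundle {b37SPDI, b38SPDI, b37HGVS, b38HGVS}.
# Transcript-level inputs project to both builds' chromosomes; chromosome-
# level inputs keep their own build directly and reach the other build by
# projecting through a shared transcript; SPDI inputs are first converted
# to HGVS and then routed through the HGVS pipelines. Failures are recorded
# per field with their taxonomy label — never silent nulls.

BUNDLE_FIELDS <- c("b37SPDI", "b38SPDI", "b37HGVS", "b38HGVS")

# Map a build label onto a bundle slot prefix ("b37"/"b38").
.build_slot <- function(build) {
  if (grepl("37", build)) "b37"
  else if (grepl("38", build)) "b38"
  else NA_character_
}

.empty_bundle <- function(raw) {
  structure(list(raw = raw,
                 fields = stats::setNames(as.list(rep(NA_character_, 4)),
                                          BUNDLE_FIELDS),
                 status = stats::setNames(as.list(rep("not attempted", 4)),
                                          BUNDLE_FIELDS),
                 failure = NA_character_),
            class = "normalized_bundle")
}

.bundle_fail_all <- function(bundle, reason) {
  bundle$failure <- reason
  for (f in BUNDLE_FIELDS)
    if (identical(bundle$status[[f]], "not attempted"))
      bundle$status[[f]] <- reason
  bundle
}

.fail_slot <- function(bundle, slot, reason) {
  for (f in paste0(slot, c("SPDI", "HGVS")))
    bundle$status[[f]] <- reason
  bundle
}

.reason <- function(cnd) {
  paste0(gn_condition_label(cnd), ": ", conditionMessage(cnd))
}

# Emit both representations of a genomic variant into its build's slots.
.emit_genomic <- function(bundle, gv, catalog) {
  slot <- .build_slot(build_of(catalog, gv$accession))
  if (is.na(slot)) {
    return(bundle)  # fixture accession outside the two-build contract
  }
  sp <- tryCatch(hgvs_g_to_spdi(gv, catalog, justify = TRUE),
                 genonorm_error = function(e) e)
  f <- paste0(slot, "SPDI")
  if (inherits(sp, "condition")) {
    bundle$status[[f]] <- .reason(sp)
  } else {
    bundle$fields[[f]] <- format_spdi(sp)
    bundle$status[[f]] <- "ok"
  }
  f <- paste0(slot, "HGVS")
  hg <- tryCatch({
    src <- if (inherits(sp, "condition"))
      hgvs_g_to_spdi(gv, catalog, justify = FALSE) else sp
    format_hgvs(spdi_to_hgvs_g(src, catalog))
  }, genonorm_error = function(e) e)
  if (inherits(hg, "condition")) {
    bundle$status[[f]] <- .reason(hg)
  } else {
    bundle$fields[[f]] <- hg
    bundle$status[[f]] <- "ok"
  }
  bundle
}

# Transcript-level SPDI -> c. HGVS using the transcript's cds offset.
.transcript_spdi_to_c <- function(sp, aln) {
  sp <- trim_spdi(sp)
  if (is_identity_variant(sp))
    gn_validation_error("identity record cannot be normalized")
  p <- sp$position; cs <- aln$cds_start
  dlen <- nchar(sp$deleted); ilen <- nchar(sp$inserted)
  cpos <- function(i) cds_position(i - cs + 1)  # 0-based t index -> c. base
  if (dlen == 1 && ilen == 1)
    hgvs_c_variant(sp$sequence_id, "sub", cpos(p), cpos(p),
                   sp$deleted, sp$inserted)
  else if (dlen > 0 && ilen == 0)
    hgvs_c_variant(sp$sequence_id, "del", cpos(p), cpos(p + dlen - 1),
                   sp$deleted, "")
  else if (dlen == 0 && ilen > 0)
    hgvs_c_variant(sp$sequence_id, "ins", cpos(p - 1), cpos(p),
                   "", sp$inserted)
  else
    hgvs_c_variant(sp$sequence_id, "delins", cpos(p), cpos(p + dlen - 1),
                   sp$deleted, sp$inserted)
}

.route_transcript <- function(bundle, cv, db, catalog) {
  alns <- transcript_alignments(db, cv$accession)
  if (!length(alns))
    return(.bundle_fail_all(bundle, "transcript not in alignment database"))
  for (aln in alns) {
    slot <- .build_slot(aln$build)
    if (is.na(slot)) next
    gv <- tryCatch(project_c_to_g(cv, aln), genonorm_error = function(e) e)
    if (inherits(gv, "condition")) {
      bundle <- .fail_slot(bundle, slot, .reason(gv))
    } else {
      bundle <- .emit_genomic(bundle, gv, catalog)
    }
  }
  for (f in BUNDLE_FIELDS)
    if (identical(bundle$status[[f]], "not attempted"))
      bundle$status[[f]] <- "transcript has no alignment on this build"
  bundle
}

.route_chromosome <- function(bundle, gv, db, catalog) {
  b <- tryCatch(build_of(catalog, gv$accession),
                genonorm_error = function(e) e)
  if (inherits(b, "condition"))
    return(.bundle_fail_all(bundle, .reason(b)))
  slot_this <- .build_slot(b)
  if (is.na(slot_this))
    return(.bundle_fail_all(bundle, "accession is not on a 37/38 build"))
  bundle <- .emit_genomic(bundle, gv, catalog)
  slot_other <- setdiff(c("b37", "b38"), slot_this)
  aln_this <- tryCatch(select_transcript(gv, db),
                       genonorm_error = function(e) e)
  if (inherits(aln_this, "condition"))
    return(.fail_slot(bundle, slot_other, "no transcript alignment"))
  others <- Filter(function(a) identical(.build_slot(a$build), slot_other),
                   transcript_alignments(db, aln_this$transcript_accession))
  if (!length(others))
    return(.fail_slot(bundle, slot_other,
                      "transcript has no alignment on the other build"))
  res <- tryCatch({
    cv <- project_g_to_c(gv, aln_this)
    project_c_to_g(cv, others[[1]])
  }, genonorm_error = function(e) e)
  if (inherits(res, "condition"))
    return(.fail_slot(bundle, slot_other, .reason(res)))
  .emit_genomic(bundle, res, catalog)
}

#' Normalize a variant string into the four-field bundle
#'
#' Detects the input class (HGVS/SPDI x transcript/chromosome), routes it
#' through the matching pipeline, and emits the canonical fully justified
#' SPDI plus the right-rolled HGVS on both builds. Per-field failures carry
#' their taxonomy label; only a totally unparseable input raises.
#'
#' @param text variant string in HGVS or SPDI form.
#' @param db an [alignment_db()].
#' @param catalog a [seq_catalog()].
#' @return An object of class `normalized_bundle` with elements `raw`,
#'   `fields` (named `b37SPDI`, `b38SPDI`, `b37HGVS`, `b38HGVS`), `status`
#'   (per-field `"ok"` or failure reason), and `failure` (overall reason or
#'   `NA`).
#' @export
normalize_variant_bundle <- function(text, db, catalog) {
  fmt <- detect_format(text)
  bundle <- .empty_bundle(text)
  if (fmt$syntax == "HGVS") {
    v <- parse_hgvs(text)
    if (inherits(v, "hgvs_c_variant"))
      return(.route_transcript(bundle, v, db, catalog))
    return(.route_chromosome(bundle, v, db, catalog))
  }
  sp <- parse_spdi(text)
  if (fmt$level == "transcript") {
    alns <- transcript_alignments(db, sp$sequence_id)
    if (!length(alns))
      return(.bundle_fail_all(bundle, "transcript not in alignment database"))
    cv <- tryCatch(.transcript_spdi_to_c(sp, alns[[1]]),
                   genonorm_error = function(e) e)
    if (inherits(cv, "condition"))
      return(.bundle_fail_all(bundle, .reason(cv)))
    return(.route_transcript(bundle, cv, db, catalog))
  }
  gv <- tryCatch(spdi_to_hgvs_g(sp, catalog), genonorm_error = function(e) e)
  if (inherits(gv, "condition"))
    return(.bundle_fail_all(bundle, .reason(gv)))
  .route_chromosome(bundle, gv, db, catalog)
}

#' @export
print.normalized_bundle <- function(x, ...) {
  cat("<normalized_bundle> ", x$raw, "\n", sep = "")
  for (f in BUNDLE_FIELDS) {
    val <- if (identical(x$status[[f]], "ok")) x$fields[[f]]
           else paste0("<", x$status[[f]], ">")
    cat(sprintf("  %s: %s\n", f, val))
  }
  invisible(x)
}

#' Canonical SPDI keys of a bundle
#'
#' The canonical SPDI strings of the fields that normalized successfully
#' (used as matching keys by the query layer).
#'
#' @param bundle a `normalized_bundle`.
#' @return Character vector (possibly empty).
#' @export
bundle_keys <- function(bundle) {
  stopifnot(inherits(bundle, "normalized_bundle"))
  keys <- character(0)
  for (f in c("b38SPDI", "b37SPDI"))
    if (identical(bundle$status[[f]], "ok"))
      keys <- c(keys, bundle$fields[[f]])
  keys
}

#' Serialize a bundle as JSON
#'
#' Emits an object with keys exactly `b37SPDI`, `b38SPDI`, `b37HGVS`,
#' `b38HGVS` plus `raw` and per-field `status`.
#'
#' @param bundle a `normalized_bundle`.
#' @param pretty pretty-print.
#' @return A JSON string.
#' @export
bundle_to_json <- function(bundle, pretty = TRUE) {
  obj <- bundle$fields
  obj$raw <- bundle$raw
  obj$status <- bundle$status
  jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = pretty, null = "null",
                   na = "null")
}
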