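# ConceptMap-based exact-match terminology translation. Each map is a
# function from source code to at most one (target code, display) pair —
# a source code never fans out within one target system. Query expansion
# appends the translated code and always retains the submitted one, so
# translation can only widen a search.

#' Concept map
#'
#' @param source_system,target_system canonical system URIs (exact strings,
#'   no URI canonicalization).
#' @param entries data frame with columns `code`, `target`, `display`.
#' @param id,version map identity metadata.
#' @return An object of class `concept_map`.
#' @export
concept_map <- function(source_system, target_system, entries,
                        id = NA_character_, version = NA_character_) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  stopifnot(all(c("code", "target", "display") %in% names(entries)))
  entries$code <- as.character(entries$code)
  if (anyDuplicated(entries$code))
    gn_schema_error(sprintf(
      "duplicate source code in map %s -> %s: %s", source_system,
      target_system, entries$code[duplicated(entries$code)][1]))
  structure(list(source_system = source_system,
                 target_system = target_system, entries = entries,
                 id = id, version = version),
            class = "concept_map")
}

#' Concept-map registry
#'
#' @param maps list of [concept_map()]s; at most one per
#'   (source system, target system) pair.
#' @return An object of class `concept_map_registry`.
#' @export
concept_map_registry <- function(maps = list()) {
  for (m in maps) stopifnot(inherits(m, "concept_map"))
  keys <- vapply(maps, function(m)
    paste(m$source_system, m$target_system, sep = " -> "), "")
  if (anyDuplicated(keys))
    gn_schema_error("duplicate (source, target) concept map")
  structure(list(maps = stats::setNames(maps, keys)), class = "concept_map_registry")
}

#' @export
print.concept_map_registry <- function(x, ...) {
  cat("<concept_map_registry> ", length(x$maps), " map(s)\n", sep = "")
  for (k in names(x$maps))
    cat("  ", k, " (", nrow(x$maps[[k]]$entries), " entries)\n", sep = "")
  invisible(x)
}

#' Load concept maps from JSON
#'
#' FHIR-ConceptMap-inspired subset: a JSON array of maps, each with `id`,
#' `version` and `group` entries carrying `source`, `target` and
#' `element[].code -> target[].code/display`. The functional invariant
#' (one target per source code) is enforced at load; an empty file yields
#' an empty registry.
#'
#' @param path JSON file path.
#' @return A [concept_map_registry()].
#' @export
load_concept_maps <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (!nzchar(trimws(txt))) return(concept_map_registry())
  recs <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  maps <- list()
  for (r in recs) {
    for (g in r$group) {
      entries <- do.call(rbind, lapply(g$element, function(el) {
        tg <- el$target[[1]]
        data.frame(code = el$code, target = tg$code,
                   display = tg$display %||% NA_character_,
                   stringsAsFactors = FALSE)
      }))
      maps[[length(maps) + 1L]] <- concept_map(
        g$source, g$target, entries,
        id = r$id %||% NA_character_, version = r$version %||% NA_character_)
    }
  }
  concept_map_registry(maps)
}

#' Write a registry back to the ConceptMap JSON subset
#'
#' @param registry a [concept_map_registry()].
#' @param path output file.
#' @export
write_concept_maps <- function(registry, path) {
  recs <- lapply(registry$maps, function(m) {
    list(id = m$id, version = m$version,
         group = list(list(
           source = m$source_system, target = m$target_system,
           element = lapply(seq_len(nrow(m$entries)), function(i)
             list(code = m$entries$code[i],
                  target = list(list(code = m$entries$target[i],
                                     display = m$entries$display[i])))))))
  })
  jsonlite::write_json(unname(recs), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Translate a code into every mapped target system
#'
#' For each target system reachable from `system`, returns a
#' `"match found"` outcome with the target code and display, or a
#' `"no match found"` outcome naming only the system. Target systems are
#' visited in alphabetical order; an unknown source system yields an empty
#' list. Total: never raises.
#'
#' @param system source system URI.
#' @param code source code.
#' @param registry a [concept_map_registry()].
#' @param strip_spaces normalize internal spaces out of target codes (codes
#'   are otherwise returned verbatim as stored, e.g. `"DOID : 3908"`).
#' @return List of outcome lists with fields `outcome`, `system` and, on a
#'   match, `code` and `display`.
#' @export
translate <- function(system, code, registry, strip_spaces = FALSE) {
  stopifnot(inherits(registry, "concept_map_registry"))
  maps <- Filter(function(m) m$source_system == system, registry$maps)
  if (!length(maps)) return(list())
  targets <- vapply(maps, function(m) m$target_system, "")
  maps <- unname(maps[order(targets)])
  lapply(maps, function(m) {
    i <- match(as.character(code), m$entries$code)
    if (is.na(i))
      return(list(outcome = "no match found", system = m$target_system))
    tgt <- m$entries$target[i]
    if (strip_spaces) tgt <- gsub("[[:space:]]+", "", tgt)
    list(outcome = "match found", system = m$target_system, code = tgt,
         display = m$entries$display[i])
  })
}

#' Expand a query code through terminology translation
#'
#' Search pseudologic for condition/treatment parameters: when the
#' submitted code's system has concept maps and an exact translation toward
#' `target_system` exists, the translated code is appended; the submitted
#' code is always retained first, so expansion never loses recall.
#'
#' @inheritParams translate
#' @param target_system target system URI to translate toward.
#' @return Data frame with columns `system`, `code` (original first).
#' @export
expand_query_codes <- function(system, code, registry, target_system) {
  out <- data.frame(system = system, code = as.character(code),
                    stringsAsFactors = FALSE)
  key <- paste(system, target_system, sep = " -> ")
  m <- registry$maps[[key]]
  if (is.null(m)) return(out)
  i <- match(as.character(code), m$entries$code)
  if (is.na(i)) return(out)
  rbind(out, data.frame(system = target_system, code = m$entries$target[i],
                        stringsAsFactors = FALSE))
}
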