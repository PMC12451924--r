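# Structured error conditions. Every failure the pipelines can produce has a
# distinct condition class so callers (and the ingestion layer) can record a
# failure taxonomy instead of matching on message text. All classes inherit
# from "genonorm_error".

gn_stop <- function(class, message, ..., data = NULL) {
  cnd <- errorCondition(message, data = data,
                        class = c(class, "genonorm_error", "error"))
  stop(cnd)
}

gn_parse_error            <- function(msg, ...) gn_stop("gn_parse_error", msg, ...)
gn_format_error           <- function(msg, ...) gn_stop("gn_format_error", msg, ...)
gn_validation_error       <- function(msg, ...) gn_stop("gn_validation_error", msg, ...)
gn_registration_error     <- function(msg, ...) gn_stop("gn_registration_error", msg, ...)
gn_coverage_error         <- function(msg, ...) gn_stop("gn_coverage_error", msg, ...)
gn_not_found              <- function(msg, ...) gn_stop("gn_not_found", msg, ...)
gn_unsupported_reference  <- function(msg, ...) gn_stop("gn_unsupported_reference", msg, ...)
gn_unsupported_syntax     <- function(msg, ...) gn_stop("gn_unsupported_syntax", msg, ...)
gn_reference_disagreement <- function(msg, ...) gn_stop("gn_reference_disagreement", msg, ...)
gn_ambiguous_context      <- function(msg, ...) gn_stop("gn_ambiguous_context", msg, ...)
gn_projection_gap         <- function(msg, ...) gn_stop("gn_projection_gap", msg, ...)
gn_junction_unsupported   <- function(msg, ...) gn_stop("gn_junction_unsupported", msg, ...)
gn_no_transcript          <- function(msg, ...) gn_stop("gn_no_transcript", msg, ...)
gn_out_of_transcript      <- function(msg, ...) gn_stop("gn_out_of_transcript", msg, ...)
gn_unknown_mac            <- function(msg, ...) gn_stop("gn_unknown_mac", msg, ...)
gn_unknown_allele         <- function(msg, ...) gn_stop("gn_unknown_allele", msg, ...)
gn_schema_error           <- function(msg, ...) gn_stop("gn_schema_error", msg, ...)

# First genonorm-specific class of a caught condition; used in ingestion
# reports so failures keep their taxonomy label.
gn_condition_label <- function(cnd) {
  cls <- class(cnd)
  own <- cls[startsWith(cls, "gn_")]
  if (length(own)) own[[1]] else "error"
}
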