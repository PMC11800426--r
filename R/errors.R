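# Condition constructors. Every user-facing failure is a classed condition so
# callers (and the CLI exit-code mapping) can react to the class, not the text.

omi_error <- function(class, message, ...) {
  stop(structure(
    class = c(class, "omi_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

omi_config_error    <- function(msg, ...) omi_error("omi_config_error", msg, ...)
omi_storage_error   <- function(msg, ...) omi_error("omi_storage_error", msg, ...)
omi_schema_error    <- function(msg, ...) omi_error("omi_schema_error", msg, ...)
omi_naming_error    <- function(msg, ...) omi_error(c("omi_naming_error", "omi_schema_error"), msg, ...)
omi_duplicate_error <- function(msg, ...) omi_error("omi_duplicate_error", msg, ...)
omi_not_found_error <- function(msg, ...) omi_error("omi_not_found_error", msg, ...)
omi_alignment_error <- function(msg, ...) omi_error("omi_alignment_error", msg, ...)
omi_append_error    <- function(msg, ...) omi_error(c("omi_append_error", "omi_schema_error"), msg, ...)
omi_query_error     <- function(msg, ...) omi_error("omi_query_error", msg, ...)
omi_join_error      <- function(msg, ...) omi_error("omi_join_error", msg, ...)
omi_parse_error     <- function(msg, ...) omi_error("omi_parse_error", msg, ...)
omi_ingest_error    <- function(msg, ...) omi_error("omi_ingest_error", msg, ...)
omi_spec_error      <- function(msg, ...) omi_error("omi_spec_error", msg, ...)
omi_io_error        <- function(msg, ...) omi_error("omi_io_error", msg, ...)
omi_bench_error     <- function(msg, ...) omi_error("omi_bench_error", msg, ...)

# Debug-level transaction log, silent unless options(omistack.log = TRUE)
# (or log level "debug" set through the CLI).
log_debug <- function(...) {
  if (isTRUE(getOption("omistack.log", FALSE))) {
    message("[omistack] ", sprintf(...))
  }
  invisible(NULL)
}
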