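# Internal helpers: classified conditions, logging, seeded evaluation.

#' @importFrom withr with_seed
NULL

# Classified errors. Every user-facing failure carries a short machine-readable
# category ("format", "validation", "hierarchy", "gene_overlap", "columns",
# "runtime") so the CLI can map it to an exit code and a one-line message.
stop_sctyper <- function(msg, category, class) {
  cond <- structure(
    class = c(class, "sctyper_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), category = category)
  )
  stop(cond)
}

stop_validation <- function(msg, category = "validation") {
  stop_sctyper(msg, category, "sctyper_validation_error")
}

stop_format <- function(msg, category = "format") {
  stop_sctyper(msg, category, "sctyper_format_error")
}

# Log to stderr; results never go through here.
st_log <- function(...) {
  message("[sctyper] ", ...)
}

# Derive a secondary seed from a base seed, kept inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(offset)) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_number <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_validation(sprintf("'%s' must be a single finite number", name))
  }
  if (positive && x <= 0) {
    stop_validation(sprintf("'%s' must be > 0", name))
  }
  invisible(x)
}
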