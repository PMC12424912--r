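# Classified error conditions.
#
# Every failure raised by the package carries class
# c("clarid_<kind>_error", "clarid_error", ...) so callers (the batch
# processor, the CLI, tests) can branch on the kind of failure without
# string-matching messages.

clarid_abort <- function(kind, message, ...) {
  rlang::abort(
    message,
    class = c(paste0("clarid_", kind, "_error"), "clarid_error"),
    ...
  )
}

abort_io         <- function(msg, ...) clarid_abort("io", msg, ...)
abort_parse      <- function(msg, ...) clarid_abort("parse", msg, ...)
abort_validation <- function(msg, ...) clarid_abort("validation", msg, ...)
abort_vocabulary <- function(msg, ...) clarid_abort("vocabulary", msg, ...)
abort_decode     <- function(msg, ...) clarid_abort("decode", msg, ...)
abort_structure  <- function(msg, ...) clarid_abort("structure", msg, ...)
abort_range      <- function(msg, ...) clarid_abort("range", msg, ...)
abort_format     <- function(msg, ...) clarid_abort("format", msg, ...)
abort_overflow   <- function(msg, ...) clarid_abort("overflow", msg, ...)
abort_lookup     <- function(msg, ...) clarid_abort("lookup", msg, ...)
abort_config     <- function(msg, ...) clarid_abort("config", msg, ...)
abort_qr         <- function(msg, ...) clarid_abort("qr", msg, ...)

#' Is a condition a claridr error?
#'
#' All errors signalled by claridr inherit from class `"clarid_error"`,
#' with a more specific first class naming the failure kind (for example
#' `"clarid_vocabulary_error"` for an unknown codebook term or
#' `"clarid_structure_error"` for a malformed identifier).
#'
#' @param x An object, typically caught with [tryCatch()].
#' @return `TRUE` if `x` is a condition raised by claridr.
#' @export
is_clarid_error <- function(x) inherits(x, "clarid_error")
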