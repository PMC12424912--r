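# JSON Schema validation (draft 2020-12 subset).
#
# The codebook schema only needs a small, well-defined keyword set:
# type, required, properties, additionalProperties, patternProperties,
# pattern, minLength, enum, items, and local "$ref"s into "$defs".
# The validator below implements exactly that subset and reports every
# violation with a JSON-Pointer-like path into the document.

schema_is_object <- function(x) is.list(x) && (length(x) == 0L || !is.null(names(x)))
schema_is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

schema_type_ok <- function(x, type) {
  switch(type,
    object  = schema_is_object(x),
    array   = is.list(x) && is.null(names(x)),
    string  = schema_is_string(x),
    number  = is.numeric(x) && length(x) == 1L,
    integer = is.numeric(x) && length(x) == 1L && x == floor(x),
    boolean = is.logical(x) && length(x) == 1L,
    null    = is.null(x),
    TRUE
  )
}

resolve_ref <- function(ref, root) {
  if (!grepl("^#(/|$)", ref)) {
    abort_config(sprintf("only local '#/...' schema references are supported, not '%s'", ref))
  }
  keys <- strsplit(sub("^#/?", "", ref), "/", fixed = TRUE)[[1L]]
  node <- root
  for (k in keys) {
    k <- gsub("~1", "/", gsub("~0", "~", k, fixed = TRUE), fixed = TRUE)
    node <- node[[k]]
    if (is.null(node)) abort_config(sprintf("unresolvable schema reference '%s'", ref))
  }
  node
}

validate_schema_node <- function(x, schema, path, root) {
  findings <- list()
  note <- function(message) {
    findings[[length(findings) + 1L]] <<- tibble::tibble(
      severity = "error", path = path, message = message
    )
  }
  if (isTRUE(schema)) return(NULL)
  if (isFALSE(schema)) {
    note("schema forbids this location")
    return(dplyr::bind_rows(findings))
  }
  if (!is.null(schema[["$ref"]])) {
    schema <- resolve_ref(schema[["$ref"]], root)
  }
  if (!is.null(schema$type)) {
    types <- unlist(schema$type)
    if (!any(vapply(types, schema_type_ok, logical(1), x = x))) {
      note(sprintf("expected type %s", paste(types, collapse = " or ")))
      return(dplyr::bind_rows(findings))
    }
  }
  if (!is.null(schema$enum)) {
    if (!any(vapply(schema$enum, identical, logical(1), y = x))) {
      note("value is not one of the allowed values")
    }
  }
  if (schema_is_string(x)) {
    if (!is.null(schema$minLength) && nchar(x) < schema$minLength) {
      note(sprintf("string shorter than minLength %d", schema$minLength))
    }
    if (!is.null(schema$pattern) && !grepl(schema$pattern, x, perl = TRUE)) {
      note(sprintf("string '%s' does not match pattern '%s'", x, schema$pattern))
    }
  }
  if (schema_is_object(x)) {
    for (req in unlist(schema$required)) {
      if (!req %in% names(x)) note(sprintf("required property '%s' is missing", req))
    }
    for (key in names(x)) {
      child_path <- paste(path, key, sep = ".")
      matched <- FALSE
      if (!is.null(schema$properties) && key %in% names(schema$properties)) {
        matched <- TRUE
        findings[[length(findings) + 1L]] <-
          validate_schema_node(x[[key]], schema$properties[[key]], child_path, root)
      }
      for (pat in names(schema$patternProperties %||% list())) {
        if (grepl(pat, key, perl = TRUE)) {
          matched <- TRUE
          findings[[length(findings) + 1L]] <-
            validate_schema_node(x[[key]], schema$patternProperties[[pat]], child_path, root)
        }
      }
      if (!matched && !is.null(schema$additionalProperties)) {
        ap <- schema$additionalProperties
        if (isFALSE(ap)) {
          findings[[length(findings) + 1L]] <- tibble::tibble(
            severity = "error", path = child_path,
            message = "additional property not allowed"
          )
        } else if (!isTRUE(ap)) {
          findings[[length(findings) + 1L]] <-
            validate_schema_node(x[[key]], ap, child_path, root)
        }
      }
    }
  }
  if (is.list(x) && is.null(names(x)) && !is.null(schema$items)) {
    for (i in seq_along(x)) {
      findings[[length(findings) + 1L]] <-
        validate_schema_node(x[[i]], schema$items, paste0(path, "[", i, "]"), root)
    }
  }
  dplyr::bind_rows(findings)
}

#' Validate a codebook YAML file against the ClarID JSON Schema
#'
#' Checks the document twice: first against the JSON Schema (structure,
#' required keys, string patterns — a hyphen in a `code`, a missing
#' `stub_code`), then against the ClarID-specific invariants the schema
#' cannot express (uniqueness of codes and stub codes within a
#' component, fixed stub widths, valid rule regexes). All findings are
#' collected into a single report; nothing is thrown for codebook
#' defects. Unknown keys are reported as warnings, not errors, since the
#' codebook is user-extensible.
#'
#' @param cb_path Path to the codebook YAML (default: bundled codebook).
#' @param schema_path Path to the JSON Schema (default: bundled schema).
#' @return A `clarid_validation` report: `valid` (no error-severity
#'   findings) plus a `findings` tibble with `severity`, `path`,
#'   `message`.
#' @examples
#' report <- validate_codebook()
#' report$valid
#' @export
validate_codebook <- function(cb_path = clarid_example("clarid-codebook.yaml"),
                              schema_path = clarid_example("clarid-codebook-schema.json")) {
  if (!file.exists(schema_path)) {
    abort_config(sprintf("schema file '%s' does not exist", schema_path))
  }
  schema <- tryCatch(
    jsonlite::fromJSON(schema_path, simplifyVector = FALSE),
    error = function(e) abort_config(sprintf(
      "schema '%s' is not valid JSON: %s", schema_path, conditionMessage(e)
    ))
  )
  if (!schema_is_object(schema)) {
    abort_config(sprintf("schema '%s' is not a JSON Schema object", schema_path))
  }
  if (!file.exists(cb_path)) {
    abort_io(sprintf("codebook file '%s' does not exist", cb_path))
  }
  raw <- tryCatch(
    yaml::read_yaml(cb_path),
    error = function(e) abort_parse(sprintf(
      "cannot parse YAML in '%s': %s", cb_path, conditionMessage(e)
    ))
  )
  findings <- dplyr::bind_rows(
    validate_schema_node(raw, schema, "$", schema),
    codebook_findings(raw)
  )
  findings <- dplyr::distinct(findings)
  if (nrow(findings) == 0L) {
    findings <- tibble::tibble(severity = character(0), path = character(0), message = character(0))
  }
  structure(
    list(valid = !any(findings$severity == "error"), findings = findings, path = cb_path),
    class = "clarid_validation"
  )
}

#' @export
print.clarid_validation <- function(x, ...) {
  cat("<clarid_validation>", x$path, "\n")
  cat("  valid:", x$valid, "\n")
  if (nrow(x$findings) > 0L) {
    apply(x$findings, 1L, function(row) {
      cat(sprintf("  %s [%s] %s\n", row[["severity"]], row[["path"]], row[["message"]]))
    })
  } else {
    cat("  no findings\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a codebook validation report
#'
#' @param x A `clarid_validation` report.
#' @param ... Unused.
#' @return `tidy()`: the findings as a tibble (`severity`, `path`,
#'   `message`); `glance()`: a one-row summary with `valid` and finding
#'   counts.
#' @method tidy clarid_validation
#' @export
tidy.clarid_validation <- function(x, ...) x$findings

#' @rdname tidy.clarid_validation
#' @method glance clarid_validation
#' @export
glance.clarid_validation <- function(x, ...) {
  tibble::tibble(
    valid = x$valid,
    n_findings = nrow(x$findings),
    n_errors = sum(x$findings$severity == "error"),
    n_warnings = sum(x$findings$severity == "warning")
  )
}
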