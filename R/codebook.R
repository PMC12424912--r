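#' Load a ClarID codebook
#'
#' Reads a YAML codebook defining, per entity (`biosample`, `subject`) and
#' component (`project`, `species`, `tissue`, ...), the controlled terms
#' with their human-format `code`, compact `stub_code`, display `label`
#' and ontology CURIE `id`. Rule-based components (`subject_id`,
#' `duration`, `batch`, `replicate`, `condition`) are defined by regular
#' expressions under a `rules` section; built-in defaults apply when the
#' section is absent.
#'
#' The loader enforces the structural invariants identifiers depend on:
#' within one (entity, component) all terms, `code`s and `stub_code`s are
#' unique; `code`s contain no hyphen (the human-format delimiter); and
#' `stub_code`s of fixed-width components have the declared width
#' (species 2; tissue, sample type, assay, timepoint, subject type and
#' sex 1; age group 2). Project and study stub codes are variable-length.
#' Violations raise a validation error naming the offending path; use
#' [validate_codebook()] for a non-throwing report.
#'
#' @param path Path to the YAML codebook. Defaults to the bundled example
#'   codebook shipped with the package.
#' @return A `clarid_codebook` object: the entity/component/term map plus
#'   a `lookup` tibble (one row per term) and the compiled component rules.
#' @examples
#' cb <- load_codebook()
#' resolve_term(cb, "biosample", "tissue", "Liver")$code
#' @export
load_codebook <- function(path = clarid_example("clarid-codebook.yaml")) {
  if (!file.exists(path)) {
    abort_io(sprintf("codebook file '%s' does not exist", path))
  }
  raw <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) abort_parse(sprintf("cannot parse YAML in '%s': %s", path, conditionMessage(e)))
  )
  findings <- codebook_findings(raw)
  errors <- findings[findings$severity == "error", , drop = FALSE]
  if (nrow(errors) > 0L) {
    abort_validation(paste0(
      "invalid codebook:\n",
      paste0("  [", errors$path, "] ", errors$message, collapse = "\n")
    ))
  }
  new_codebook(raw, path)
}

#' Path to a bundled claridr data file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   arguments, lists the available files.
#' @return A file path (or a vector of file names).
#' @export
clarid_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "claridr")))
  }
  path <- system.file("extdata", file, package = "claridr")
  if (identical(path, "")) {
    abort_io(sprintf("no bundled file '%s'", file))
  }
  path
}

# Required vocabulary components per entity, and fixed stub widths.
.required_components <- list(
  biosample = c("project", "species", "tissue", "sample_type", "assay", "timepoint"),
  subject   = c("type", "sex", "age_group")
)

.stub_widths <- list(
  biosample = c(species = 2L, tissue = 1L, sample_type = 1L, assay = 1L, timepoint = 1L),
  subject   = c(type = 1L, sex = 1L, age_group = 2L)
)

.default_rules <- c(
  subject_id = "^[0-9]{1,5}$",
  duration   = "^P([0-9][DWMY]|0N)$",
  batch      = "^[1-9][0-9]?$",
  replicate  = "^[1-9][0-9]?$",
  condition  = "^([A-Z][0-9]{2}(\\.[0-9]{1,2})?|NA)$"
)

trim <- function(x) if (is.character(x)) trimws(x) else x

# Collect structural findings on the parsed YAML without throwing.
# Returns a tibble(severity, path, message); severity "error" or "warning".
codebook_findings <- function(raw) {
  f <- list()
  note <- function(severity, path, message) {
    f[[length(f) + 1L]] <<- tibble::tibble(severity = severity, path = path, message = message)
  }
  if (!is.list(raw) || is.null(names(raw))) {
    note("error", "(root)", "missing entity sections: document is not a mapping")
    return(dplyr::bind_rows(f))
  }
  for (entity in c("biosample", "subject")) {
    if (is.null(raw[[entity]])) {
      note("error", entity, sprintf("missing entity section '%s'", entity))
      next
    }
    comps <- raw[[entity]]
    if (!is.list(comps) || is.null(names(comps))) {
      note("error", entity, "entity section is not a mapping of components")
      next
    }
    for (req in .required_components[[entity]]) {
      if (is.null(comps[[req]])) {
        note("error", paste(entity, req, sep = "."), "required component missing")
      }
    }
    for (comp in names(comps)) {
      cpath <- paste(entity, comp, sep = ".")
      terms <- comps[[comp]]
      if (!is.list(terms) || is.null(names(terms)) || length(terms) == 0L) {
        note("error", cpath, "component is not a non-empty mapping of terms")
        next
      }
      codes <- character(0)
      stubs <- character(0)
      width <- if (comp %in% names(.stub_widths[[entity]])) .stub_widths[[entity]][[comp]] else NULL
      for (term in names(terms)) {
        tpath <- paste(cpath, term, sep = ".")
        entry <- terms[[term]]
        if (!is.list(entry)) {
          note("error", tpath, "term entry is not a mapping")
          next
        }
        code <- trim(entry$code)
        stub <- trim(as.character(entry$stub_code %||% character(0)))
        if (is.null(code) || !nzchar(code %||% "")) {
          note("error", tpath, "missing or empty 'code'")
        } else {
          if (grepl("-", code, fixed = TRUE)) {
            note("error", tpath, sprintf("code '%s' contains a hyphen (reserved delimiter)", code))
          }
          codes <- c(codes, code)
        }
        if (length(stub) == 0L || !nzchar(stub)) {
          note("error", tpath, "missing or empty 'stub_code'")
        } else {
          if (!is.null(width) && nchar(stub) != width) {
            note("error", tpath, sprintf(
              "stub_code '%s' has width %d; component '%s' requires width %d",
              stub, nchar(stub), comp, width
            ))
          }
          stubs <- c(stubs, stub)
        }
        id <- trim(entry$id)
        if (!is.null(id) && !grepl("^[A-Za-z][A-Za-z0-9_.]*:[^ ]+$", id)) {
          note("warning", tpath, sprintf("'id' (%s) is not a CURIE of the form prefix:reference", id))
        }
        known <- c("code", "stub_code", "label", "id", "tax_code")
        extra <- setdiff(names(entry), known)
        if (length(extra) > 0L) {
          note("warning", tpath, paste0("unknown key(s): ", paste(extra, collapse = ", ")))
        }
      }
      dup_c <- unique(codes[duplicated(codes)])
      if (length(dup_c) > 0L) {
        note("error", cpath, paste0("duplicate code(s): ", paste(dup_c, collapse = ", ")))
      }
      dup_s <- unique(stubs[duplicated(stubs)])
      if (length(dup_s) > 0L) {
        note("error", cpath, paste0("duplicate stub_code(s): ", paste(dup_s, collapse = ", ")))
      }
    }
  }
  if (!is.null(raw$rules)) {
    for (rule in names(raw$rules)) {
      pat <- raw$rules[[rule]]
      ok <- is.character(pat) && length(pat) == 1L &&
        !inherits(tryCatch(grepl(pat, ""), error = identity, warning = identity), c("error", "warning"))
      if (!ok) note("error", paste0("rules.", rule), "rule is not a valid regular expression")
    }
  }
  extra_top <- setdiff(names(raw), c("biosample", "subject", "rules"))
  if (length(extra_top) > 0L) {
    f[[length(f) + 1L]] <- tibble::tibble(
      severity = "warning", path = "(root)",
      message = paste0("unknown top-level key(s): ", paste(extra_top, collapse = ", "))
    )
  }
  out <- dplyr::bind_rows(f)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(severity = character(0), path = character(0), message = character(0))
  }
  out
}

new_codebook <- function(raw, path) {
  rows <- list()
  for (entity in c("biosample", "subject")) {
    for (comp in names(raw[[entity]])) {
      terms <- raw[[entity]][[comp]]
      for (term in names(terms)) {
        e <- terms[[term]]
        rows[[length(rows) + 1L]] <- tibble::tibble(
          entity    = entity,
          component = comp,
          term      = trimws(term),
          code      = trimws(e$code),
          stub_code = trimws(as.character(e$stub_code)),
          label     = trimws(e$label %||% NA_character_),
          id        = trimws(e$id %||% NA_character_),
          tax_code  = trimws(e$tax_code %||% NA_character_)
        )
      }
    }
  }
  rules <- .default_rules
  for (r in names(raw$rules)) rules[[r]] <- raw$rules[[r]]
  structure(
    list(
      entities = raw[c("biosample", "subject")],
      rules = rules,
      lookup = dplyr::bind_rows(rows),
      path = path
    ),
    class = "clarid_codebook"
  )
}

#' @export
print.clarid_codebook <- function(x, ...) {
  cat("<clarid_codebook>", x$path, "\n")
  summ <- dplyr::count(x$lookup, .data$entity, .data$component)
  for (entity in unique(summ$entity)) {
    rows <- summ[summ$entity == entity, ]
    cat(" ", entity, ": ",
        paste0(rows$component, " (", rows$n, ")", collapse = ", "), "\n", sep = "")
  }
  cat("  rules: ", paste(names(x$rules), collapse = ", "), "\n", sep = "")
  invisible(x)
}

check_entity <- function(cb, entity) {
  if (!entity %in% c("biosample", "subject")) {
    abort_config(sprintf("unknown entity '%s' (expected 'biosample' or 'subject')", entity))
  }
  entity
}

component_table <- function(cb, entity, component) {
  tab <- cb$lookup[cb$lookup$entity == entity & cb$lookup$component == component, ]
  if (nrow(tab) == 0L) {
    abort_config(sprintf("entity '%s' has no vocabulary component '%s'", entity, component))
  }
  tab
}

#' Look up a codebook entry by term
#'
#' Exact, case-sensitive forward lookup used by the encoder: the
#' vocabulary term (e.g. `"Liver"`) resolves to its entry with `code`,
#' `stub_code`, `label` and `id`.
#'
#' @param cb A `clarid_codebook` from [load_codebook()].
#' @param entity `"biosample"` or `"subject"`.
#' @param component Component name (e.g. `"tissue"`).
#' @param term Vocabulary term.
#' @return A one-row tibble (the entry).
#' @examples
#' cb <- load_codebook()
#' resolve_term(cb, "biosample", "assay", "RNA_seq")
#' @export
resolve_term <- function(cb, entity, component, term) {
  check_entity(cb, entity)
  tab <- component_table(cb, entity, component)
  hit <- tab[tab$term == term, ]
  if (nrow(hit) != 1L) {
    abort_vocabulary(sprintf(
      "unknown %s %s term '%s'; valid terms: %s",
      entity, component, term, paste(sort(tab$term), collapse = ", ")
    ))
  }
  hit
}

#' Look up a vocabulary term by its code or stub code
#'
#' Reverse lookup used by the decoder: maps a human-format `code`
#' (`fmt = "human"`) or a compact `stub_code` (`fmt = "stub"`) back to its
#' vocabulary term. Uniqueness within one (entity, component) is a
#' codebook invariant, so the match is never ambiguous.
#'
#' @inheritParams resolve_term
#' @param token The `code` or `stub_code` to invert.
#' @param fmt `"human"` or `"stub"`.
#' @return The vocabulary term (length-1 character).
#' @examples
#' cb <- load_codebook()
#' reverse_lookup(cb, "biosample", "tissue", "LIV", "human")
#' @export
reverse_lookup <- function(cb, entity, component, token, fmt = c("human", "stub")) {
  fmt <- match.arg(fmt)
  check_entity(cb, entity)
  tab <- component_table(cb, entity, component)
  col <- if (fmt == "human") tab$code else tab$stub_code
  hit <- tab$term[col == token]
  if (length(hit) != 1L) {
    abort_decode(sprintf(
      "no %s %s %s matches token '%s'",
      entity, component, if (fmt == "human") "code" else "stub_code", token
    ))
  }
  hit
}

# Match a value against a named rule regex (rule-based components).
check_rule <- function(cb, rule, value, what = rule) {
  pat <- cb$rules[[rule]]
  if (is.null(pat)) abort_config(sprintf("codebook defines no rule '%s'", rule))
  if (length(value) != 1L || is.na(value) || !grepl(pat, value)) {
    abort_format(sprintf("invalid %s '%s' (must match %s)", what, as.character(value), pat))
  }
  invisible(value)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
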