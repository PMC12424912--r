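# Identifier parsing.
#
# Human identifiers are split on "-" (subject parsing is right-anchored:
# the study is the variable element); stub identifiers are parsed by
# fixed-width slicing after stripping the optional batch/replicate
# suffixes and resolving the variable-length project prefix. Decoding is
# strict: no case folding and no whitespace inside identifiers (leading/
# trailing whitespace of the whole string is trimmed).

#' Strip batch/replicate suffixes from a stub identifier
#'
#' Greedily removes, from the right, a replicate token `"R" + 2 digits`,
#' then a batch token `"B" + 2 digits`. Absence of either is legal.
#'
#' @param stub Stub identifier string.
#' @return A list with `core` (remaining string), `batch` and
#'   `replicate` (integers or `NA`).
#' @examples
#' strip_optional_suffixes("CT01001LTR0000101T1WB01R05")
#' @export
strip_optional_suffixes <- function(stub) {
  stopifnot(is.character(stub), length(stub) == 1L)
  batch <- NA_integer_
  replicate <- NA_integer_
  if (grepl("R[0-9]{2}$", stub)) {
    replicate <- as.integer(substr(stub, nchar(stub) - 1L, nchar(stub)))
    stub <- substr(stub, 1L, nchar(stub) - 3L)
  }
  if (grepl("B[0-9]{2}$", stub)) {
    batch <- as.integer(substr(stub, nchar(stub) - 1L, nchar(stub)))
    stub <- substr(stub, 1L, nchar(stub) - 3L)
  }
  list(core = stub, batch = batch, replicate = replicate)
}

# Parse a biosample stub core (optionals already stripped) under one
# project candidate: fixed widths species 2, subject_id 3, tissue 1,
# sample_type 1, assay 1, condition 5, timepoint 1, then a 1-2 character
# duration payload. Returns the record list or signals a clarid error.
parse_biosample_core_remainder <- function(rem, cb, table) {
  if (nchar(rem) < 15L || nchar(rem) > 16L) {
    abort_structure(sprintf(
      "stub remainder '%s' has length %d; expected 15-16", rem, nchar(rem)
    ))
  }
  cut <- c(species = 2L, subject_id = 3L, tissue = 1L, sample_type = 1L,
           assay = 1L, condition = 5L, timepoint = 1L)
  pos <- cumsum(c(1L, cut))
  slice <- function(i) substr(rem, pos[i], pos[i + 1L] - 1L)
  payload <- substr(rem, pos[length(pos)], nchar(rem))
  duration <- validate_duration(paste0("P", payload))
  list(
    species     = reverse_lookup(cb, "biosample", "species", slice(1L), "stub"),
    subject_id  = base62_decode(slice(2L)),
    tissue      = reverse_lookup(cb, "biosample", "tissue", slice(3L), "stub"),
    sample_type = reverse_lookup(cb, "biosample", "sample_type", slice(4L), "stub"),
    assay       = reverse_lookup(cb, "biosample", "assay", slice(5L), "stub"),
    condition   = decode_condition_stub(slice(6L), table),
    timepoint   = reverse_lookup(cb, "biosample", "timepoint", slice(7L), "stub"),
    duration    = duration
  )
}

#' Resolve the variable-length project prefix of a biosample stub
#'
#' Project stub codes are the only variable-width element of a biosample
#' stub core, so the parse tries every project whose stub code prefixes
#' the core and keeps the unique candidate under which the fixed-width
#' remainder parses completely. Zero full parses and multiple full
#' parses are distinct errors (the latter means the codebook's project
#' stub codes are ambiguous and should be redefined).
#'
#' @param core Stub core (optional suffixes already stripped).
#' @param cb A `clarid_codebook`.
#' @param table A `clarid_icd10` table.
#' @return A list with `project` (term), `remainder` (string) and
#'   `record` (the parsed remainder fields).
#' @export
resolve_project_prefix <- function(core, cb, table) {
  if (!is.character(core) || length(core) != 1L || !nzchar(core)) {
    abort_structure("empty stub core")
  }
  ptab <- component_table(cb, "biosample", "project")
  hits <- list()
  for (i in seq_len(nrow(ptab))) {
    stub <- ptab$stub_code[i]
    if (startsWith(core, stub)) {
      rem <- substr(core, nchar(stub) + 1L, nchar(core))
      parsed <- tryCatch(parse_biosample_core_remainder(rem, cb, table),
                         clarid_error = function(e) NULL)
      if (!is.null(parsed)) {
        hits[[length(hits) + 1L]] <- list(project = ptab$term[i], remainder = rem, record = parsed)
      }
    }
  }
  if (length(hits) == 0L) {
    abort_decode(sprintf("no project stub matches '%s'", core))
  }
  if (length(hits) > 1L) {
    abort_decode(sprintf(
      "ambiguous stub '%s' (projects %s all parse); redefine project stub_codes",
      core, paste(vapply(hits, `[[`, "", "project"), collapse = ", ")
    ))
  }
  hits[[1L]]
}

decode_biosample_stub_one <- function(id, cb, table) {
  if (!nzchar(id)) abort_structure("empty identifier")
  stripped <- strip_optional_suffixes(id)
  # Re-parse guard: a stripped core that fails to parse falls back to
  # less-stripped variants (a legitimate core could end in digits).
  candidates <- list(stripped)
  if (!is.na(stripped$replicate) && !is.na(stripped$batch)) {
    candidates <- c(candidates, list(list(
      core = substr(id, 1L, nchar(id) - 3L),
      batch = NA_integer_,
      replicate = as.integer(substr(id, nchar(id) - 1L, nchar(id)))
    )))
  }
  if (!is.na(stripped$replicate) || !is.na(stripped$batch)) {
    candidates <- c(candidates, list(list(core = id, batch = NA_integer_, replicate = NA_integer_)))
  }
  last_err <- NULL
  for (cand in candidates) {
    res <- tryCatch(resolve_project_prefix(cand$core, cb, table),
                    clarid_error = function(e) e)
    if (!is_clarid_error(res)) {
      return(c(list(project = res$project), res$record,
               list(batch = cand$batch, replicate = cand$replicate)))
    }
    last_err <- res
  }
  stop(last_err)
}

decode_biosample_human_one <- function(id, cb, table) {
  tokens <- strsplit(id, "-", fixed = TRUE)[[1L]]
  if (length(tokens) < 9L || length(tokens) > 11L || any(!nzchar(tokens))) {
    abort_structure(sprintf(
      "'%s' splits into %d hyphen-separated tokens; a biosample identifier has 9-11",
      id, length(tokens)
    ))
  }
  batch <- NA_integer_
  replicate <- NA_integer_
  opt <- tokens[-seq_len(9L)]
  for (tk in opt) {
    if (grepl("^B[0-9]{2}$", tk) && is.na(batch) && is.na(replicate)) {
      batch <- as.integer(substr(tk, 2L, 3L))
    } else if (grepl("^R[0-9]{2}$", tk) && is.na(replicate)) {
      replicate <- as.integer(substr(tk, 2L, 3L))
    } else {
      abort_structure(sprintf("malformed optional token '%s' (expected Bnn then Rnn)", tk))
    }
  }
  ptab <- component_table(cb, "biosample", "project")
  project <- ptab$term[match(tokens[1L], ptab$code)]
  if (is.na(project)) {
    # free-form project: restricted to the human-format identifier charset
    if (!grepl(.free_text_pattern, tokens[1L])) {
      abort_vocabulary(sprintf("position 1 (project): invalid token '%s'", tokens[1L]))
    }
    project <- tokens[1L]
  }
  if (!grepl("^[0-9]{5}$", tokens[3L])) {
    abort_structure(sprintf("position 3 (subject_id): '%s' is not a 5-digit token", tokens[3L]))
  }
  if (!tokens[7L] %in% table$code) {
    abort_lookup(sprintf("position 7 (condition): '%s' is not in the ICD-10 table", tokens[7L]))
  }
  look <- function(pos, comp) {
    tryCatch(reverse_lookup(cb, "biosample", comp, tokens[pos], "human"),
             clarid_error = function(e) abort_vocabulary(sprintf(
               "position %d (%s): %s", pos, comp, conditionMessage(e))))
  }
  list(
    project = project,
    species = look(2L, "species"),
    subject_id = as.numeric(tokens[3L]),
    tissue = look(4L, "tissue"),
    sample_type = look(5L, "sample_type"),
    assay = look(6L, "assay"),
    condition = tokens[7L],
    timepoint = look(8L, "timepoint"),
    duration = validate_duration(tokens[9L]),
    batch = batch,
    replicate = replicate
  )
}

decode_subject_human_one <- function(id, cb, table) {
  tokens <- strsplit(id, "-", fixed = TRUE)[[1L]]
  if (length(tokens) < 6L || any(!nzchar(tokens))) {
    abort_structure(sprintf(
      "'%s' splits into %d hyphen-separated tokens; a subject identifier has at least 6",
      id, length(tokens)
    ))
  }
  # right-anchored: last 5 tokens are fixed, the remainder is the study
  n <- length(tokens)
  fixed <- tokens[(n - 4L):n]
  study <- paste(tokens[seq_len(n - 5L)], collapse = "-")
  if (!all(grepl(.free_text_pattern, tokens[seq_len(n - 5L)]))) {
    abort_structure(sprintf("study '%s' contains characters outside the identifier charset", study))
  }
  if (!grepl("^[0-9]{5}$", fixed[1L])) {
    abort_structure(sprintf("subject_id token '%s' is not a 5-digit token", fixed[1L]))
  }
  if (!fixed[3L] %in% table$code) {
    abort_lookup(sprintf("condition '%s' is not in the ICD-10 table", fixed[3L]))
  }
  look <- function(tk, comp) {
    tryCatch(reverse_lookup(cb, "subject", comp, tk, "human"),
             clarid_error = function(e) abort_vocabulary(sprintf("%s: %s", comp, conditionMessage(e))))
  }
  list(
    study = study,
    subject_id = as.numeric(fixed[1L]),
    type = look(fixed[2L], "type"),
    condition = fixed[3L],
    sex = look(fixed[4L], "sex"),
    age_group = look(fixed[5L], "age_group")
  )
}

decode_subject_stub_one <- function(id, cb, table) {
  if (nchar(id) < 13L) {
    abort_structure(sprintf(
      "subject stub '%s' is too short (study + 12-character tail required)", id
    ))
  }
  n <- nchar(id)
  study <- substr(id, 1L, n - 12L)
  tail <- substr(id, n - 11L, n)
  look <- function(tk, comp) {
    tryCatch(reverse_lookup(cb, "subject", comp, tk, "stub"),
             clarid_error = function(e) abort_vocabulary(sprintf("%s: %s", comp, conditionMessage(e))))
  }
  list(
    study = study,
    subject_id = base62_decode(substr(tail, 1L, 3L)),
    type = look(substr(tail, 4L, 4L), "type"),
    condition = decode_condition_stub(substr(tail, 5L, 9L), table),
    sex = look(substr(tail, 10L, 10L), "sex"),
    age_group = look(substr(tail, 11L, 12L), "age_group")
  )
}

#' Attach the condition name to a decoded record
#'
#' Translates the record's ICD-10 `condition` code to its display name
#' via the lookup table, adding a `condition_name` column; the `"NA"`
#' sentinel translates to the placeholder `"not available"`.
#'
#' @param record A data frame with a `condition` column (e.g. the output
#'   of [clarid_decode()]).
#' @param table A `clarid_icd10` table.
#' @return `record` with `condition_name` added.
#' @export
attach_condition_name <- function(record, table) {
  stopifnot(is.data.frame(record), "condition" %in% names(record))
  dplyr::mutate(tibble::as_tibble(record),
                condition_name = condition_name(table, .data$condition))
}

decode_one <- function(id, entity, fmt, cb, table) {
  if (!is.character(id) || length(id) != 1L || is.na(id)) {
    abort_structure("identifier must be a single character string")
  }
  id <- trimws(id)
  if (!nzchar(id)) abort_structure("empty identifier")
  if (entity == "biosample") {
    if (fmt == "human") decode_biosample_human_one(id, cb, table)
    else decode_biosample_stub_one(id, cb, table)
  } else {
    if (fmt == "human") decode_subject_human_one(id, cb, table)
    else decode_subject_stub_one(id, cb, table)
  }
}

#' Decode one ClarID identifier
#'
#' Parses a single identifier back into its component record. See
#' [clarid_decode()] for the data-frame-first batch variant.
#'
#' @param id Identifier string.
#' @param entity `"biosample"` or `"subject"`.
#' @param cb A `clarid_codebook`.
#' @param table A `clarid_icd10` table.
#' @param fmt `"human"` or `"stub"`.
#' @param with_condition_name Also translate the ICD-10 code to its name.
#' @return A one-row tibble of component values (plus `condition_name`
#'   when requested).
#' @examples
#' cb <- load_codebook(); icd <- load_icd10()
#' decode_identifier("COPDStudy-01001-Case-J44.9-Male-A40_49", "subject", cb, icd)
#' @export
decode_identifier <- function(id, entity = c("biosample", "subject"), cb, table,
                              fmt = c("human", "stub"), with_condition_name = FALSE) {
  entity <- match.arg(entity)
  fmt <- match.arg(fmt)
  rec <- decode_one(id, entity, fmt, cb, table)
  out <- tibble::as_tibble(rec)
  if (with_condition_name) out <- attach_condition_name(out, table)
  attr(out, "source_format") <- fmt
  out
}

#' Decode ClarID identifiers in bulk
#'
#' Data-frame-first decoder: takes a data frame holding identifiers (or
#' a bare character vector) and returns one component column per field.
#'
#' @param data Data frame with an identifier column, or a character
#'   vector of identifiers.
#' @param entity `"biosample"` or `"subject"`.
#' @param format `"human"` or `"stub"`.
#' @param codebook A `clarid_codebook` (default: bundled codebook).
#' @param icd10 A `clarid_icd10` table (default: bundled table).
#' @param col Name of the identifier column when `data` is a data frame.
#' @param with_condition_name Add a `condition_name` column translated
#'   from the ICD-10 table.
#' @param on_error `"abort"` (default) or `"na"`: leave failed rows as
#'   `NA` and report them in the `clarid_errors` attribute.
#' @return A tibble with one decoded record per row.
#' @examples
#' clarid_decode("COPDStudy-01001-Case-J44.9-Male-A40_49",
#'               entity = "subject", format = "human")
#' @export
clarid_decode <- function(data, entity = c("biosample", "subject"),
                          format = c("human", "stub"),
                          codebook = load_codebook(), icd10 = load_icd10(),
                          col = "clarid", with_condition_name = FALSE,
                          on_error = c("abort", "na")) {
  entity <- match.arg(entity)
  format <- match.arg(format)
  on_error <- match.arg(on_error)
  ids <- if (is.data.frame(data)) {
    if (!col %in% names(data)) abort_config(sprintf("input lacks identifier column '%s'", col))
    as.character(data[[col]])
  } else {
    as.character(data)
  }
  fields <- .record_columns[[entity]]
  recs <- vector("list", length(ids))
  errs <- list()
  for (i in seq_along(ids)) {
    rec <- tryCatch(decode_one(ids[i], entity, format, codebook, icd10),
                    clarid_error = function(e) e)
    if (is_clarid_error(rec)) {
      if (on_error == "abort") {
        clarid_abort(sub("^clarid_([a-z]+)_error$", "\\1", class(rec)[1L]),
                     sprintf("row %d ('%s'): %s", i, ids[i], conditionMessage(rec)))
      }
      errs[[length(errs) + 1L]] <- tibble::tibble(
        row = i, error_class = sub("^clarid_([a-z]+)_error$", "\\1", class(rec)[1L]),
        error = conditionMessage(rec)
      )
      recs[[i]] <- NULL
    } else {
      recs[[i]] <- rec
    }
  }
  grab <- function(f) {
    vapply(recs, function(r) {
      if (is.null(r) || is.null(r[[f]])) NA else r[[f]]
    }, if (f %in% c("subject_id", "batch", "replicate")) numeric(1) else character(1))
  }
  out <- tibble::as_tibble(stats::setNames(lapply(fields, grab), fields))
  if (with_condition_name) {
    nm <- rep(NA_character_, nrow(out))
    ok <- !is.na(out$condition)
    nm[ok] <- condition_name(icd10, out$condition[ok])
    out$condition_name <- nm
  }
  err_tab <- if (length(errs) > 0L) dplyr::bind_rows(errs) else
    tibble::tibble(row = integer(0), error_class = character(0), error = character(0))
  attr(out, "clarid_errors") <- err_tab
  attr(out, "source_format") <- format
  out
}
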