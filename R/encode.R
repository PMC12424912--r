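# Identifier construction.
#
# Human format: verbose, hyphen-delimited codebook codes.
#   biosample: project-species-subject_id-tissue-sample_type-assay-
#              condition-timepoint-duration[-Bbb][-Rrr]   (9 + 2 optional)
#   subject:   study-subject_id-type-condition-sex-age_group (6 fields)
# Stub format: delimiter-free concatenation of fixed-width short codes.
#   biosample: project* + species(2) + subject_id base62(3) + tissue(1) +
#              sample_type(1) + assay(1) + condition(5) + timepoint(1) +
#              duration payload(1-2) [+ Bbb][+ Rrr]
#   subject:   study* + subject_id base62(3) + type(1) + condition(5) +
#              sex(1) + age_group(2)      (fixed 12-character tail)
# (* variable width: project stub_code from the codebook; study verbatim.)

#' Format a subject ID for the human identifier format
#'
#' @param n Positive integers, `1..99999`.
#' @return Zero-padded 5-digit decimal tokens (e.g. `1` becomes
#'   `"00001"`); padding preserves numeric order under lexicographic
#'   comparison.
#' @export
format_subject_id_human <- function(n) {
  n <- suppressWarnings(as.numeric(n))
  if (anyNA(n) || any(n != floor(n)) || any(n < 1) || any(n > 99999)) {
    abort_range("subject_id must be an integer between 1 and 99999")
  }
  sprintf("%05d", as.integer(n))
}

#' Validate an ISO 8601-style duration token
#'
#' Durations are restricted to at most 3 characters: a leading `"P"`,
#' one digit and one unit letter among `D`, `W`, `M`, `Y` (e.g. `"P1W"`,
#' one week), or the sentinel `"P0N"` meaning duration not available.
#'
#' @param s Duration token.
#' @return The token, unchanged, when valid; otherwise a format error.
#' @examples
#' validate_duration("P1W")
#' @export
validate_duration <- function(s) {
  if (!is.character(s) || length(s) != 1L || is.na(s)) {
    abort_format("duration must be a single character token")
  }
  if (nchar(s) > 3L) {
    abort_format(sprintf("duration '%s' exceeds the 3-character maximum", s))
  }
  if (!grepl("^P([0-9][DWMY]|0N)$", s)) {
    abort_format(sprintf(
      "invalid duration '%s' (expected 'P' + digit + unit D/W/M/Y, or 'P0N')", s
    ))
  }
  s
}

#' Stub encoding of a clinical condition
#'
#' The stub format encodes a condition as a fixed 5-character token: the
#' 3-character Base62 encoding of the code's rank in the ICD-10 table
#' (see [condition_rank()]) followed by the reserved suffix `"01"`. The
#' `"NA"` sentinel (rank 0) therefore encodes as `"00001"`.
#' `decode_condition_stub()` inverts the token back to the ICD-10 code.
#'
#' @param code ICD-10 code present in `table`, or `"NA"`.
#' @param table A `clarid_icd10` table from [load_icd10()].
#' @return A 5-character token (encode) or the ICD-10 code (decode).
#' @export
encode_condition_stub <- function(code, table) {
  paste0(base62_encode(condition_rank(table, code), 3L), "01")
}

#' @param token 5-character condition stub token.
#' @rdname encode_condition_stub
#' @export
decode_condition_stub <- function(token, table) {
  if (!is.character(token) || length(token) != 1L || nchar(token) != 5L) {
    abort_structure(sprintf("condition stub '%s' must be exactly 5 characters",
                            as.character(token)))
  }
  if (substr(token, 4L, 5L) != "01") {
    abort_decode(sprintf("condition stub '%s' lacks the reserved '01' suffix", token))
  }
  rank <- base62_decode(substr(token, 1L, 3L))
  rank_to_condition(table, rank)$code
}

sanitize_free_text <- function(x) gsub("-", "_", x, fixed = TRUE)

.free_text_pattern <- "^[A-Za-z0-9_.]+$"

# --- vectorized row encoding ------------------------------------------------

# Column sets per entity, in identifier order.
.record_columns <- list(
  biosample = c("project", "species", "subject_id", "tissue", "sample_type",
                "assay", "condition", "timepoint", "duration", "batch", "replicate"),
  subject   = c("study", "subject_id", "type", "condition", "sex", "age_group")
)

.vocab_components <- list(
  biosample = c("species", "tissue", "sample_type", "assay", "timepoint"),
  subject   = c("type", "sex", "age_group")
)

# Missing-value policy: these components have a dedicated "not available"
# encoding instead of failing the row.
apply_na_policy <- function(data, entity) {
  fill <- function(col, value) {
    if (!col %in% names(data)) data[[col]] <<- rep(NA_character_, nrow(data))
    v <- as.character(data[[col]])
    v[is.na(v) | v == ""] <- value
    data[[col]] <<- v
  }
  fill("condition", "NA")
  if (entity == "biosample") {
    fill("duration", "P0N")
    fill("assay", "Not_available")
  }
  data
}

# Encode every row of `data`; returns tibble(clarid, error_class, error).
# Invalid rows yield NA identifiers and a classified message instead of
# aborting, so batch callers can collect failures.
encode_rows <- function(data, entity, cb, table, fmt) {
  n <- nrow(data)
  err_class <- rep(NA_character_, n)
  err <- rep(NA_character_, n)
  flag <- function(bad, class, msg) {
    fresh <- bad & is.na(err)
    err_class[fresh] <<- class
    err[fresh] <<- msg[fresh]
  }
  # optionals and NA-policy fields (condition, duration, assay) may be absent
  optional_cols <- c("batch", "replicate", "condition",
                     if (entity == "biosample") c("duration", "assay"))
  for (col in setdiff(.record_columns[[entity]], optional_cols)) {
    if (!col %in% names(data)) {
      abort_config(sprintf("input lacks required column '%s' for entity '%s'", col, entity))
    }
  }
  data <- apply_na_policy(data, entity)

  tokens <- list()
  # vocabulary components -> code / stub_code
  for (comp in .vocab_components[[entity]]) {
    tab <- component_table(cb, entity, comp)
    vals <- as.character(data[[comp]])
    i <- match(vals, tab$term)
    flag(is.na(i), "vocabulary",
         sprintf("unknown %s term '%s'", comp, vals))
    tokens[[comp]] <- list(code = tab$code[i], stub = tab$stub_code[i])
  }
  # free-form-capable prefix component (project / study)
  prefix_comp <- if (entity == "biosample") "project" else "study"
  pvals <- as.character(data[[prefix_comp]])
  flag(is.na(pvals) | pvals == "", "vocabulary",
       rep(sprintf("missing %s", prefix_comp), n))
  ptab <- tryCatch(component_table(cb, entity, prefix_comp), clarid_error = function(e) NULL)
  pi <- if (is.null(ptab)) rep(NA_integer_, n) else match(pvals, ptab$term)
  known <- !is.na(pi)
  pcode <- ifelse(known, ptab$code[pi], sanitize_free_text(pvals))
  pstub <- ifelse(known, ptab$stub_code[pi], NA_character_)
  if (fmt == "human") {
    # stub format carries the study verbatim, so the character restriction
    # (hyphen is the human-format delimiter) only binds in human format
    bad_free <- !known & !is.na(pvals) & !grepl(.free_text_pattern, sanitize_free_text(pvals))
    flag(bad_free, "format",
         sprintf("free-form %s '%s' contains characters outside [A-Za-z0-9_.]", prefix_comp, pvals))
  }
  if (fmt == "stub") {
    if (entity == "biosample") {
      flag(!known, "config",
           sprintf("project '%s' has no stub_code in the codebook (required for stub format)", pvals))
    } else {
      pstub <- pvals  # study is carried verbatim in stub format
    }
  }

  # subject_id
  sid <- suppressWarnings(as.numeric(data$subject_id))
  bad_sid <- is.na(sid) | sid != floor(sid) | sid < 1 | sid > 99999
  flag(bad_sid, "range",
       sprintf("subject_id '%s' is not an integer in 1..99999", as.character(data$subject_id)))
  sid[bad_sid] <- 1  # placeholder; rows already flagged

  # condition
  cvals <- as.character(data$condition)
  ci <- match(cvals, table$code)
  flag(is.na(ci), "lookup",
       sprintf("condition '%s' is not in the ICD-10 table", cvals))
  crank <- ifelse(is.na(ci), 0L, table$rank[ci])

  # duration / optionals (biosample only)
  if (entity == "biosample") {
    dvals <- as.character(data$duration)
    bad_dur <- nchar(dvals) > 3L | !grepl("^P([0-9][DWMY]|0N)$", dvals)
    flag(bad_dur, "format", sprintf("invalid duration '%s'", dvals))
    dvals[bad_dur] <- "P0N"
    opt <- function(col) {
      v <- if (col %in% names(data)) suppressWarnings(as.numeric(data[[col]])) else rep(NA_real_, n)
      bad <- !is.na(v) & (v != floor(v) | v < 1 | v > 99)
      flag(bad, "range", sprintf("%s '%s' is not an integer in 1..99", col,
                                 as.character(if (col %in% names(data)) data[[col]] else NA)))
      v[bad] <- NA_real_
      v
    }
    batch <- opt("batch")
    replicate <- opt("replicate")
    opt_human <- paste0(
      ifelse(is.na(batch), "", sprintf("-B%02d", as.integer(batch))),
      ifelse(is.na(replicate), "", sprintf("-R%02d", as.integer(replicate)))
    )
    opt_stub <- gsub("-", "", opt_human, fixed = TRUE)
  }

  if (fmt == "human") {
    id <- if (entity == "biosample") {
      paste(pcode, tokens$species$code, sprintf("%05d", as.integer(sid)),
            tokens$tissue$code, tokens$sample_type$code, tokens$assay$code,
            cvals, tokens$timepoint$code, dvals, sep = "-")
    } else {
      paste(pcode, sprintf("%05d", as.integer(sid)), tokens$type$code,
            cvals, tokens$sex$code, tokens$age_group$code, sep = "-")
    }
    if (entity == "biosample") id <- paste0(id, opt_human)
  } else {
    sid62 <- base62_encode(as.integer(sid), 3L)
    cond62 <- paste0(base62_encode(crank, 3L), "01")
    id <- if (entity == "biosample") {
      paste0(pstub, tokens$species$stub, sid62, tokens$tissue$stub,
             tokens$sample_type$stub, tokens$assay$stub, cond62,
             tokens$timepoint$stub, sub("^P", "", dvals), opt_stub)
    } else {
      paste0(pstub, sid62, tokens$type$stub, cond62,
             tokens$sex$stub, tokens$age_group$stub)
    }
  }
  id[!is.na(err)] <- NA_character_
  tibble::tibble(clarid = id, error_class = err_class, error = err)
}

record_to_row <- function(record, entity) {
  record <- record[!vapply(record, is.null, logical(1))]
  unknown <- setdiff(names(record), .record_columns[[entity]])
  if (length(unknown) > 0L) {
    abort_config(paste0("unknown record field(s): ", paste(unknown, collapse = ", ")))
  }
  tibble::as_tibble(lapply(record, function(x) x[[1L]]))
}

raise_row_error <- function(row) {
  fn <- switch(row$error_class,
    vocabulary = abort_vocabulary, range = abort_range, format = abort_format,
    lookup = abort_lookup, config = abort_config, abort_validation
  )
  fn(row$error)
}

#' Encode one biosample or subject record
#'
#' Builds the ClarID identifier for a single record given as a named
#' list (or one-row data frame). Biosample fields: `project`, `species`,
#' `subject_id`, `tissue`, `sample_type`, `assay`, `condition`,
#' `timepoint`, `duration`, plus optional `batch` and `replicate`
#' (integers 1-99). Subject fields: `study`, `subject_id`, `type`,
#' `condition`, `sex`, `age_group`. Missing `condition`, `duration` and
#' `assay` fall back to their "not available" encodings (`"NA"`,
#' `"P0N"`, `Not_available`); a missing project stub code is an error in
#' stub format since free-text projects have no compact form.
#'
#' @param record Named list or one-row data frame of component values.
#' @param cb A `clarid_codebook`.
#' @param table A `clarid_icd10` condition table.
#' @param fmt `"human"` or `"stub"`.
#' @return The identifier string.
#' @examples
#' cb <- load_codebook(); icd <- load_icd10()
#' encode_biosample(
#'   list(project = "CNAG_Test", species = "Human", subject_id = 1,
#'        tissue = "Liver", sample_type = "Tumor", assay = "RNA_seq",
#'        condition = "C22.0", timepoint = "Treatment", duration = "P1W",
#'        batch = 1, replicate = 5),
#'   cb, icd, "human")
#' @export
encode_biosample <- function(record, cb, table, fmt = c("human", "stub")) {
  fmt <- match.arg(fmt)
  out <- encode_rows(record_to_row(record, "biosample"), "biosample", cb, table, fmt)
  if (!is.na(out$error[1L])) raise_row_error(out[1L, ])
  out$clarid[1L]
}

#' @rdname encode_biosample
#' @export
encode_subject <- function(record, cb, table, fmt = c("human", "stub")) {
  fmt <- match.arg(fmt)
  out <- encode_rows(record_to_row(record, "subject"), "subject", cb, table, fmt)
  if (!is.na(out$error[1L])) raise_row_error(out[1L, ])
  out$clarid[1L]
}

#' Encode a data frame of records into ClarID identifiers
#'
#' Data-frame-first encoder: takes one record per row (canonical
#' component columns, see [encode_biosample()] for the field lists) and
#' appends a `clarid` column. Designed to chain with the pipe.
#'
#' @param data Data frame with one record per row.
#' @param entity `"biosample"` or `"subject"`.
#' @param format `"human"` or `"stub"`.
#' @param codebook A `clarid_codebook` (default: bundled codebook).
#' @param icd10 A `clarid_icd10` table (default: bundled table).
#' @param on_error `"abort"` (default) stops at the first invalid row;
#'   `"na"` leaves `NA` identifiers and records row-level failures in
#'   the `clarid_errors` attribute (a tibble with `row`, `error_class`,
#'   `error`), which batch processing reports.
#' @return `data` as a tibble with a `clarid` column appended.
#' @examples
#' library(tibble)
#' tibble(study = "COPDStudy", subject_id = 1001, type = "Case",
#'        condition = "J44.9", sex = "Male", age_group = "A40_49") |>
#'   clarid_encode("subject", "human")
#' @export
clarid_encode <- function(data, entity = c("biosample", "subject"),
                          format = c("human", "stub"),
                          codebook = load_codebook(), icd10 = load_icd10(),
                          on_error = c("abort", "na")) {
  entity <- match.arg(entity)
  format <- match.arg(format)
  on_error <- match.arg(on_error)
  stopifnot(is.data.frame(data))
  res <- encode_rows(tibble::as_tibble(data), entity, codebook, icd10, format)
  bad <- which(!is.na(res$error))
  if (length(bad) > 0L && on_error == "abort") {
    raise_row_error(dplyr::mutate(res[bad[1L], ], error = sprintf("row %d: %s", bad[1L], error)))
  }
  out <- dplyr::mutate(tibble::as_tibble(data), clarid = res$clarid)
  attr(out, "clarid_errors") <- tibble::tibble(
    row = bad, error_class = res$error_class[bad], error = res$error[bad]
  )
  out
}
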