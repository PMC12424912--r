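#' Load an ICD-10 condition lookup table
#'
#' Clinical conditions are not part of the YAML codebook; they are looked
#' up in a JSON table of `{"code": ..., "name": ...}` objects. The table
#' is canonicalized on load: the `"NA"` sentinel (condition not
#' available) is placed first, remaining codes are sorted
#' lexicographically, and each code's 0-based position in that order is
#' its *rank* — the quantity the stub format encodes in Base62 (see
#' [encode_condition_stub()]).
#'
#' The bundled table is a compact excerpt of the classification covering
#' common conditions; users can substitute a fuller table with the same
#' JSON shape (note that ranks, and therefore stub identifiers, are
#' relative to the table in use).
#'
#' @param path Path to the JSON table; defaults to the bundled mini table.
#' @return A `clarid_icd10` object: a tibble with columns `code`, `name`,
#'   `rank`, ordered by rank.
#' @examples
#' icd <- load_icd10()
#' condition_rank(icd, "NA")
#' @export
load_icd10 <- function(path = clarid_example("icd10-mini.json")) {
  if (!file.exists(path)) {
    abort_io(sprintf("ICD-10 table '%s' does not exist", path))
  }
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
    error = function(e) abort_parse(sprintf("cannot parse JSON in '%s': %s", path, conditionMessage(e)))
  )
  if (!is.data.frame(raw) || !all(c("code", "name") %in% names(raw))) {
    abort_validation("ICD-10 table must be a JSON array of {code, name} objects")
  }
  tab <- tibble::tibble(code = trimws(raw$code), name = trimws(raw$name))
  bad <- tab$code[!grepl("^([A-Z][0-9]{2}(\\.[0-9]{1,2})?|NA)$", tab$code)]
  if (length(bad) > 0L) {
    abort_validation(paste0("invalid ICD-10 code(s): ", paste(unique(bad), collapse = ", ")))
  }
  if (anyDuplicated(tab$code)) {
    abort_validation(paste0(
      "duplicate ICD-10 code(s): ",
      paste(unique(tab$code[duplicated(tab$code)]), collapse = ", ")
    ))
  }
  rest <- tab[tab$code != "NA", ]
  rest <- rest[order(rest$code, method = "radix"), ]
  sentinel <- tab[tab$code == "NA", ]
  if (nrow(sentinel) == 0L) {
    sentinel <- tibble::tibble(code = "NA", name = "not available")
  }
  out <- dplyr::bind_rows(sentinel, rest)
  out$rank <- seq_len(nrow(out)) - 1L
  structure(out, class = c("clarid_icd10", class(out)))
}

#' Condition rank and its inverse
#'
#' `condition_rank()` maps an ICD-10 code to its 0-based rank in the
#' table's canonical order (`"NA"` is always rank 0);
#' `rank_to_condition()` inverts it, returning the `(code, name)` pair at
#' a rank. The two are mutually inverse over the whole table.
#'
#' @param table A `clarid_icd10` table from [load_icd10()].
#' @param code An ICD-10 code present in the table, or `"NA"`.
#' @param rank A 0-based rank `< nrow(table)`.
#' @return `condition_rank()`: an integer rank. `rank_to_condition()`: a
#'   one-row tibble with `code` and `name`.
#' @examples
#' icd <- load_icd10()
#' rank_to_condition(icd, condition_rank(icd, "C22.0"))
#' @export
condition_rank <- function(table, code) {
  stopifnot(inherits(table, "clarid_icd10"))
  i <- match(code, table$code)
  if (length(code) != 1L || is.na(i)) {
    abort_lookup(sprintf("ICD-10 code '%s' is not in the condition table", as.character(code)))
  }
  table$rank[i]
}

#' @rdname condition_rank
#' @export
rank_to_condition <- function(table, rank) {
  stopifnot(inherits(table, "clarid_icd10"))
  if (length(rank) != 1L || is.na(rank) || rank < 0 || rank >= nrow(table) || rank != floor(rank)) {
    abort_lookup(sprintf("rank %s is outside the condition table (0..%d)",
                         as.character(rank), nrow(table) - 1L))
  }
  table[table$rank == rank, c("code", "name")]
}

#' Translate an ICD-10 code to its condition name
#'
#' @inheritParams condition_rank
#' @return The condition name; the `"NA"` sentinel translates to the
#'   placeholder `"not available"`.
#' @export
condition_name <- function(table, code) {
  stopifnot(inherits(table, "clarid_icd10"))
  i <- match(code, table$code)
  if (anyNA(i)) {
    abort_lookup(sprintf(
      "ICD-10 code(s) not in the condition table: %s",
      paste(unique(code[is.na(i)]), collapse = ", ")
    ))
  }
  table$name[i]
}
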