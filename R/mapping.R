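# External column-mapping configurations.
#
# Real-world tables (e.g. clinical exports) rarely carry the canonical
# component columns. A YAML mapping config relates input columns to
# ClarID components, recodes values into vocabulary terms, marks
# missing-value spellings, derives a numeric subject_id (directly or by
# rank of first appearance of a UUID), and bins ages into the codebook's
# decade age groups.

#' Load a ClarID mapping configuration
#'
#' The YAML config may contain: `entity` (`"biosample"` or
#' `"subject"`); `columns` (component name -> input column name);
#' `recodes` (component -> map of input value -> vocabulary term);
#' `na_values` (strings treated as missing, default `""`, `"NA"`,
#' `"'--"`); `id_strategy` (`"numeric"`: the mapped subject_id column is
#' already numeric; `"uuid_order"`: subject_id is the 1-based rank of
#' first appearance of the value, turning UUIDs into stable small
#' integers); `age` (`column`: input column with age in years, binned
#' into the codebook's age groups); and optionally explicit `age_bins`
#' (list of `{min, max, term}`).
#'
#' @param path Path to the YAML mapping file.
#' @return A `clarid_mapping` object.
#' @export
load_mapping <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("mapping file '%s' does not exist", path))
  raw <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) abort_parse(sprintf("cannot parse YAML in '%s': %s", path, conditionMessage(e)))
  )
  new_mapping(raw, path)
}

new_mapping <- function(raw, path = "<in-memory>") {
  if (!is.list(raw)) abort_config("mapping config must be a YAML mapping")
  entity <- raw$entity %||% "subject"
  if (!entity %in% c("biosample", "subject")) {
    abort_config(sprintf("mapping entity '%s' must be 'biosample' or 'subject'", entity))
  }
  bad <- setdiff(names(raw$columns %||% list()), .record_columns[[entity]])
  if (length(bad) > 0L) {
    abort_config(paste0("mapped component(s) not part of entity '", entity, "': ",
                        paste(bad, collapse = ", ")))
  }
  id_strategy <- raw$id_strategy %||% "numeric"
  if (!id_strategy %in% c("numeric", "uuid_order")) {
    abort_config(sprintf("id_strategy '%s' must be 'numeric' or 'uuid_order'", id_strategy))
  }
  bins <- NULL
  if (!is.null(raw$age_bins)) {
    bins <- tibble::tibble(
      min = vapply(raw$age_bins, function(b) as.numeric(b$min), numeric(1)),
      max = vapply(raw$age_bins, function(b) as.numeric(b$max), numeric(1)),
      term = vapply(raw$age_bins, function(b) as.character(b$term), character(1))
    )
    check_age_bins(bins)
  }
  structure(
    list(
      entity = entity,
      column_map = raw$columns %||% list(),
      value_recodes = raw$recodes %||% list(),
      na_values = as.character(raw$na_values %||% c("", "NA", "'--")),
      id_strategy = id_strategy,
      age_column = raw$age$column %||% NULL,
      age_bins = bins,
      path = path
    ),
    class = "clarid_mapping"
  )
}

check_age_bins <- function(bins) {
  bins <- bins[order(bins$min), ]
  if (bins$min[1L] != 0 || bins$max[nrow(bins)] < 99 ||
      any(bins$min > bins$max) ||
      (nrow(bins) > 1L && any(bins$min[-1L] != bins$max[-nrow(bins)] + 1))) {
    abort_config("age bins must be non-overlapping, sorted, and cover ages 0-99")
  }
  invisible(bins)
}

#' Derive decade age bins from a codebook's age groups
#'
#' Parses `age_group` terms of the form `A<lo>_<hi>` (e.g. `A40_49`)
#' into a bin table usable by [bin_age()].
#'
#' @param cb A `clarid_codebook`.
#' @return A tibble with `min`, `max`, `term`, sorted by `min`.
#' @export
age_bins_from_codebook <- function(cb) {
  terms <- component_table(cb, "subject", "age_group")$term
  m <- regmatches(terms, regexec("^A([0-9]+)_([0-9]+)$", terms))
  ok <- lengths(m) == 3L
  if (!all(ok)) {
    abort_config(paste0("age_group term(s) not of the form A<lo>_<hi>: ",
                        paste(terms[!ok], collapse = ", ")))
  }
  bins <- tibble::tibble(
    min = as.numeric(vapply(m, `[`, "", 2L)),
    max = as.numeric(vapply(m, `[`, "", 3L)),
    term = terms
  )
  bins <- bins[order(bins$min), ]
  check_age_bins(bins)
  bins
}

#' Bin an age in years into an age-group term
#'
#' @param age Non-negative ages in years (fractions allowed; `floor()`
#'   is applied before binning, so 49.9 falls in the 40-49 bin).
#' @param bins Bin table (`min`, `max`, `term`), e.g. from
#'   [age_bins_from_codebook()].
#' @return The age-group terms.
#' @examples
#' bin_age(45, age_bins_from_codebook(load_codebook()))
#' @export
bin_age <- function(age, bins) {
  age <- suppressWarnings(as.numeric(age))
  if (anyNA(age) || any(age < 0)) {
    abort_range("age must be a non-negative number")
  }
  yr <- floor(age)
  idx <- vapply(yr, function(y) {
    i <- which(bins$min <= y & y <= bins$max)
    if (length(i) != 1L) NA_integer_ else i
  }, integer(1))
  if (anyNA(idx)) {
    abort_range(sprintf("age(s) outside all bins: %s",
                        paste(unique(age[is.na(idx)]), collapse = ", ")))
  }
  bins$term[idx]
}

#' Apply a mapping configuration to raw input rows
#'
#' Renames input columns to canonical component names, blanks the
#' configured missing-value spellings, recodes values into vocabulary
#' terms, derives `subject_id` per the `id_strategy` and bins ages into
#' age groups. The result has the canonical columns [clarid_encode()]
#' expects; row-level problems (an unknown term that survives recoding,
#' a missing required value) are left for the encoder to flag so batch
#' runs can report them per row.
#'
#' @param data Input tibble (raw columns).
#' @param mapping A `clarid_mapping` from [load_mapping()].
#' @param codebook A `clarid_codebook` (source of the default age bins).
#' @return A tibble with canonical component columns.
#' @export
apply_mapping <- function(data, mapping, codebook = load_codebook()) {
  stopifnot(inherits(mapping, "clarid_mapping"), is.data.frame(data))
  data <- tibble::as_tibble(data)
  entity <- mapping$entity
  out <- tibble::tibble(.rows = nrow(data))
  for (comp in names(mapping$column_map)) {
    src <- mapping$column_map[[comp]]
    if (!src %in% names(data)) {
      abort_config(sprintf("mapped column '%s' (component '%s') is absent from the input", src, comp))
    }
    out[[comp]] <- as.character(data[[src]])
  }
  # untouched canonical columns pass through
  for (comp in setdiff(.record_columns[[entity]], names(out))) {
    if (comp %in% names(data)) out[[comp]] <- data[[comp]]
  }
  for (comp in names(out)) {
    v <- out[[comp]]
    if (is.character(v)) v[v %in% mapping$na_values] <- NA_character_
    out[[comp]] <- v
  }
  for (comp in names(mapping$value_recodes)) {
    if (!comp %in% names(out)) next
    map <- mapping$value_recodes[[comp]]
    v <- as.character(out[[comp]])
    hit <- v %in% names(map)
    v[hit] <- unlist(map)[v[hit]]
    out[[comp]] <- v
  }
  if (!is.null(mapping$age_column)) {
    if (!mapping$age_column %in% names(data)) {
      abort_config(sprintf("age column '%s' is absent from the input", mapping$age_column))
    }
    ages <- as.character(data[[mapping$age_column]])
    ages[ages %in% mapping$na_values] <- NA_character_
    bins <- mapping$age_bins %||% age_bins_from_codebook(codebook)
    grp <- rep(NA_character_, length(ages))
    ok <- !is.na(ages)
    if (any(ok)) grp[ok] <- bin_age(as.numeric(ages[ok]), bins)
    out$age_group <- grp
  }
  if (mapping$id_strategy == "uuid_order" && "subject_id" %in% names(out)) {
    v <- as.character(out$subject_id)
    out$subject_id <- match(v, unique(v))
  }
  out
}

#' @export
print.clarid_mapping <- function(x, ...) {
  cat("<clarid_mapping>", x$path, "\n")
  cat("  entity:", x$entity, " id_strategy:", x$id_strategy, "\n")
  if (length(x$column_map) > 0L) {
    cat("  columns:", paste(names(x$column_map), unlist(x$column_map),
                            sep = " <- ", collapse = ", "), "\n")
  }
  invisible(x)
}
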