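# Batch CSV/TSV processing: the file-level surface behind the CLI's
# `code` subcommand. Dialect is chosen by extension (.csv comma,
# .tsv/.txt tab) unless overridden; files are UTF-8 with a header row.

read_table_auto <- function(path, delim = NULL) {
  if (!file.exists(path)) abort_io(sprintf("input file '%s' does not exist", path))
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                    na = character(), progress = FALSE, show_col_types = FALSE)
}

write_table_auto <- function(data, path, delim = NULL) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  readr::write_delim(data, path, delim = delim, na = "", progress = FALSE)
  invisible(path)
}

#' Encode or decode a metadata table in bulk
#'
#' The batch engine behind the command-line `code` subcommand. Encoding
#' appends a `clarid` column to the input rows; decoding emits one
#' column per component (plus `condition_name` when requested). Failed
#' rows are collected, not fatal (unless `strict = TRUE`), and row order
#' is preserved. Outputs contain no timestamps, so identical inputs and
#' configuration give byte-identical output files.
#'
#' @param input Input tibble, or path to a CSV/TSV file (UTF-8, header
#'   row; dialect by extension, overridable via `delim`).
#' @param action `"encode"` or `"decode"`.
#' @param format `"human"` or `"stub"`.
#' @param entity `"biosample"` or `"subject"`.
#' @param codebook A `clarid_codebook` or a path to a codebook YAML.
#' @param icd10 A `clarid_icd10` table or a path to an ICD-10 JSON file.
#' @param mapping Optional `clarid_mapping` or path to a mapping YAML,
#'   applied before encoding.
#' @param with_condition_name When decoding, add a `condition_name`
#'   column.
#' @param id_col Identifier column name (decode input / encode output).
#' @param output Optional output file path (CSV/TSV by extension).
#' @param strict Abort on the first failed row instead of collecting it.
#' @param delim Optional single-character delimiter override for file
#'   input/output.
#' @return A `clarid_batch` result: row counts (`rows_in`,
#'   `rows_encoded`, `rows_failed`), the per-row `failures` tibble, and
#'   the result table in `$data`.
#' @examples
#' library(tibble)
#' tbl <- tibble(study = "COPDStudy", subject_id = 1001, type = "Case",
#'               condition = "J44.9", sex = "Male", age_group = "A40_49")
#' res <- clarid_batch(tbl, action = "encode", format = "human", entity = "subject")
#' res$data$clarid
#' @export
clarid_batch <- function(input, action = c("encode", "decode"),
                         format = c("human", "stub"),
                         entity = c("biosample", "subject"),
                         codebook = load_codebook(), icd10 = load_icd10(),
                         mapping = NULL, with_condition_name = FALSE,
                         id_col = "clarid", output = NULL, strict = FALSE,
                         delim = NULL) {
  action <- match.arg(action)
  format <- match.arg(format)
  entity <- match.arg(entity)
  if (is.character(codebook)) codebook <- load_codebook(codebook)
  if (is.character(icd10)) icd10 <- load_icd10(icd10)
  if (is.character(mapping)) mapping <- load_mapping(mapping)
  data <- if (is.character(input)) read_table_auto(input, delim) else tibble::as_tibble(input)
  rows_in <- nrow(data)
  on_error <- if (strict) "abort" else "na"
  if (action == "encode") {
    work <- if (!is.null(mapping)) apply_mapping(data, mapping, codebook) else data
    res <- clarid_encode(work, entity, format, codebook, icd10, on_error = on_error)
    out <- dplyr::mutate(data, !!id_col := res$clarid)
    failures <- attr(res, "clarid_errors")
  } else {
    out <- clarid_decode(data, entity, format, codebook, icd10, col = id_col,
                         with_condition_name = with_condition_name,
                         on_error = on_error)
    failures <- attr(out, "clarid_errors")
  }
  if (!is.null(output)) write_table_auto(out, output, delim)
  structure(
    list(
      action = action, format = format, entity = entity,
      rows_in = rows_in,
      rows_encoded = rows_in - nrow(failures),
      rows_failed = nrow(failures),
      failures = failures,
      data = out,
      output = output
    ),
    class = "clarid_batch"
  )
}

#' @export
print.clarid_batch <- function(x, ...) {
  cat(sprintf("<clarid_batch> %s %s %s: %d rows in, %d ok, %d failed\n",
              x$action, x$entity, x$format, x$rows_in, x$rows_encoded, x$rows_failed))
  if (x$rows_failed > 0L) {
    head_f <- utils::head(x$failures, 5L)
    apply(head_f, 1L, function(row) {
      cat(sprintf("  row %s [%s] %s\n", row[["row"]], row[["error_class"]], row[["error"]]))
    })
    if (x$rows_failed > 5L) cat("  ...\n")
  }
  invisible(x)
}

#' Tidy a batch result
#'
#' @param x A `clarid_batch` result.
#' @param ... Unused.
#' @return `tidy()`: the per-row failures tibble; `glance()`: a one-row
#'   summary with the row counts.
#' @method tidy clarid_batch
#' @export
tidy.clarid_batch <- function(x, ...) x$failures

#' @rdname tidy.clarid_batch
#' @method glance clarid_batch
#' @export
glance.clarid_batch <- function(x, ...) {
  tibble::tibble(
    action = x$action, entity = x$entity, format = x$format,
    rows_in = x$rows_in, rows_encoded = x$rows_encoded, rows_failed = x$rows_failed
  )
}

#' Plot batch and validation outcomes
#'
#' `autoplot.clarid_batch()` shows processed vs failed row counts (failed
#' rows broken down by error class); `autoplot.clarid_validation()` shows
#' validation findings by severity.
#'
#' @param object A `clarid_batch` or `clarid_validation` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @method autoplot clarid_batch
#' @export
autoplot.clarid_batch <- function(object, ...) {
  counts <- dplyr::bind_rows(
    tibble::tibble(outcome = "encoded", class = "ok", n = object$rows_encoded),
    dplyr::count(object$failures, class = .data$error_class, name = "n") |>
      dplyr::mutate(outcome = "failed")
  )
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$outcome, y = .data$n, fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      title = sprintf("ClarID batch %s (%s, %s format)", object$action, object$entity, object$format),
      x = NULL, y = "rows", fill = "error class"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.clarid_batch
#' @method autoplot clarid_validation
#' @export
autoplot.clarid_validation <- function(object, ...) {
  f <- object$findings
  if (nrow(f) == 0L) {
    f <- tibble::tibble(severity = "none", n = 0L)
  } else {
    f <- dplyr::count(f, .data$severity, name = "n")
  }
  ggplot2::ggplot(f, ggplot2::aes(x = .data$severity, y = .data$n, fill = .data$severity)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(title = "Codebook validation findings", x = NULL, y = "findings") +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot
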