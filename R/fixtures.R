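# Seeded test-surface generators: valid records sampled from the
# codebook vocabularies, the worked identifier examples, and an
# adversarial corpus for decoder error-totality checks.

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.study_pool <- c("COPDStudy", "AsthmaTrial", "BrainBank", "GTEx_v8",
                 "UK_BB_2025", "CNAG_Cohort", "LiverRegistry")

.duration_pool <- c("P1D", "P1W", "P2W", "P1M", "P6M", "P1Y", "P0N")

#' Generate seeded valid records
#'
#' Samples `n` valid biosample or subject records uniformly from the
#' codebook vocabularies and the ICD-10 table: every generated record
#' passes encoder validation, and identical `(seed, arguments)` give
#' identical output. `subject_id` is drawn from 1..99999, durations from
#' a fixed valid pool (`P1D P1W P2W P1M P6M P1Y P0N`), batch/replicate
#' (biosamples) are each present with probability `optional_rate`, and
#' with probability `na_rate` the NA-policy fields (`condition`, and for
#' biosamples `duration`/`assay`) independently take their "not
#' available" encodings.
#'
#' @param n Number of records.
#' @param entity `"biosample"` or `"subject"`.
#' @param seed Integer seed; the global RNG state is restored afterwards.
#' @param cb A `clarid_codebook`.
#' @param table A `clarid_icd10` table.
#' @param optional_rate Probability of including batch / replicate.
#' @param na_rate Probability of an NA-policy field per record.
#' @return A tibble with one record per row (canonical columns).
#' @examples
#' generate_records(3, "subject", seed = 42)
#' @export
generate_records <- function(n, entity = c("biosample", "subject"), seed = 1L,
                             cb = load_codebook(), table = load_icd10(),
                             optional_rate = 0.3, na_rate = 0.1) {
  entity <- match.arg(entity)
  stopifnot(n >= 0, optional_rate >= 0, optional_rate <= 1, na_rate >= 0, na_rate <= 1)
  vocab <- function(comp, drop = character(0)) {
    terms <- setdiff(component_table(cb, entity, comp)$term, drop)
    if (length(terms) == 0L) abort_config(sprintf("empty vocabulary for %s.%s", entity, comp))
    sample(terms, n, replace = TRUE)
  }
  # the "not available" encodings are governed by na_rate, not sampled
  codes <- setdiff(table$code, "NA")
  with_local_seed(seed, {
    if (entity == "biosample") {
      out <- tibble::tibble(
        project = vocab("project"),
        species = vocab("species"),
        subject_id = sample.int(99999L, n, replace = TRUE),
        tissue = vocab("tissue"),
        sample_type = vocab("sample_type"),
        assay = vocab("assay", drop = "Not_available"),
        condition = sample(codes, n, replace = TRUE),
        timepoint = vocab("timepoint"),
        duration = sample(setdiff(.duration_pool, "P0N"), n, replace = TRUE),
        batch = ifelse(stats::runif(n) < optional_rate, sample.int(99L, n, replace = TRUE), NA_integer_),
        replicate = ifelse(stats::runif(n) < optional_rate, sample.int(99L, n, replace = TRUE), NA_integer_)
      )
      na_hit <- function(x, value) ifelse(stats::runif(n) < na_rate, value, x)
      out$condition <- na_hit(out$condition, "NA")
      out$duration <- na_hit(out$duration, "P0N")
      out$assay <- na_hit(out$assay, "Not_available")
    } else {
      out <- tibble::tibble(
        study = sample(.study_pool, n, replace = TRUE),
        subject_id = sample.int(99999L, n, replace = TRUE),
        type = vocab("type"),
        condition = ifelse(stats::runif(n) < na_rate, "NA", sample(codes, n, replace = TRUE)),
        sex = vocab("sex"),
        age_group = vocab("age_group")
      )
    }
    out
  })
}

#' Worked identifier examples
#'
#' The reference (record, human identifier) pairs used as exact
#' encoding checks against the bundled codebook: the CNAG_Test and
#' TARGET_AML biosamples and the COPDStudy and TCGA-LIHC subjects.
#'
#' @return A tibble with columns `entity`, `expected_human` and a
#'   `record` list-column.
#' @export
worked_examples <- function() {
  tibble::tibble(
    entity = c("biosample", "subject", "biosample", "subject"),
    expected_human = c(
      "CNAG_Test-HomSap-00001-LIV-TUM-RNA-C22.0-TRT-P1W-B01-R05",
      "COPDStudy-01001-Case-J44.9-Male-A40_49",
      "TARGET_AML-HomSap-00002-BMR-PRI-NAV-C92.0-COL-P0N",
      "TCGA_LIHC-00003-Case-C22.0-Male-A40_49"
    ),
    record = list(
      list(project = "CNAG_Test", species = "Human", subject_id = 1,
           tissue = "Liver", sample_type = "Tumor", assay = "RNA_seq",
           condition = "C22.0", timepoint = "Treatment", duration = "P1W",
           batch = 1, replicate = 5),
      list(study = "COPDStudy", subject_id = 1001, type = "Case",
           condition = "J44.9", sex = "Male", age_group = "A40_49"),
      list(project = "TARGET_AML", species = "Human", subject_id = 2,
           tissue = "Bone_marrow", sample_type = "Primary", assay = "Not_available",
           condition = "C92.0", timepoint = "Collection", duration = "P0N"),
      list(study = "TCGA-LIHC", subject_id = 3, type = "Case",
           condition = "C22.0", sex = "Male", age_group = "A40_49")
    )
  )
}

#' Adversarial decoder inputs
#'
#' A seeded fuzz corpus: random printable-ASCII strings of length 0-64
#' plus one-character mutations (substitution, deletion, insertion) of
#' valid identifiers. Decoders must classify every element — either a
#' structured error or, for the rare accidentally valid mutant, a record
#' that re-encodes consistently.
#'
#' @param seed Integer seed.
#' @param n Number of random strings (the mutation set is added on top).
#' @param cb,table Codebook and ICD-10 table for the mutated identifiers.
#' @return Character vector of inputs (stable for a fixed seed).
#' @export
adversarial_inputs <- function(seed = 1L, n = 100L,
                               cb = load_codebook(), table = load_icd10()) {
  ascii <- strsplit(rawToChar(as.raw(32:126)), "")[[1L]]
  with_local_seed(seed, {
    random <- vapply(seq_len(n), function(i) {
      len <- sample(0:64, 1L)
      paste0(sample(ascii, len, replace = TRUE), collapse = "")
    }, character(1))
    recs_b <- generate_records(5L, "biosample", seed = seed + 1L, cb = cb, table = table)
    recs_s <- generate_records(5L, "subject", seed = seed + 2L, cb = cb, table = table)
    valid <- c(
      clarid_encode(recs_b, "biosample", "human", cb, table)$clarid,
      clarid_encode(recs_b, "biosample", "stub", cb, table)$clarid,
      clarid_encode(recs_s, "subject", "human", cb, table)$clarid,
      clarid_encode(recs_s, "subject", "stub", cb, table)$clarid
    )
    mutate1 <- function(id) {
      i <- sample.int(nchar(id), 1L)
      op <- sample(c("sub", "del", "ins"), 1L)
      switch(op,
        sub = paste0(substr(id, 1L, i - 1L), sample(ascii, 1L), substr(id, i + 1L, nchar(id))),
        del = paste0(substr(id, 1L, i - 1L), substr(id, i + 1L, nchar(id))),
        ins = paste0(substr(id, 1L, i), sample(ascii, 1L), substr(id, i, nchar(id)))
      )
    }
    c("", random, vapply(valid, mutate1, character(1), USE.NAMES = FALSE))
  })
}
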