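test_that("the worked reference records encode byte-for-byte in human format", {
  we <- worked_examples()
  for (i in seq_len(nrow(we))) {
    id <- encode_record(we$record[[i]], we$entity[i], "human")
    expect_identical(id, we$expected_human[i])
  }
})

test_that("duration tokens are capped at three characters", {
  expect_identical(validate_duration("P1W"), "P1W")
  expect_identical(validate_duration("P0N"), "P0N")
  expect_identical(validate_duration("P6M"), "P6M")
  expect_error(validate_duration("P10W"), class = "clarid_format_error")
  expect_error(validate_duration("1W"), class = "clarid_format_error")
  expect_error(validate_duration("P1X"), class = "clarid_format_error")
  expect_error(validate_duration("PW"), class = "clarid_format_error")
})

test_that("condition stubs are 5 characters: base62 rank plus the reserved 01 suffix", {
  expect_identical(encode_condition_stub("NA", test_icd), "00001")
  tok <- encode_condition_stub("C22.0", test_icd)
  expect_identical(nchar(tok), 5L)
  expect_identical(substr(tok, 4, 5), "01")
  expect_identical(substr(tok, 1, 3), base62_encode(condition_rank(test_icd, "C22.0"), 3))
  # decode inverts encode over the whole bundled table
  for (code in test_icd$code) {
    expect_identical(decode_condition_stub(encode_condition_stub(code, test_icd), test_icd), code)
  }
  expect_error(encode_condition_stub("Z99.99", test_icd), class = "clarid_lookup_error")
})

test_that("stub identifiers have the documented fixed-width structure", {
  we <- worked_examples()
  stub1 <- encode_record(we$record[[1]], "biosample", "stub")
  expect_identical(nchar(stub1), 24L)
  expect_true(startsWith(stub1, "CT01001LTR"))
  expect_true(endsWith(stub1, "T1WB01R05"))
  expect_identical(substr(stub1, 11, 15), encode_condition_stub("C22.0", test_icd))

  stub2 <- encode_record(we$record[[2]], "subject", "stub")
  expect_identical(nchar(stub2), 21L)
  expect_identical(
    stub2,
    paste0("COPDStudy", "0G9", "C", encode_condition_stub("J44.9", test_icd), "M", "A4")
  )
})

test_that("human identifiers split into the documented field counts", {
  we <- worked_examples()
  full <- encode_record(we$record[[1]], "biosample", "human")
  expect_length(strsplit(full, "-", fixed = TRUE)[[1]], 11L)
  no_opt <- we$record[[1]]
  no_opt$batch <- NULL; no_opt$replicate <- NULL
  expect_length(strsplit(encode_record(no_opt, "biosample", "human"), "-", fixed = TRUE)[[1]], 9L)
  batch_only <- no_opt; batch_only$batch <- 3
  expect_length(strsplit(encode_record(batch_only, "biosample", "human"), "-", fixed = TRUE)[[1]], 10L)
  subj <- encode_record(we$record[[2]], "subject", "human")
  expect_length(strsplit(subj, "-", fixed = TRUE)[[1]], 6L)
})

test_that("missing values fall back to their dedicated encodings", {
  rec <- list(project = "CNAG_Test", species = "Human", subject_id = 7,
              tissue = "Liver", sample_type = "Normal",
              timepoint = "Baseline")
  id <- encode_biosample(rec, test_cb, test_icd, "human")
  tokens <- strsplit(id, "-", fixed = TRUE)[[1]]
  expect_identical(tokens[6], "NAV")  # assay not available
  expect_identical(tokens[7], "NA")   # condition sentinel
  expect_identical(tokens[9], "P0N")  # duration not available
})

test_that("a free-text project encodes in human format but not in stub format", {
  rec <- list(project = "MyLocalProject", species = "Human", subject_id = 1,
              tissue = "Liver", sample_type = "Tumor", assay = "RNA_seq",
              condition = "C22.0", timepoint = "Treatment", duration = "P1W")
  expect_match(encode_biosample(rec, test_cb, test_icd, "human"), "^MyLocalProject-")
  expect_error(encode_biosample(rec, test_cb, test_icd, "stub"),
               "stub_code", class = "clarid_config_error")
})

test_that("hyphens in free-form study names are sanitized in human format only", {
  rec <- list(study = "TCGA-LIHC", subject_id = 3, type = "Case",
              condition = "C22.0", sex = "Male", age_group = "A40_49")
  expect_match(encode_subject(rec, test_cb, test_icd, "human"), "^TCGA_LIHC-")
  expect_match(encode_subject(rec, test_cb, test_icd, "stub"), "^TCGA-LIHC")
})

test_that("invalid component values raise classified errors naming the component", {
  base <- worked_examples()$record[[1]]
  bad_tissue <- base; bad_tissue$tissue <- "Spleen"
  expect_error(encode_biosample(bad_tissue, test_cb, test_icd, "human"),
               "tissue", class = "clarid_vocabulary_error")
  bad_sid <- base; bad_sid$subject_id <- 100000
  expect_error(encode_biosample(bad_sid, test_cb, test_icd, "human"),
               class = "clarid_range_error")
  bad_cond <- base; bad_cond$condition <- "X00.0"
  expect_error(encode_biosample(bad_cond, test_cb, test_icd, "human"),
               class = "clarid_lookup_error")
  bad_batch <- base; bad_batch$batch <- 100
  expect_error(encode_biosample(bad_batch, test_cb, test_icd, "human"),
               class = "clarid_range_error")
})

test_that("encoding is deterministic", {
  recs <- generate_records(50, "biosample", seed = 3)
  for (fmt in c("human", "stub")) {
    a <- clarid_encode(recs, "biosample", fmt, test_cb, test_icd)$clarid
    b <- clarid_encode(recs, "biosample", fmt, test_cb, test_icd)$clarid
    expect_identical(a, b)
  }
})

test_that("stub lengths follow the width formula", {
  for (entity in c("biosample", "subject")) {
    recs <- generate_records(200, entity, seed = 8)
    ids <- clarid_encode(recs, entity, "stub", test_cb, test_icd)$clarid
    if (entity == "biosample") {
      proj_stub <- test_cb$lookup[test_cb$lookup$component == "project", ]
      plen <- nchar(proj_stub$stub_code[match(recs$project, proj_stub$term)])
      dlen <- nchar(recs$duration) - 1L
      optn <- (!is.na(recs$batch)) + (!is.na(recs$replicate))
      # fixed core: species 2 + subject_id 3 + tissue/sample_type/assay 3 +
      # condition 5 + timepoint 1 = 14, plus the duration payload
      expect_identical(nchar(ids), as.integer(plen + 14L + dlen + 3L * optn))
    } else {
      expect_identical(nchar(ids), as.integer(nchar(recs$study) + 12L))
    }
  }
})
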