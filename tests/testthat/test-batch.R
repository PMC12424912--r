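test_that("batch encoding collects per-row failures without aborting", {
  recs <- generate_records(10, "biosample", seed = 14)
  recs$tissue[4] <- "Spleen"  # not in the codebook
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(recs, f, na = "")
  res <- clarid_batch(f, "encode", "human", "biosample", test_cb, test_icd)
  expect_identical(res$rows_in, 10L)
  expect_identical(res$rows_encoded, 9L)
  expect_identical(res$rows_failed, 1L)
  expect_identical(res$failures$row, 4L)
  expect_identical(res$rows_in, res$rows_encoded + res$rows_failed)
  expect_true(is.na(res$data$clarid[4]))
  # strict mode aborts instead
  expect_error(
    clarid_batch(f, "encode", "human", "biosample", test_cb, test_icd, strict = TRUE),
    class = "clarid_vocabulary_error"
  )
})

test_that("encode then decode of a fixture table reproduces the component columns", {
  for (entity in c("biosample", "subject")) {
    src <- clarid_example(paste0("example-", entity, "s.csv"))
    out1 <- withr::local_tempfile(fileext = ".csv")
    enc <- clarid_batch(src, "encode", "stub", entity, test_cb, test_icd, output = out1)
    expect_identical(enc$rows_failed, 0L)
    dec <- clarid_batch(out1, "decode", "stub", entity, test_cb, test_icd)
    expect_identical(dec$rows_failed, 0L)
    orig <- claridr:::read_table_auto(src)
    for (cn in names(orig)) {
      a <- orig[[cn]]; b <- as.character(dec$data[[cn]])
      a[a == ""] <- NA_character_
      expect_identical(b, a, info = paste(entity, cn))
    }
  }
})

test_that("batch outputs are byte-identical across repeated runs", {
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  src <- clarid_example("example-subjects.csv")
  clarid_batch(src, "encode", "human", "subject", test_cb, test_icd, output = f1)
  clarid_batch(src, "encode", "human", "subject", test_cb, test_icd, output = f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("tsv dialect is selected by extension", {
  recs <- generate_records(5, "subject", seed = 9)
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(recs, f, na = "")
  res <- clarid_batch(f, "encode", "human", "subject", test_cb, test_icd)
  expect_identical(res$rows_failed, 0L)
  expect_identical(nrow(res$data), 5L)
})

test_that("decode emits per-component columns plus condition_name on request", {
  recs <- generate_records(5, "subject", seed = 10, na_rate = 0)
  enc <- clarid_batch(recs, "encode", "human", "subject", test_cb, test_icd)
  dec <- clarid_batch(enc$data, "decode", "human", "subject", test_cb, test_icd,
                      with_condition_name = TRUE)
  expect_true(all(c("study", "subject_id", "type", "condition", "sex",
                    "age_group", "condition_name") %in% names(dec$data)))
  expect_identical(dec$data$condition_name, condition_name(test_icd, recs$condition))
})

test_that("missing required columns fail before processing", {
  expect_error(
    clarid_batch(tibble::tibble(study = "S"), "encode", "human", "subject",
                 test_cb, test_icd),
    class = "clarid_config_error"
  )
})

test_that("batch results summarise via glance and tidy", {
  recs <- generate_records(6, "subject", seed = 15)
  recs$sex[2] <- "unknown-token"
  res <- clarid_batch(recs, "encode", "human", "subject", test_cb, test_icd)
  g <- glance(res)
  expect_identical(g$rows_failed, 1L)
  expect_identical(tidy(res), res$failures)
  p <- ggplot2::autoplot(res)
  expect_s3_class(p, "ggplot")
})
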