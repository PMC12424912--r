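test_that("the printed human identifiers decode to their records", {
  rec <- decode_identifier("COPDStudy-01001-Case-J44.9-Male-A40_49",
                           "subject", test_cb, test_icd, "human")
  expect_records_equal(rec, list(study = "COPDStudy", subject_id = 1001,
                                 type = "Case", condition = "J44.9",
                                 sex = "Male", age_group = "A40_49"))

  rec2 <- decode_identifier("TARGET_AML-HomSap-00002-BMR-PRI-NAV-C92.0-COL-P0N",
                            "biosample", test_cb, test_icd, "human")
  expect_identical(rec2$tissue, "Bone_marrow")
  expect_identical(rec2$sample_type, "Primary")
  expect_identical(rec2$assay, "Not_available")
  expect_identical(rec2$condition, "C92.0")
  expect_true(is.na(rec2$batch) && is.na(rec2$replicate))
})

test_that("truncated and malformed identifiers give structure errors", {
  expect_error(decode_identifier("CNAG_Test-HomSap-00001-LIV", "biosample",
                                 test_cb, test_icd, "human"),
               class = "clarid_structure_error")
  expect_error(decode_identifier("", "subject", test_cb, test_icd, "human"),
               class = "clarid_structure_error")
  expect_error(decode_identifier("", "biosample", test_cb, test_icd, "stub"),
               class = "clarid_structure_error")
  # malformed optional
  expect_error(
    decode_identifier("CNAG_Test-HomSap-00001-LIV-TUM-RNA-C22.0-TRT-P1W-B1",
                      "biosample", test_cb, test_icd, "human"),
    class = "clarid_structure_error"
  )
})

test_that("subject parsing is right-anchored so the study may contain hyphens", {
  id <- "My-Odd-Study-00042-Case-NA-Female-A20_29"
  rec <- decode_identifier(id, "subject", test_cb, test_icd, "human")
  expect_identical(rec$study, "My-Odd-Study")
  expect_equal(rec$subject_id, 42)
})

test_that("optional stub suffixes strip greedily from the right", {
  got <- strip_optional_suffixes("CT01001LTR0N401T1WB01R05")
  expect_identical(got$core, "CT01001LTR0N401T1W")
  expect_identical(got$batch, 1L)
  expect_identical(got$replicate, 5L)
  expect_identical(strip_optional_suffixes("ABC"),
                   list(core = "ABC", batch = NA_integer_, replicate = NA_integer_))
  got2 <- strip_optional_suffixes("XYZB07")
  expect_identical(got2$batch, 7L)
  expect_true(is.na(got2$replicate))
})

test_that("project prefix resolution inverts the encoder and reports failures distinctly", {
  we <- worked_examples()
  stub <- encode_record(we$record[[1]], "biosample", "stub")
  core <- strip_optional_suffixes(stub)$core
  hit <- resolve_project_prefix(core, test_cb, test_icd)
  expect_identical(hit$project, "CNAG_Test")
  expect_identical(hit$remainder, substr(core, 3, nchar(core)))

  stub3 <- encode_record(we$record[[3]], "biosample", "stub")
  expect_identical(resolve_project_prefix(stub3, test_cb, test_icd)$project, "TARGET_AML")

  err <- tryCatch(resolve_project_prefix("QQ01001LTR0000101T1W", test_cb, test_icd),
                  clarid_error = identity)
  expect_s3_class(err, "clarid_decode_error")
  expect_match(conditionMessage(err), "no project stub matches")
})

test_that("stub decoding inverts stub encoding, optionals included", {
  we <- worked_examples()
  for (i in c(1, 3)) {
    stub <- encode_record(we$record[[i]], "biosample", "stub")
    rec <- decode_identifier(stub, "biosample", test_cb, test_icd, "stub")
    expect_records_equal(rec, we$record[[i]])
  }
  stub <- encode_record(we$record[[2]], "subject", "stub")
  rec <- decode_identifier(stub, "subject", test_cb, test_icd, "stub")
  expect_records_equal(rec, we$record[[2]])
})

test_that("decoding is strict about case and interior whitespace but trims the ends", {
  id <- "COPDStudy-01001-Case-J44.9-Male-A40_49"
  expect_no_error(decode_identifier(paste0("  ", id, "\n"), "subject", test_cb, test_icd, "human"))
  expect_error(decode_identifier(tolower(id), "subject", test_cb, test_icd, "human"),
               class = "clarid_error")
})

test_that("condition names attach on request, with a placeholder for the sentinel", {
  rec <- decode_identifier("COPDStudy-01001-Case-J44.9-Male-A40_49",
                           "subject", test_cb, test_icd, "human",
                           with_condition_name = TRUE)
  expect_identical(rec$condition_name,
                   "chronic obstructive pulmonary disease, unspecified")
  tbl <- attach_condition_name(data.frame(condition = c("C22.0", "C92.0", "NA")), test_icd)
  expect_identical(tbl$condition_name,
                   c("liver cell carcinoma", "acute myeloblastic leukemia", "not available"))
})

test_that("human and stub decodings of the same record agree", {
  recs <- generate_records(100, "biosample", seed = 21)
  h <- clarid_encode(recs, "biosample", "human", test_cb, test_icd)$clarid
  s <- clarid_encode(recs, "biosample", "stub", test_cb, test_icd)$clarid
  dh <- clarid_decode(h, "biosample", "human", test_cb, test_icd)
  ds <- clarid_decode(s, "biosample", "stub", test_cb, test_icd)
  expect_equal(dh, ds, ignore_attr = TRUE)
})

test_that("distinct records give distinct stub identifiers", {
  recs <- generate_records(1000, "subject", seed = 31)
  ids <- clarid_encode(recs, "subject", "stub", test_cb, test_icd)$clarid
  expect_identical(anyDuplicated(ids[!duplicated(recs)]), 0L)
})

test_that("every adversarial input yields a classified error or a consistent record", {
  corpus <- adversarial_inputs(seed = 404, n = 150, cb = test_cb, table = test_icd)
  for (s in corpus) {
    for (entity in c("biosample", "subject")) {
      for (fmt in c("human", "stub")) {
        out <- tryCatch(
          decode_identifier(s, entity, test_cb, test_icd, fmt),
          clarid_error = function(e) "classified"
        )
        if (!identical(out, "classified")) {
          # an accidental valid mutant must re-encode consistently: either
          # to the same string or (after canonicalization, e.g. hyphen
          # sanitization in a free-form study) to an identifier that
          # decodes to the same record
          reenc <- clarid_encode(out, entity, fmt, test_cb, test_icd)$clarid
          if (!identical(reenc, trimws(s))) {
            redec <- decode_identifier(reenc, entity, test_cb, test_icd, fmt)
            expect_equal(as.data.frame(redec), as.data.frame(out))
          }
        }
      }
    }
  }
  expect_true(TRUE)  # reached without an unclassified condition
})
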