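test_that("the bundled codebook carries the reference entries", {
  human <- resolve_term(test_cb, "biosample", "species", "Human")
  expect_identical(human$code, "HomSap")
  expect_identical(human$stub_code, "01")
  expect_identical(human$id, "NCBITaxon:9606")
  liver <- resolve_term(test_cb, "biosample", "tissue", "Liver")
  expect_identical(liver$code, "LIV")
  expect_identical(liver$id, "UBERON:0002107")
  rna <- resolve_term(test_cb, "biosample", "assay", "RNA_seq")
  expect_identical(rna$code, "RNA")
  expect_identical(rna$stub_code, "R")
})

test_that("loading rejects structurally invalid codebooks with the offending path", {
  empty <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", empty)
  expect_error(load_codebook(empty), "missing entity", class = "clarid_validation_error")

  raw <- codebook_raw()
  raw$biosample$tissue$Brain$stub_code <- "L"  # collides with Liver
  expect_error(load_codebook(write_codebook(raw)),
               "biosample\\.tissue.*duplicate stub_code",
               class = "clarid_validation_error")

  expect_error(load_codebook(tempfile()), class = "clarid_io_error")
})

test_that("term lookup is exact and case-sensitive", {
  expect_error(resolve_term(test_cb, "biosample", "tissue", "liver"),
               class = "clarid_vocabulary_error")
  err <- tryCatch(resolve_term(test_cb, "biosample", "tissue", "liver"),
                  clarid_error = identity)
  expect_match(conditionMessage(err), "Liver")  # lists valid terms
})

test_that("reverse lookup inverts codes and stub codes", {
  expect_identical(reverse_lookup(test_cb, "biosample", "tissue", "LIV", "human"), "Liver")
  expect_identical(reverse_lookup(test_cb, "biosample", "tissue", "L", "stub"), "Liver")
  expect_error(reverse_lookup(test_cb, "subject", "sex", "X", "stub"),
               class = "clarid_decode_error")
})

test_that("every printed vocabulary token resolves in the bundled codebook", {
  human_codes <- list(
    c("biosample", "species", "HomSap"), c("biosample", "tissue", "LIV"),
    c("biosample", "sample_type", "TUM"), c("biosample", "assay", "RNA"),
    c("biosample", "timepoint", "TRT"), c("biosample", "tissue", "BMR"),
    c("biosample", "sample_type", "PRI"), c("biosample", "assay", "NAV"),
    c("biosample", "timepoint", "COL"), c("subject", "type", "Case"),
    c("subject", "sex", "Male"), c("subject", "age_group", "A40_49")
  )
  for (tk in human_codes) {
    expect_no_error(reverse_lookup(test_cb, tk[1], tk[2], tk[3], "human"))
  }
  stub_codes <- list(
    c("biosample", "species", "01"), c("biosample", "tissue", "L"),
    c("biosample", "sample_type", "T"), c("biosample", "assay", "R"),
    c("biosample", "assay", "n"), c("biosample", "timepoint", "C"),
    c("subject", "sex", "M"), c("subject", "age_group", "A4")
  )
  for (tk in stub_codes) {
    expect_no_error(reverse_lookup(test_cb, tk[1], tk[2], tk[3], "stub"))
  }
})

test_that("term -> code -> term and term -> stub -> term are identities codebook-wide", {
  tab <- test_cb$lookup
  for (i in seq_len(nrow(tab))) {
    expect_identical(
      reverse_lookup(test_cb, tab$entity[i], tab$component[i], tab$code[i], "human"),
      tab$term[i]
    )
    expect_identical(
      reverse_lookup(test_cb, tab$entity[i], tab$component[i], tab$stub_code[i], "stub"),
      tab$term[i]
    )
  }
})
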