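# Shared fixtures: the bundled codebook and ICD-10 table, loaded once,
# plus helpers to write mutated codebook files.

test_cb <- load_codebook()
test_icd <- load_icd10()

codebook_raw <- function() {
  yaml::read_yaml(clarid_example("clarid-codebook.yaml"))
}

write_codebook <- function(raw) {
  path <- withr::local_tempfile(fileext = ".yaml", .local_envir = parent.frame())
  yaml::write_yaml(raw, path)
  path
}

encode_record <- function(record, entity, fmt, cb = test_cb, icd = test_icd) {
  if (entity == "biosample") encode_biosample(record, cb, icd, fmt)
  else encode_subject(record, cb, icd, fmt)
}

# field-wise record comparison after canonicalization (numbers as numbers,
# absent optionals as NA)
expect_records_equal <- function(decoded, reference) {
  for (cn in intersect(names(reference), names(decoded))) {
    a <- reference[[cn]]
    b <- decoded[[cn]]
    if (is.numeric(a) || is.numeric(b)) {
      expect_equal(as.numeric(a), as.numeric(b), info = cn)
    } else {
      expect_identical(as.character(a), as.character(b), info = cn)
    }
  }
}
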