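test_that("ages bin into the codebook's decade groups with floor semantics", {
  bins <- age_bins_from_codebook(test_cb)
  expect_identical(bin_age(45, bins), "A40_49")
  expect_identical(bin_age(0, bins), "A0_9")
  expect_identical(bin_age(49.9, bins), "A40_49")
  expect_identical(bin_age(50, bins), "A50_59")
  expect_identical(bin_age(99, bins), "A90_99")
  expect_error(bin_age(120, bins), class = "clarid_range_error")
  expect_error(bin_age(-1, bins), class = "clarid_range_error")
})

test_that("the bundled mapping config recodes, bins and derives subject ids", {
  raw <- claridr:::read_table_auto(clarid_example("example-subjects-raw.csv"))
  mapping <- load_mapping(clarid_example("example-mapping.yaml"))
  mapped <- apply_mapping(raw, mapping, test_cb)
  expect_identical(mapped$sex[1], "Female")
  expect_true(all(mapped$age_group %in% claridr:::component_table(test_cb, "subject", "age_group")$term))
  # rows 2 and 4 share a UUID -> same derived subject_id
  expect_identical(mapped$subject_id[2], mapped$subject_id[4])
  # first appearance order: ids are dense from 1
  expect_identical(sort(unique(mapped$subject_id)), seq_len(9L))
  # "'--" cohort value is treated as missing
  expect_true(is.na(mapped$type[10]))
})

test_that("a declared-missing value becomes a row error at encode time", {
  raw <- claridr:::read_table_auto(clarid_example("example-subjects-raw.csv"))
  mapping <- load_mapping(clarid_example("example-mapping.yaml"))
  mapped <- apply_mapping(raw, mapping, test_cb)
  res <- clarid_encode(mapped, "subject", "human", test_cb, test_icd, on_error = "na")
  errs <- attr(res, "clarid_errors")
  expect_true(10L %in% errs$row)
  expect_identical(errs$error_class[errs$row == 10L], "vocabulary")
})

test_that("mapping configs are validated up front", {
  expect_error(claridr:::new_mapping(list(entity = "plate")), class = "clarid_config_error")
  expect_error(claridr:::new_mapping(list(entity = "subject", columns = list(tissue = "x"))),
               class = "clarid_config_error")
  expect_error(claridr:::new_mapping(list(entity = "subject", id_strategy = "hash")),
               class = "clarid_config_error")
  bad_bins <- list(entity = "subject", age_bins = list(
    list(min = 0, max = 50, term = "A0_9"), list(min = 40, max = 99, term = "A40_49")
  ))
  expect_error(claridr:::new_mapping(bad_bins), class = "clarid_config_error")
  raw <- tibble::tibble(x = 1)
  mapping <- claridr:::new_mapping(list(entity = "subject", columns = list(study = "absent")))
  expect_error(apply_mapping(raw, mapping, test_cb), class = "clarid_config_error")
})
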