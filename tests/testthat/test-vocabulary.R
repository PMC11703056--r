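# Vocabulary store: ATHENA loading, local mappings, ICD-10-GM normalisation,
# standard-concept resolution.

test_that("the bundled fixture loads and every Maps-to target is standard", {
  store <- h_store()
  expect_s3_class(store, "vocabulary_store")
  # oracle: linear scan over the raw frames
  std_ids <- store$concepts$concept_id[store$concepts$standard_concept == "S"]
  expect_true(all(store$maps_to$target_id %in% std_ids))
  expect_true(all(store$maps_to$target_id %in% store$concepts$concept_id))
  expect_false(any(store$concepts$concept_id == 0))
})

test_that("ATHENA loader fails fast on structural problems", {
  dir <- system.file("extdata", "vocab", package = "hdlomop")
  con <- file.path(dir, "CONCEPT.csv")
  rel <- file.path(dir, "CONCEPT_RELATIONSHIP.csv")

  tmp <- withr::local_tempfile(fileext = ".csv")
  x <- readLines(con)
  writeLines(c(x, x[[2]]), tmp)  # duplicate concept row
  expect_error(load_athena(tmp, rel), "duplicate concept_id")

  tmp2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(sub("concept_code", "code", x), tmp2)
  expect_error(load_athena(tmp2, rel), "concept_code")

  # empty relationship file: loads, but nothing resolves
  tmp3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(readLines(rel)[1], tmp3)
  st <- load_athena(con, tmp3)
  expect_equal(nrow(map_to_standard("E11.9", "ICD10GM", st)), 0L)
})

test_that("only APPROVED local mappings are registered; unknown targets are fatal", {
  store <- load_vocab_fixture(local = FALSE)
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c('"source_code","source_description","source_context","target_concept_id","mapping_status"',
               '"X1","thing","visit","9201","APPROVED"',
               '"X2","thing","visit","9202","UNCHECKED"'), tmp)
  expect_message(load_local_mappings(tmp, store), "1 local mapping")
  st <- suppressMessages(load_local_mappings(tmp, store))
  expect_equal(as.numeric(hdlomop:::resolve_local("X1", "visit", st)), 9201)
  expect_equal(as.numeric(hdlomop:::resolve_local("X2", "visit", st)), 0)

  tmp2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c('"source_code","source_description","source_context","target_concept_id","mapping_status"',
               '"X1","thing","visit","424242","APPROVED"'), tmp2)
  expect_error(load_local_mappings(tmp2, store), "absent from store")
})

test_that("the COPD disease management program resolves to its management concept", {
  store <- h_store()
  cid <- as.numeric(hdlomop:::resolve_local("COPD", "dmp", store))
  expect_equal(cid, 4233538)
  expect_match(hdlomop:::concept_name(cid, store), "chronic obstructive pulmonary disease")
  # the UNCHECKED row is not registered
  expect_equal(as.numeric(hdlomop:::resolve_local("KHK", "dmp", store)), 0)
})

test_that("ICD-10-GM normalisation strips modifiers, keeps them reconstructible", {
  cases <- list(c("U07.1!", "U07.1", "!"),
                c("E11.9", "E11.9", ""),
                c("M05.44†", "M05.44", "†"),
                c("J45.9*", "J45.9", "*"),
                c("U07.1! L", "U07.1", "! L"),
                c("garbage", "garbage", ""))
  for (cs in cases) {
    n <- normalize_icd_gm(cs[[1]])
    expect_equal(n$clean, cs[[2]], info = cs[[1]])
    expect_equal(n$modifiers, cs[[3]], info = cs[[1]])
    expect_equal(paste0(n$clean, n$modifiers), cs[[1]])
  }
})

test_that("normalisation is idempotent", {
  raw <- c("U07.1!", "M05.44†", "Z99.2", "E11.9", "A00", "K52.9 R")
  once <- normalize_icd_gm(raw)
  twice <- normalize_icd_gm(once$clean)
  expect_equal(twice$clean, once$clean)
  expect_true(all(twice$modifiers == ""))
})

test_that("map_to_standard is pure, returns domains, and never maps PZN", {
  store <- h_store()
  r1 <- map_to_standard("E11.9", "ICD10GM", store)
  expect_equal(r1$concept_id, 201826)
  expect_equal(r1$domain_id, "Condition")
  expect_identical(r1, map_to_standard("E11.9", "ICD10GM", store))

  dual <- map_to_standard("Z99.2", "ICD10GM", store)
  expect_equal(nrow(dual), 2L)  # fixture constructed with a dual mapping
  expect_setequal(dual$domain_id, c("Condition", "Procedure"))

  expect_equal(nrow(map_to_standard("04773414", "PZN", store)), 0L)
  expect_equal(nrow(map_to_standard("ZZ99", "ICD10GM", store)), 0L)

  # only standard concepts ever come back
  all_codes <- store$concepts$concept_code[store$concepts$vocabulary_id %in% c("ICD10GM", "OPS")]
  std <- store$concepts$concept_id[store$concepts$standard_concept == "S"]
  for (v in c("ICD10GM", "OPS"))
    for (code in all_codes)
      expect_true(all(map_to_standard(code, v, store)$concept_id %in% std))
})
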