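# CDM store: key allocation, upsert/extend semantics, persistence.

test_that("person upsert allocates once per psid and updates in place", {
  db <- cdm_new()
  id <- upsert_person("A1", list(gender = "w", year_of_birth = 1960), 2009, db)
  expect_equal(id, 1)
  expect_equal(db$tables$person$person_source_value, "A1")
  id2 <- upsert_person("A1", list(gender = "w", year_of_birth = 1960), 2010, db)
  expect_equal(id2, 1)
  expect_equal(nrow(db$tables$person), 1L)
  id3 <- upsert_person("B2", list(gender = "m", year_of_birth = 1980), 2009, db)
  expect_equal(id3, 2)
  expect_error(upsert_person("", list(), 2009, db), "psid")
})

test_that("gender outside the binary pair maps to concept 0", {
  db <- cdm_new()
  upsert_person("A1", list(gender = "divers", year_of_birth = 1990), 2009, db)
  upsert_person("A2", list(gender = "w", year_of_birth = 1990), 2009, db)
  upsert_person("A3", list(gender = "m", year_of_birth = 1990), 2009, db)
  expect_equal(db$tables$person$gender_concept_id, c(0, 8532, 8507))
})

test_that("observation periods extend by union and stay idempotent", {
  db <- cdm_new()
  p <- upsert_person("A1", list(gender = "w"), 2009, db)
  extend_observation_period(p, as.Date("2009-01-01"), as.Date("2009-12-31"), db)
  extend_observation_period(p, as.Date("2010-01-01"), as.Date("2010-12-31"), db)
  op <- db$tables$observation_period
  expect_equal(nrow(op), 1L)
  expect_equal(op$observation_period_start_date, as.Date("2009-01-01"))
  expect_equal(op$observation_period_end_date, as.Date("2010-12-31"))
  # idempotent re-add
  extend_observation_period(p, as.Date("2010-01-01"), as.Date("2010-12-31"), db)
  expect_equal(nrow(db$tables$observation_period), 1L)
  # a distant year opens a second, non-overlapping period
  extend_observation_period(p, as.Date("2014-01-01"), as.Date("2014-12-31"), db)
  expect_equal(nrow(db$tables$observation_period), 2L)
  expect_error(extend_observation_period(p, as.Date("2015-02-01"),
                                         as.Date("2015-01-01"), db), "start after end")
})

test_that("payer plan periods are keyed by vsid and span the reported year", {
  db <- cdm_new()
  p1 <- upsert_person("A1", list(gender = "w"), 2009, db)
  p2 <- upsert_person("A2", list(gender = "m"), 2009, db)
  id <- get_or_create_payer_plan_period("V1", p1, 2009, list(), db)
  expect_equal(db$tables$payer_plan_period$payer_plan_period_start_date, as.Date("2009-01-01"))
  expect_equal(db$tables$payer_plan_period$payer_plan_period_end_date, as.Date("2009-12-31"))
  expect_equal(get_or_create_payer_plan_period("V1", p1, 2009, list(), db), id)
  expect_equal(nrow(db$tables$payer_plan_period), 1L)
  # two insurances, one person: two rows, same person
  get_or_create_payer_plan_period("V2", p1, 2009, list(), db)
  expect_equal(sum(db$tables$payer_plan_period$person_id == p1), 2L)
  # vsid reuse across persons violates source semantics
  expect_error(get_or_create_payer_plan_period("V1", p2, 2009, list(), db),
               "different person")
})

test_that("providers and care sites deduplicate on their natural key", {
  db <- cdm_new()
  a <- upsert_provider("L1", list(specialty_concept_id = 38004446,
                                  specialty_source_value = "01"), db)
  b <- upsert_provider("L1", list(), db)
  expect_equal(a, b)
  expect_equal(nrow(db$tables$provider), 1L)
  c2 <- upsert_provider("L2", list(), db)
  expect_equal(nrow(db$tables$provider), 2L)
  expect_true(a != c2)
  s1 <- upsert_care_site("IK1", list(), db)
  expect_equal(upsert_care_site("IK1", list(), db), s1)
  expect_equal(nrow(db$tables$care_site), 1L)
  # specialty via local mapping when present, else 0
  store <- h_store()
  ids <- hdlomop:::vec_providers(db, c("L7", "L8"), c("03", "99"), c(NA_real_, NA_real_), store)
  pr <- db$tables$provider
  expect_equal(pr$specialty_concept_id[match(ids, pr$provider_id)], c(38004451, 0))
})

test_that("an empty database writes only headers and round-trips", {
  db <- cdm_new()
  dir <- withr::local_tempdir()
  write_cdm(db, dir)
  files <- list.files(dir)
  expect_setequal(files, paste0(names(db$tables), ".csv"))
  for (f in files) expect_equal(length(readLines(file.path(dir, f))), 1L, info = f)
  back <- read_cdm(dir)
  for (nm in names(db$tables)) expect_equal(nrow(back$tables[[nm]]), 0L)
})

test_that("write/read round-trip preserves all rows; reruns are byte-identical", {
  db <- h_run1(n = 8, seed = 9)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cdm(db, d1)
  back <- read_cdm(d1)
  for (nm in names(db$tables)) {
    a <- db$tables[[nm]]
    a <- a[order(a[[hdlomop:::.cdm_pk[[nm]]]]), , drop = FALSE]
    rownames(a) <- NULL
    expect_equal(back$tables[[nm]], a, info = nm)
  }
  db2 <- h_run1(n = 8, seed = 9)
  write_cdm(db2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)), info = f)
})
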