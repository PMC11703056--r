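# Quality layer: field coverage, mapping coverage against brute-force
# recounts, and the check catalog including seeded-defect detection.

test_that("field coverage follows the transformed/(transformed+untransformable) rule", {
  l1 <- make_ledger_fixture(1)
  expect_equal(round(field_coverage(l1, 1), 1), 92.7)
  l3 <- make_ledger_fixture(3)
  expect_equal(round(field_coverage(l3, 3), 2), 86.21)
  # no untransformable fields -> 100%
  l <- l1[l1$status != "untransformable", ]
  expect_equal(field_coverage(l, 1), 100)
  # empty denominator errors
  expect_error(field_coverage(l1[0, ], 1), "denominator")
})

test_that("field coverage is scale-free", {
  l1 <- make_ledger_fixture(1)
  doubled <- rbind(l1, transform(l1, field = paste0(l1$field, "_bis")))
  class(doubled) <- class(l1)
  expect_equal(field_coverage(doubled, 1), field_coverage(l1, 1))
})

test_that("mapping coverage reproduces the 3-codes/2-mapped visit case", {
  db <- cdm_new()
  # visit mix: two mapped types and the obligatory "0" filler, 3:1 ratio
  concepts <- c(rep(9201, 6), rep(2004000001, 3), rep(0, 3))
  src <- c(rep("1", 6), rep("2", 3), rep("0", 3))
  hdlomop:::cdm_append(db, "visit_occurrence",
                       visit_occurrence_id = seq_along(concepts),
                       person_id = 1, visit_concept_id = concepts,
                       visit_start_date = as.Date("2009-01-01"),
                       visit_end_date = as.Date("2009-01-01"),
                       visit_type_concept_id = 32810, visit_source_value = src)
  cov <- mapping_coverage(db)
  v <- cov[cov$domain == "Visit", ]
  expect_equal(v$codes_source, 3L)
  expect_equal(v$codes_mapped, 2L)
  expect_equal(v$pct_codes, 66.7)
  expect_equal(v$records_mapped, 9L)
  expect_equal(v$pct_records, 75.0)
})

test_that("coverage percentages equal an independent full-scan recount", {
  db <- h_run1(n = 40, seed = 13)
  cov <- mapping_coverage(db)
  # oracle: second, independent implementation by direct table scans
  recount <- function(src, cid) {
    ok <- !is.na(src)
    src <- src[ok]; cid <- cid[ok]
    mapped_codes <- unique(src[cid != 0])
    list(cs = length(unique(src)), cm = length(mapped_codes),
         rs = length(src), rm = sum(cid != 0))
  }
  t <- db$tables$condition_occurrence
  o <- recount(t$condition_source_value, t$condition_concept_id)
  row <- cov[cov$domain == "Condition", ]
  expect_equal(row$codes_source, o$cs)
  expect_equal(row$codes_mapped, o$cm)
  expect_equal(row$records_mapped, o$rm)
  expect_equal(row$pct_codes, hdlomop:::round_half_up(100 * o$cm / o$cs, 1))
  t <- db$tables$drug_exposure
  o <- recount(t$drug_source_value, t$drug_concept_id)
  row <- cov[cov$domain == "Drug", ]
  expect_equal(row$codes_mapped, 0L)   # PZN never maps
  expect_equal(row$records_source, o$rs)
  t <- db$tables$observation
  o <- recount(t$observation_source_value, t$observation_concept_id)
  row <- cov[cov$domain == "Observation", ]
  expect_equal(row$records_mapped, o$rm)
  # all-mapped corner: local-concept observations are fully mapped
  expect_equal(row$pct_codes, 100)
})

test_that("a clean synthetic run passes every conformance check", {
  db <- h_run1(n = 30, seed = 17)
  checks <- run_checks(db, h_store())
  conf <- checks[checks$category == "Conformance", ]
  expect_gt(nrow(conf), 20)
  expect_true(all(conf$passed))
  db3 <- h_run3(n = 20, seed = 17)
  checks3 <- run_checks(db3, h_store())
  expect_true(all(checks3$passed[checks3$category == "Conformance"]))
})

test_that("each seeded defect class is caught by exactly its intended check", {
  store <- h_store()
  base <- h_run1(n = 12, seed = 19)
  base_failed <- run_checks(base, store)$check[!run_checks(base, store)$passed]
  plant <- function(mutate) {
    db <- h_run1(n = 12, seed = 19)
    mutate(db)
    ck <- run_checks(db, store)
    setdiff(ck$check[!ck$passed], base_failed)
  }
  # condition row carrying a Drug-domain concept
  expect_equal(plant(function(db)
    db$tables$condition_occurrence$condition_concept_id[1] <- 19078097),
    "domain_match_condition_occurrence")
  # dangling person foreign key
  expect_equal(plant(function(db)
    db$tables$condition_occurrence$person_id[1] <- 999999),
    "fk_condition_occurrence_person_id")
  # duplicated primary key (cost has no children, so the effect is isolated)
  expect_equal(plant(function(db)
    db$tables$cost$cost_id[2] <- db$tables$cost$cost_id[1]),
    "pk_unique_cost")
  # missing required person field
  expect_equal(plant(function(db)
    db$tables$person$year_of_birth[1] <- NA_real_),
    "required_person_fields")
  # visit ending before it starts
  expect_equal(plant(function(db)
    db$tables$visit_occurrence$visit_end_date[1] <-
      db$tables$visit_occurrence$visit_start_date[1] - 5),
    "date_order_visit_occurrence")
  # non-standard concept planted on a condition row: its domain still matches,
  # so only the standard-flag check trips
  expect_equal(plant(function(db)
    db$tables$condition_occurrence$condition_concept_id[1] <- 45000001),
    "standard_concept_condition_occurrence")
  # overlapping observation periods
  res <- plant(function(db) {
    t <- db$tables$observation_period
    t[nrow(t) + 1, ] <- t[1, ]
    t$observation_period_id[nrow(t)] <- max(t$observation_period_id) + 1
    db$tables$observation_period <- t
  })
  expect_true("observation_periods_no_overlap" %in% res)
})

test_that("plausibility checks appear only when enabled", {
  db <- h_run1(n = 10, seed = 23)
  off <- run_checks(db, h_store(), enable_plausibility = FALSE)
  expect_equal(sum(off$category == "Plausibility"), 0L)
  on <- run_checks(db, h_store(), enable_plausibility = TRUE)
  expect_gt(sum(on$category == "Plausibility"), 0L)
})

test_that("validation-context checks compare the CDM against its source", {
  ds <- h_ds1(n = 10, seed = 29)
  db <- run_format1(ds, h_store(), cdm_new())
  ck <- run_checks(db, h_store(), source = list(ds))
  val <- ck[ck$context == "Validation", ]
  expect_gt(nrow(val), 0)
  expect_true(all(val$passed))
  # remove a person -> the source-coverage validation fails
  db$tables$person <- db$tables$person[-1, ]
  db$person_ids <- db$person_ids[-1]
  ck2 <- run_checks(db, h_store(), source = list(ds))
  expect_false(ck2$passed[ck2$check == "source_persons_in_cdm_f1"])
})

test_that("rendered reports agree with the in-memory numbers and sum correctly", {
  db <- h_run1(n = 10, seed = 31)
  rep <- quality_report(db, h_store(), ledgers = list(make_ledger_fixture(1)))
  dir <- withr::local_tempdir()
  render_report(rep, dir)
  j <- jsonlite::read_json(file.path(dir, "report.json"), simplifyVector = TRUE)
  expect_equal(round(j$field_coverage$pct[1], 1), 92.7)
  expect_equal(nrow(j$checks), nrow(rep$checks))
  tot <- j$totals
  for (ctx in unique(tot$context)) {
    t <- tot[tot$context == ctx, ]
    expect_equal(t$total[t$category == "Total"],
                 sum(t$total[t$category != "Total"]))
    expect_equal(t$pass + t$fail, t$total)
  }
  expect_true(file.exists(file.path(dir, "report.md")))
  # empty database: all-zero tables, no crash
  rep0 <- quality_report(cdm_new(), h_store())
  render_report(rep0, dir)
  expect_true(all(rep0$mapping_coverage$records_source == 0))
})
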