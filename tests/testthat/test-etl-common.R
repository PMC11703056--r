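# Shared transformation rules: vague dates, imputation, intervals, routing.

test_that("vague_date enforces its component invariants", {
  expect_error(vague_date(2010, quarter = 5), "quarter")
  expect_error(vague_date(2010, month = 13), "month")
  expect_error(vague_date(2010, day = 5), "day given without month")
  expect_error(vague_date(2010, quarter = 1, month = 7), "contradicts")
  v <- vague_date(2010, quarter = 3, month = 7)
  expect_identical(v$quarter, 3L)
})

test_that("imputation uses the first day of the most precise period", {
  expect_equal(impute_date(vague_date(2010, quarter = 2)), as.Date("2010-04-01"))
  expect_equal(impute_date(vague_date(2010, month = 7, day = 15)), as.Date("2010-07-15"))
  expect_equal(impute_date(vague_date(2010)), as.Date("2010-01-01"))
  expect_equal(impute_date(vague_date(2010, month = 11)), as.Date("2010-11-01"))
})

test_that("case imputation adds one day per following case, first case un-offset", {
  expect_equal(impute_case_date(vague_date(2009, quarter = 2), 1), as.Date("2009-04-01"))
  # oracle: calendar arithmetic, base + 2 days
  expect_equal(impute_case_date(vague_date(2009, quarter = 2), 3),
               as.Date("2009-04-01") + 2)
  expect_equal(impute_case_date(vague_date(2009), 1), as.Date("2009-01-01"))
  expect_error(impute_case_date(vague_date(2009), 0), "case_index")
})

test_that("case imputation is strictly increasing in the case index", {
  for (v in list(vague_date(2010, quarter = 4), vague_date(2012, month = 2),
                 vague_date(2009))) {
    d <- vapply(1:60, function(k) as.integer(impute_case_date(v, k)), 0L)
    expect_true(all(diff(d) == 1L))
  }
})

test_that("imputation is monotone in precision within the same period", {
  # adding a finer component never yields an earlier date
  for (y in c(2009L, 2012L)) for (q in 1:4) {
    base <- impute_date(vague_date(y, quarter = q))
    for (m in ((q - 1) * 3 + 1):(q * 3)) {
      dm <- impute_date(vague_date(y, quarter = q, month = m))
      expect_gte(as.integer(dm), as.integer(base))
      expect_gte(as.integer(impute_date(vague_date(y, month = m, day = 17))),
                 as.integer(dm))
    }
  }
})

test_that("death date is December 31st regardless of month lengths", {
  expect_equal(death_date(2010), as.Date("2010-12-31"))
  expect_equal(death_date(2009), as.Date("2009-12-31"))
  expect_equal(death_date(2012), as.Date("2012-12-31"))
})

test_that("drug interval adds 29 days, across year and leap-day boundaries", {
  expect_equal(drug_interval(as.Date("2010-05-03"))$end, as.Date("2010-06-01"))
  expect_equal(drug_interval(as.Date("2010-12-20"))$end, as.Date("2011-01-18"))
  expect_equal(drug_interval(as.Date("2012-02-01"))$end, as.Date("2012-03-01"))
})

test_that("route_event places events by target domain with concept-0 fallback", {
  store <- h_store()
  r <- route_event("E11.9", "ICD10GM", "condition_occurrence", store)
  expect_equal(nrow(r), 1L)
  expect_equal(r$target_table, "condition_occurrence")
  expect_equal(r$concept_id, 201826)

  # unknown code: exactly one event in the default table, source retained
  r <- route_event("X99.9", "ICD10GM", "condition_occurrence", store)
  expect_equal(nrow(r), 1L)
  expect_equal(r$concept_id, 0)
  expect_equal(r$source_code, "X99.9")
  expect_equal(r$target_table, "condition_occurrence")

  # OPS whose standard concept lives in the Drug domain
  r <- route_event("6-002.1", "OPS", "procedure_occurrence", store)
  expect_equal(r$target_table, "drug_exposure")

  # dual mapping fans out into both domains
  r <- route_event("Z99.2", "ICD10GM", "condition_occurrence", store)
  expect_equal(nrow(r), 2L)
  expect_setequal(r$target_table, c("condition_occurrence", "procedure_occurrence"))
})

test_that("routing conserves events: |output| = max(1, fan-out) for every code", {
  store <- h_store()
  codes <- c("E11.9", "I10", "Z99.2", "Z01.7", "Z34", "X11.1", "QQ", "U07.1")
  # oracle: brute-force scan of the concept / Maps-to data frames
  for (code in codes) {
    src <- store$concepts$concept_id[store$concepts$vocabulary_id == "ICD10GM" &
                                       store$concepts$concept_code == code]
    fanout <- if (length(src)) sum(store$maps_to$source_id == src) else 0L
    r <- route_event(code, "ICD10GM", "condition_occurrence", store)
    expect_equal(nrow(r), max(1L, fanout), info = code)
  }
  # and vectorised routing agrees with the per-code calls
  rv <- hdlomop:::route_codes(codes, "ICD10GM", "condition_occurrence", store)
  per_code <- lapply(codes, route_event, vocabulary_id = "ICD10GM",
                     default_table = "condition_occurrence", store = store)
  expect_equal(nrow(rv), sum(vapply(per_code, nrow, 0L)))
})
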