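# Format 1 transformation: worked single-person examples plus dataset-level
# conservation properties.

test_that("death flag with year-only information lands on December 31st", {
  ds <- h_manual_f1(dead = TRUE, dead_year = 2009)
  db <- run_format1(ds, h_store(), cdm_new())
  expect_equal(nrow(db$tables$death), 1L)
  expect_equal(db$tables$death$death_date, as.Date("2009-12-31"))
})

test_that("a person present in two years keeps one row and one merged period", {
  db <- cdm_new()
  run_format1(h_manual_f1(year = 2009), h_store(), db)
  run_format1(h_manual_f1(year = 2010), h_store(), db)
  expect_equal(nrow(db$tables$person), 1L)
  op <- db$tables$observation_period
  expect_equal(nrow(op), 1L)
  expect_equal(op$observation_period_start_date, as.Date("2009-01-01"))
  expect_equal(op$observation_period_end_date, as.Date("2010-12-31"))
})

test_that("RSC day counts become observations with a local concept and the value", {
  ds <- h_manual_f1(rsc = list(list(psid = "A1", vsid = "V1", em_rente_tage = "30",
                                    erstattung_tage = "", krankengeld_tage = "")))
  db <- run_format1(ds, h_store(), cdm_new())
  obs <- db$tables$observation
  row <- obs[obs$observation_concept_id == 2000000001, ]
  expect_equal(nrow(row), 1L)
  expect_equal(row$value_as_number, 30)
})

test_that("an inpatient row builds its visit from month + case and links the condition", {
  ds <- h_manual_f1(kh = list(list(psid = "A1", vsid = "V1", entlassungsmonat = "3",
                                   fall = "1", aufnahmeart = "1", verweildauer = "4",
                                   entlassungsgrund = "01", icd_code = "E11.9",
                                   diagnoseart = "H")))
  db <- run_format1(ds, h_store(), cdm_new())
  vis <- db$tables$visit_occurrence
  expect_equal(nrow(vis), 1L)
  # oracle: hand computation, first-of-month + (case - 1) days
  expect_equal(vis$visit_start_date, as.Date("2009-03-01"))
  expect_equal(vis$visit_end_date, as.Date("2009-03-05"))
  expect_equal(vis$visit_concept_id, 9201)
  con <- db$tables$condition_occurrence
  expect_equal(nrow(con), 1L)
  expect_equal(con$condition_concept_id, 201826)
  expect_equal(con$visit_occurrence_id, vis$visit_occurrence_id)
  expect_equal(con$condition_status_concept_id, 32902)
  expect_equal(con$condition_start_date, as.Date("2009-03-01"))
})

test_that("case enumerators keep diagnosis order by shifting one day per case", {
  ds <- h_manual_f1(kh = lapply(1:3, function(k)
    list(psid = "A1", vsid = "V1", entlassungsmonat = "6", fall = as.character(k),
         aufnahmeart = "2", verweildauer = "0", entlassungsgrund = "01",
         icd_code = "I10", diagnoseart = "H")))
  db <- run_format1(ds, h_store(), cdm_new())
  vis <- db$tables$visit_occurrence
  expect_equal(sort(vis$visit_start_date), as.Date("2009-06-01") + 0:2)
  expect_equal(unique(vis$visit_concept_id), 2004000001)  # outpatient in hospital
})

test_that("excluded outpatient diagnoses become Disorder-excluded observations only", {
  ds <- h_manual_f1(amb = list(
    list(psid = "A1", vsid = "V1", quartal = "2", icd_code = "E11.9",
         qualifizierung = "A", icd_zusatz = ""),
    list(psid = "A1", vsid = "V1", quartal = "2", icd_code = "I10",
         qualifizierung = "G", icd_zusatz = "")))
  db <- run_format1(ds, h_store(), cdm_new())
  obs <- db$tables$observation
  excl <- obs[obs$observation_concept_id == 4129922, ]
  expect_equal(nrow(excl), 1L)
  expect_equal(excl$observation_source_value, "E11.9")
  con <- db$tables$condition_occurrence
  expect_equal(nrow(con), 1L)  # only the confirmed diagnosis
  expect_equal(con$condition_source_value, "I10")
  expect_equal(con$condition_status_concept_id, 32893)
  # outpatient visits carry the quarter-imputed date and visit concept 0
  vis <- db$tables$visit_occurrence
  expect_equal(unique(vis$visit_start_date), as.Date("2009-04-01"))
  expect_equal(unique(vis$visit_concept_id), 0)
  expect_equal(unique(vis$visit_source_value), "0")
})

test_that("an empty inpatient visit-type field yields visit concept 0, source '0'", {
  ds <- h_manual_f1(kh = list(list(psid = "A1", vsid = "V1", entlassungsmonat = "1",
                                   fall = "1", aufnahmeart = "", verweildauer = "1",
                                   entlassungsgrund = "01", icd_code = "E11.9",
                                   diagnoseart = "N")))
  db <- run_format1(ds, h_store(), cdm_new())
  expect_equal(db$tables$visit_occurrence$visit_concept_id, 0)
  expect_equal(db$tables$visit_occurrence$visit_source_value, "0")
})

test_that("blood purification yields one dialysis procedure on January 1st", {
  ds <- h_manual_f1(bp = list(list(psid = "A1", vsid = "V1",
                                   blutreinigung_kz = "1", lokalisation = "L")))
  db <- run_format1(ds, h_store(), cdm_new())
  pr <- db$tables$procedure_occurrence
  expect_equal(nrow(pr), 1L)
  expect_equal(pr$procedure_concept_id, 4032243)
  expect_equal(pr$procedure_date, as.Date("2009-01-01"))
})

test_that("prescriptions keep the PZN at concept 0 with the 29-day interval", {
  ds <- h_manual_f1(rx = list(list(psid = "A1", vsid = "V1", pzn = "04773414",
                                   verordnungsdatum = "2009-05-03", menge = "2",
                                   faktor = "1", zuzahlung = "5.00", apotheke_ik = "X")))
  db <- run_format1(ds, h_store(), cdm_new())
  dr <- db$tables$drug_exposure
  expect_equal(nrow(dr), 1L)
  expect_equal(dr$drug_concept_id, 0)
  expect_equal(dr$drug_source_value, "04773414")
  expect_equal(dr$drug_exposure_start_date, as.Date("2009-05-03"))
  expect_equal(dr$drug_exposure_end_date, as.Date("2009-06-01"))
  expect_equal(dr$quantity, 2)
  # the copayment becomes a drug-linked cost row on the vsid's payer period
  cost <- db$tables$cost[db$tables$cost$cost_type_concept_id == 2005000017, ]
  expect_equal(nrow(cost), 1L)
  expect_equal(cost$paid_patient_copay, 5)
  expect_equal(cost$cost_event_id, dr$drug_exposure_id)
  expect_equal(cost$payer_plan_period_id, db$tables$payer_plan_period$payer_plan_period_id)
})

test_that("expenditure amounts become typed cost rows linked to the payer period", {
  ds <- h_manual_f1()
  ds$tables$ausgaben[1, ] <- as.list(c(psid = "A1", vsid = "V1", ausg_kh = "123.45",
                                       ausg_amb = "", ausg_arznei = "", ausg_zahn = "",
                                       ausg_heilmittel = "", ausg_hilfsmittel = "",
                                       ausg_krankengeld = "", ausg_fahrkosten = "",
                                       ausg_vorsorge = "", ausg_sonstige = ""))
  db <- run_format1(ds, h_store(), cdm_new())
  cost <- db$tables$cost
  expect_equal(nrow(cost), 1L)
  expect_equal(cost$total_cost, 123.45)
  expect_equal(cost$cost_type_concept_id, 2005000001)
  expect_equal(cost$payer_plan_period_id, db$tables$payer_plan_period$payer_plan_period_id)
})

test_that("single-mapped, non-excluded diagnoses yield exactly N visits and N events", {
  rows <- lapply(1:4, function(k)
    list(psid = "A1", vsid = "V1", quartal = as.character(k), icd_code = "E11.9",
         qualifizierung = "G", icd_zusatz = ""))
  ds <- h_manual_f1(amb = rows)
  db <- run_format1(ds, h_store(), cdm_new())
  expect_equal(nrow(db$tables$visit_occurrence), 4L)
  expect_equal(nrow(db$tables$condition_occurrence), 4L)
})

test_that("two sequential years count persons as the union of their psids", {
  db <- cdm_new()
  run_format1(h_ds1(n = 12, seed = 4, years = c(2009, 2010)), h_store(), db)
  ds2 <- generate_format1(h_cfg1(n = 12, seed = 4, years = c(2009, 2010)), year = 2010)
  run_format1(ds2, h_store(), db)
  # oracle: set union over the two demographics tables
  psids <- union(h_ds1(n = 12, seed = 4, years = c(2009, 2010))$tables$vers_stamm$psid,
                 ds2$tables$vers_stamm$psid)
  expect_equal(nrow(db$tables$person), length(psids))
  # manifest records both years
  expect_setequal(names(db$manifest), c("format1:2009", "format1:2010"))
})

test_that("an empty dataset produces an empty CDM and a zero-count manifest", {
  ds <- h_manual_f1()
  for (tb in source_tables(1)) ds$tables[[tb]] <- ds$tables[[tb]][0, ]
  db <- run_format1(ds, h_store(), cdm_new())
  for (tb in names(db$tables)) expect_equal(nrow(db$tables[[tb]]), 0L, info = tb)
  expect_true(all(unlist(db$manifest[["format1:2009"]]$rows_in) == 0))
})
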