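# Format 3 transformation: date cascades, schema case linkage, domain routing.

test_that("quarter appearances span one observation period with interior quarters covered", {
  ds <- h_manual_f3(quarters = c(1, 3))
  db <- run_format3(ds, h_store(), cdm_new())
  op <- db$tables$observation_period
  expect_equal(nrow(op), 1L)
  expect_equal(op$observation_period_start_date, as.Date("2019-01-01"))
  expect_equal(op$observation_period_end_date, as.Date("2019-09-30"))
})

test_that("an exact death date is used as-is (no December-31 rule)", {
  ds <- h_manual_f3(dead = TRUE, sterbedatum = "2019-06-02", sterbequartal = "2")
  db <- run_format3(ds, h_store(), cdm_new())
  expect_equal(db$tables$death$death_date, as.Date("2019-06-02"))
  # without the day, the quarter end is used; without both, December 31st
  ds2 <- h_manual_f3(dead = TRUE, sterbedatum = "", sterbequartal = "2")
  db2 <- run_format3(ds2, h_store(), cdm_new())
  expect_equal(db2$tables$death$death_date, as.Date("2019-06-30"))
})

test_that("a COPD disease-management enrolment maps to its management procedure", {
  ds <- h_manual_f3(rows = list(vers_dmp = list(list(
    psid = "A1", vsid = "V1", dmp_typ = "COPD", einschreibedatum = "2019-02-10",
    austrittsdatum = "", dmp_status = "A"))))
  db <- run_format3(ds, h_store(), cdm_new())
  pr <- db$tables$procedure_occurrence
  expect_equal(nrow(pr), 1L)
  expect_equal(pr$procedure_concept_id, 4233538)
  expect_equal(pr$procedure_date, as.Date("2019-02-10"))
  expect_equal(pr$procedure_source_value, "COPD")
})

test_that("hospital cases merge two source tables into one dated visit with statuses", {
  ds <- h_manual_f3(rows = list(
    kh_faelle = list(list(psid = "A1", vsid = "V1", kh_fallnr = "K1",
                          aufnahmedatum = "2019-03-05", entlassungsdatum = "2019-03-10",
                          aufnahmegrund = "01", aufnahmeanlass = "E",
                          entlassungsgrund = "02", behandlungsart = "V",
                          ik = "260000001", ik_plz = "24103", traegerart = "oeff")),
    kh_khdiag = list(list(psid = "A1", vsid = "V1", kh_fallnr = "K1",
                          icd_code = "J44.9", diagnoseart = "H", lokalisation = ""))))
  db <- run_format3(ds, h_store(), cdm_new())
  vis <- db$tables$visit_occurrence
  expect_equal(nrow(vis), 1L)
  expect_equal(vis$visit_start_date, as.Date("2019-03-05"))
  expect_equal(vis$visit_end_date, as.Date("2019-03-10"))
  expect_equal(vis$visit_concept_id, 9201)
  expect_equal(vis$admitted_from_source_value, "01")
  con <- db$tables$condition_occurrence
  expect_equal(con$condition_start_date, as.Date("2019-03-05"))
  expect_equal(con$condition_end_date, as.Date("2019-03-10"))
  expect_equal(con$condition_status_concept_id, 32902)  # primary
  expect_equal(con$visit_occurrence_id, vis$visit_occurrence_id)
  # admission reason survives as an observation with the local concept
  expect_true(2000000008 %in% db$tables$observation$observation_concept_id)
  # care site registered from the facility id
  expect_equal(db$tables$care_site$care_site_source_value, "260000001")
})

test_that("an OPS code with a Drug-domain target becomes a visit-linked drug exposure", {
  ds <- h_manual_f3(rows = list(
    kh_faelle = list(list(psid = "A1", vsid = "V1", kh_fallnr = "K1",
                          aufnahmedatum = "2019-05-01", entlassungsdatum = "2019-05-04",
                          aufnahmegrund = "01", aufnahmeanlass = "E",
                          entlassungsgrund = "01", behandlungsart = "V",
                          ik = "260000001", ik_plz = "", traegerart = "oeff")),
    kh_ops = list(list(psid = "A1", vsid = "V1", kh_fallnr = "K1",
                       ops_code = "6-002.1", ops_datum = "2019-05-02",
                       lokalisation = "", anzahl = "1"))))
  db <- run_format3(ds, h_store(), cdm_new())
  dr <- db$tables$drug_exposure
  expect_equal(nrow(dr), 1L)
  expect_equal(dr$drug_concept_id, 19078097)
  expect_equal(dr$drug_source_value, "6-002.1")
  expect_equal(dr$visit_occurrence_id, db$tables$visit_occurrence$visit_occurrence_id)
})

test_that("OPS localisation is retained only as source value, not mapped", {
  ds <- h_manual_f3(rows = list(
    kh_faelle = list(list(psid = "A1", vsid = "V1", kh_fallnr = "K1",
                          aufnahmedatum = "2019-05-01", entlassungsdatum = "2019-05-02",
                          aufnahmegrund = "01", aufnahmeanlass = "E",
                          entlassungsgrund = "01", behandlungsart = "V",
                          ik = "260000001", ik_plz = "", traegerart = "frei")),
    kh_ops = list(list(psid = "A1", vsid = "V1", kh_fallnr = "K1",
                       ops_code = "5-511.1", ops_datum = "", lokalisation = "L",
                       anzahl = "1"))))
  db <- run_format3(ds, h_store(), cdm_new())
  pr <- db$tables$procedure_occurrence
  expect_equal(pr$procedure_concept_id, 4301351)
  expect_equal(pr$modifier_source_value, "L")
  expect_equal(pr$modifier_concept_id, 0)
  # no date on the OPS row: the case admission date steps in
  expect_equal(pr$procedure_date, as.Date("2019-05-01"))
})

test_that("ambulatory diagnoses strip special characters for mapping, keep them as source", {
  ds <- h_manual_f3(rows = list(
    amb_faelle = list(list(psid = "A1", vsid = "V1", amb_fallnr = "C1",
                           behandlung_von = "2019-02-04", behandlung_bis = "",
                           quartal = "1", unfall_kz = "1", notfall_kz = "0",
                           lanr = "L000001", fachgruppe = "03", bsnr = "B000001",
                           plz_praxis = "24103", praxisart = "EP",
                           blutreinigung_kz = "0")),
    amb_diagnosen = list(list(psid = "A1", vsid = "V1", amb_fallnr = "C1",
                              icd_code = "U07.1!", qualifizierung = "G",
                              lokalisation = ""))))
  db <- run_format3(ds, h_store(), cdm_new())
  con <- db$tables$condition_occurrence
  expect_equal(con$condition_concept_id, 37311061)
  expect_equal(con$condition_source_value, "U07.1!")
  # end = start when no end is available; accident flag becomes an observation
  vis <- db$tables$visit_occurrence
  expect_equal(vis$visit_end_date, vis$visit_start_date)
  expect_equal(vis$visit_start_date, as.Date("2019-02-04"))
  expect_true(2000000007 %in% db$tables$observation$observation_concept_id)
  # the treating physician carries the mapped cardiology specialty
  expect_equal(db$tables$provider$specialty_concept_id, 38004451)
})

test_that("unmapped tariff numbers fall back to procedure concept 0 with costs attached", {
  ds <- h_manual_f3(rows = list(
    amb_faelle = list(list(psid = "A1", vsid = "V1", amb_fallnr = "C1",
                           behandlung_von = "2019-08-12", behandlung_bis = "",
                           quartal = "3", unfall_kz = "0", notfall_kz = "0",
                           lanr = "L000001", fachgruppe = "01", bsnr = "B000001",
                           plz_praxis = "", praxisart = "EP", blutreinigung_kz = "0")),
    amb_leistungen = list(list(psid = "A1", vsid = "V1", amb_fallnr = "C1",
                               uas_ziffer = "03230", datum = "", anzahl = "2",
                               bruttobetrag = "31.50", punktzahl = "120",
                               eigenanteil = ""))))
  db <- run_format3(ds, h_store(), cdm_new())
  pr <- db$tables$procedure_occurrence
  expect_equal(pr$procedure_concept_id, 0)
  expect_equal(pr$procedure_source_value, "03230")
  expect_equal(pr$quantity, 2)
  cost <- db$tables$cost[db$tables$cost$cost_type_concept_id == 2005000013, ]
  expect_equal(cost$total_charge, 31.5)
  expect_equal(cost$cost_event_id, pr$procedure_occurrence_id)
})

test_that("dental cases fall back to the first day of the quarter and sum their costs", {
  ds <- h_manual_f3(rows = list(
    zahn_faelle = list(list(psid = "A1", vsid = "V1", zahn_fallnr = "Z1",
                            behandlungstag = "", behandlungsende = "", quartal = "3",
                            behandlungsart = "RB", zahnarzt_lanr = "Z000001",
                            fallkosten = "100", laborkosten = "40",
                            fremdlaborkosten = "10", versichertenanteil = "12.50")),
    zahn_leistungen = list(list(psid = "A1", vsid = "V1", zahn_fallnr = "Z1",
                                leistungsgruppe = "2", gebnr = "107a", datum = "",
                                anzahl = "1", zahn = "36")),
    zahn_befunde = list(list(psid = "A1", vsid = "V1", zahn_fallnr = "Z1",
                             befund = "K", befundart = "01", befunddatum = "",
                             zahn = "36", refart = ""))))
  db <- run_format3(ds, h_store(), cdm_new())
  vis <- db$tables$visit_occurrence
  expect_equal(vis$visit_start_date, as.Date("2019-07-01"))
  expect_equal(vis$visit_end_date, as.Date("2019-07-01"))
  expect_equal(vis$visit_concept_id, 2004000004)
  expect_equal(vis$visit_source_value, "RB")  # treatment type kept as source
  # oracle: 100 + 40 + 10 summed into one dental-claim cost row
  cost <- db$tables$cost[db$tables$cost$cost_type_concept_id == 2005000011, ]
  expect_equal(nrow(cost), 1L)
  expect_equal(cost$total_cost, 150)
  expect_equal(cost$paid_by_patient, 12.5)
  # service group 2 maps to its fixture concept; finding kept as source value
  pr <- db$tables$procedure_occurrence
  expect_equal(pr$procedure_concept_id, 4159251)
  expect_equal(pr$procedure_source_value, "G2/107a")
  obs <- db$tables$observation[db$tables$observation$observation_concept_id == 2000000011, ]
  expect_equal(obs$observation_source_value, "K")
})

test_that("prescriptions produce one exposure and a three-way pharmacy cost split", {
  ds <- h_manual_f3(rows = list(
    am_rezepte = list(list(psid = "A1", vsid = "V1", am_fallnr = "R1",
                           pzn = "01234567", verordnungsdatum = "2019-12-20",
                           menge = "1", faktor = "1", darreichungsform = "TAB",
                           packungsgroesse = "N2", autidem_kz = "0",
                           verordnender_lanr = "L000002", verordnender_fachgruppe = "01",
                           verordnender_bsnr = "B000002")),
    am_kosten = list(list(psid = "A1", vsid = "V1", am_fallnr = "R1",
                          zuzahlung = "5.00", gesamtkosten = "27.30",
                          bruttobetrag = "31.00", festbetrag = "",
                          apothekenzuschlag = "2.50"))))
  db <- run_format3(ds, h_store(), cdm_new())
  dr <- db$tables$drug_exposure
  expect_equal(nrow(dr), 1L)
  expect_equal(dr$drug_concept_id, 0)  # PZN never maps
  expect_equal(dr$drug_source_value, "01234567")
  expect_equal(dr$drug_exposure_end_date, as.Date("2020-01-18"))  # +29 rollover
  cost <- db$tables$cost
  expect_equal(nrow(cost), 3L)
  expect_setequal(cost$cost_type_concept_id, c(2005000014, 2005000015, 2005000016))
  expect_equal(cost$paid_by_patient[cost$cost_type_concept_id == 2005000014], 5)
  expect_equal(cost$total_cost[cost$cost_type_concept_id == 2005000015], 27.3)
  expect_equal(cost$total_charge[cost$cost_type_concept_id == 2005000016], 31)
  expect_true(all(cost$cost_event_id == dr$drug_exposure_id))
  expect_true(all(cost$payer_plan_period_id ==
                    db$tables$payer_plan_period$payer_plan_period_id))
})

test_that("activity across schemas shares one person id; reruns are identical", {
  db <- h_run3(n = 15, seed = 21)
  # oracle: join on psid -- every event's person resolves to the person table
  pids <- db$tables$person$person_id
  for (tb in c("visit_occurrence", "condition_occurrence", "procedure_occurrence",
               "drug_exposure", "observation", "measurement"))
    expect_true(all(db$tables[[tb]]$person_id %in% pids), info = tb)
  expect_equal(length(unique(db$tables$person$person_source_value)), nrow(db$tables$person))
  db2 <- h_run3(n = 15, seed = 21)
  for (tb in names(db$tables))
    expect_equal(db$tables[[tb]], db2$tables[[tb]], info = tb)
})

test_that("an empty Format 3 dataset produces an empty CDM", {
  ds <- h_manual_f3()
  for (tb in source_tables(3)) ds$tables[[tb]] <- ds$tables[[tb]][0, ]
  db <- run_format3(ds, h_store(), cdm_new())
  for (tb in names(db$tables)) expect_equal(nrow(db$tables[[tb]]), 0L, info = tb)
})
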