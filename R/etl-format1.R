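# Transformation of Format 1 (and the structurally identical Format 2).
# Stages run in a fixed order -- persons/membership first, visits before the
# events that link to them -- because the source has no primary keys beyond
# psid/vsid and visit assignment relies on temporary keys.

# Every source field the Format 1 ETL consumes, by table. The stages read
# their inputs through consumed_view(), so a field not declared here is
# physically invisible to the ETL; the union of these lists is the ledger's
# "transformed" set (38 fields).
.f1_uses <- list(
  vers_stamm = c("gebjahr", "geschlecht", "verstorben", "sterbejahr"),
  vers_rsc = c("em_rente_tage", "erstattung_tage", "krankengeld_tage"),
  blutreinigung = c("blutreinigung_kz"),
  arzneimittel = c("pzn", "verordnungsdatum", "menge", "faktor", "zuzahlung"),
  kh_diagnosen = c("entlassungsmonat", "fall", "aufnahmeart", "verweildauer",
                   "entlassungsgrund", "icd_code", "diagnoseart"),
  amb_diagnosen = c("quartal", "icd_code", "qualifizierung"),
  ausgaben = c("ausg_kh", "ausg_amb", "ausg_arznei", "ausg_zahn", "ausg_heilmittel",
               "ausg_hilfsmittel", "ausg_krankengeld", "ausg_fahrkosten",
               "ausg_vorsorge", "ausg_sonstige"),
  vers_zeiten = c("kv_ik", "kassenart"),
  gemeinde = c("gkz", "bundesland", "kreis")
)

#' Source fields consumed by an ETL
#'
#' Introspects the field-consumption declarations the ETL stages read their
#' inputs through. By construction this is the set of source fields that can
#' influence the CDM output.
#'
#' @param format_id 1 or 3.
#' @return data.frame with columns `table`, `field`.
#' @export
etl_consumed_fields <- function(format_id) {
  uses <- if (as.integer(format_id) %in% c(1L, 2L)) .f1_uses else .f3_uses
  do.call(rbind, lapply(names(uses), function(tb)
    data.frame(table = tb, field = uses[[tb]], stringsAsFactors = FALSE)))
}

# restrict a source table to its keys plus the declared fields
consumed_view <- function(ds, table, uses) {
  sc <- source_schema(ds$format_id)
  keys <- sc$field[sc$table == table & sc$status == "key"]
  ds$tables[[table]][, c(keys, uses[[table]]), drop = FALSE]
}

f1_view <- function(ds, table) consumed_view(ds, table, .f1_uses)

# cost-type concepts of the wide expenditure columns
.f1_cost_types <- c(ausg_kh = 2005000001, ausg_amb = 2005000002, ausg_arznei = 2005000003,
                    ausg_zahn = 2005000004, ausg_heilmittel = 2005000005,
                    ausg_hilfsmittel = 2005000006, ausg_krankengeld = 2005000007,
                    ausg_fahrkosten = 2005000008, ausg_vorsorge = 2005000009,
                    ausg_sonstige = 2005000010)

new_f1_context <- function(ds, store, db) {
  list(ds = ds, year = ds$reported_year, store = store, db = db,
       skips = new.env(parent = emptyenv()))
}

count_skip <- function(ctx, what, n) {
  if (n > 0) assign(what, (ctx$skips[[what]] %||% 0L) + n, envir = ctx$skips)
  invisible(NULL)
}

#' @rdname run_format1
#' @export
etl1_insured <- function(ctx) {
  db <- ctx$db; year <- ctx$year
  stamm <- f1_view(ctx$ds, "vers_stamm")
  gem <- f1_view(ctx$ds, "gemeinde")

  # municipality code -> location, attached to persons
  loc_ids <- vapply(seq_len(nrow(gem)), function(i)
    upsert_location(gem$gkz[i], list(state = gem$bundesland[i], county = gem$kreis[i]), db),
    0)
  person_loc <- stats::setNames(loc_ids, gem$psid)

  pid <- upsert_persons(data.frame(
    psid = stamm$psid, gender = stamm$geschlecht,
    year_of_birth = as_num(stamm$gebjahr),
    month_of_birth = rep(NA_real_, nrow(stamm)),
    location_id = as.numeric(person_loc[stamm$psid]),
    stringsAsFactors = FALSE), year, db)

  # one-year observation period per person, extended across reported years
  y_start <- as.Date(sprintf("%04d-01-01", year))
  y_end <- as.Date(sprintf("%04d-12-31", year))
  for (p in pid) extend_observation_period(p, y_start, y_end, db)

  # death: only the year is known -> December 31st
  dead <- stamm$verstorben == "1"
  if (any(dead)) {
    dy <- as_int(stamm$sterbejahr[dead])
    dy[is.na(dy)] <- year
    add_death(db, pid[dead], death_date(dy), db_source = NA_character_)
  }

  # membership: one payer plan period per vsid, spanning the reported year
  memb <- f1_view(ctx$ds, "vers_zeiten")
  for (i in seq_len(nrow(memb))) {
    p <- db$person_ids[memb$psid[i]]
    if (is.na(p)) { count_skip(ctx, "vers_zeiten_unknown_psid", 1L); next }
    get_or_create_payer_plan_period(memb$vsid[i], unname(p), year,
                                    list(payer_source_value = memb$kv_ik[i],
                                         plan_source_value = memb$kassenart[i]), db)
  }

  # RSC day counts as observations with local concepts
  rsc <- f1_view(ctx$ds, "vers_rsc")
  rp <- db$person_ids[rsc$psid]
  unknown <- is.na(rp)
  count_skip(ctx, "vers_rsc_unknown_psid", sum(unknown))
  rsc <- rsc[!unknown, , drop = FALSE]; rp <- unname(rp[!unknown])
  jan1 <- as.Date(sprintf("%04d-01-01", year))
  for (spec in list(c("em_rente_tage", 2000000001, "HDL-EMRT"),
                    c("erstattung_tage", 2000000002, "HDL-ERST"),
                    c("krankengeld_tage", 2000000003, "HDL-KGLD"))) {
    v <- as_num(rsc[[spec[[1]]]])
    has <- !is.na(v)
    append_value_obs(db, rp[has], as.numeric(spec[[2]]), jan1,
                     value_num = v[has], source_value = spec[[3]])
  }
  invisible(db)
}

#' @rdname run_format1
#' @export
etl1_diagnoses <- function(ctx) {
  db <- ctx$db; year <- ctx$year; store <- ctx$store

  ## inpatient diagnoses: one visit per source row, discharge month + case
  ## enumerator give the imputed, order-preserving start date
  kh <- f1_view(ctx$ds, "kh_diagnosen")
  pid <- db$person_ids[kh$psid]
  unknown <- is.na(pid)
  count_skip(ctx, "kh_unknown_psid", sum(unknown))
  month <- as_int(kh$entlassungsmonat)
  fall <- as_int(kh$fall)
  bad <- !unknown & (is.na(month) | month < 1L | month > 12L | is.na(fall) | fall < 1L)
  count_skip(ctx, "kh_bad_period", sum(bad))
  keep <- !unknown & !bad
  kh <- kh[keep, , drop = FALSE]; pid <- unname(pid[keep])
  month <- month[keep]; fall <- fall[keep]
  n <- nrow(kh)
  if (n) {
    start <- as.Date(sprintf("%04d-%02d-01", year, month)) + (fall - 1L)
    los <- as_num(kh$verweildauer); los[is.na(los)] <- 0
    end <- start + los
    vtype <- ifelse(is_blank(kh$aufnahmeart), "0", kh$aufnahmeart)
    vconcept <- resolve_local(vtype, "visit", store)
    vid <- next_ids(db, "visit_occurrence", n)
    cdm_append(db, "visit_occurrence",
               visit_occurrence_id = vid, person_id = pid,
               visit_concept_id = vconcept, visit_start_date = start,
               visit_end_date = end, visit_type_concept_id = 32810,
               visit_source_value = vtype, visit_source_concept_id = 0,
               admitted_from_concept_id = 0, discharged_to_concept_id = 0,
               discharged_to_source_value = kh$entlassungsgrund)
    # temporary key (psid, year, case) -> visit, consumed when linking events
    db$tmp_visit_keys[paste(kh$psid, year, fall, sep = "|")] <- vid
    status_src <- ifelse(is_blank(kh$diagnoseart), "0", kh$diagnoseart)
    r <- route_codes(kh$icd_code, "ICD10GM", "condition_occurrence", store)
    append_routed(db, r, list(
      person_id = pid, visit_id = vid, start = start, end = end,
      status_concept_id = resolve_local(status_src, "condition_status", store),
      status_source_value = status_src,
      source_concept_id = source_concept_ids(kh$icd_code, "ICD10GM", store)))
  }

  ## outpatient diagnoses: one visit per source row, quarter-imputed date;
  ## the source has no ambulatory visit-type code, so the obligatory visit
  ## concept field carries "0"
  amb <- f1_view(ctx$ds, "amb_diagnosen")
  pid <- db$person_ids[amb$psid]
  unknown <- is.na(pid)
  count_skip(ctx, "amb_unknown_psid", sum(unknown))
  q <- as_int(amb$quartal)
  bad <- !unknown & (is.na(q) | q < 1L | q > 4L)
  count_skip(ctx, "amb_bad_period", sum(bad))
  keep <- !unknown & !bad
  amb <- amb[keep, , drop = FALSE]; pid <- unname(pid[keep]); q <- q[keep]
  n <- nrow(amb)
  if (n) {
    start <- quarter_start(year, q)
    vid <- next_ids(db, "visit_occurrence", n)
    cdm_append(db, "visit_occurrence",
               visit_occurrence_id = vid, person_id = pid,
               visit_concept_id = 0, visit_start_date = start,
               visit_end_date = start, visit_type_concept_id = 32810,
               visit_source_value = "0", visit_source_concept_id = 0,
               admitted_from_concept_id = 0, discharged_to_concept_id = 0)
    excl <- amb$qualifizierung == "A"
    # excluded diagnoses land in observation with concept "Disorder excluded";
    # the ICD code survives as source value
    if (any(excl))
      append_value_obs(db, pid[excl], 4129922, start[excl],
                       source_value = amb$icd_code[excl], visit_id = vid[excl])
    if (any(!excl)) {
      status_src <- ifelse(is_blank(amb$qualifizierung[!excl]), "0",
                           amb$qualifizierung[!excl])
      r <- route_codes(amb$icd_code[!excl], "ICD10GM", "condition_occurrence", store)
      append_routed(db, r, list(
        person_id = pid[!excl], visit_id = vid[!excl],
        start = start[!excl], end = start[!excl],
        status_concept_id = resolve_local(status_src, "condition_status", store),
        status_source_value = status_src,
        source_concept_id = source_concept_ids(amb$icd_code[!excl], "ICD10GM", store)))
    }
  }
  invisible(db)
}

#' @rdname run_format1
#' @export
etl1_events <- function(ctx) {
  db <- ctx$db; year <- ctx$year

  # blood purification: neither date nor session count is delivered ->
  # exactly one dialysis procedure dated January 1st of the reported year
  bp <- f1_view(ctx$ds, "blutreinigung")
  bp <- bp[bp$blutreinigung_kz == "1", , drop = FALSE]
  pid <- db$person_ids[bp$psid]
  count_skip(ctx, "blutreinigung_unknown_psid", sum(is.na(pid)))
  pid <- unname(pid[!is.na(pid)])
  if (length(pid))
    cdm_append(db, "procedure_occurrence",
               procedure_occurrence_id = next_ids(db, "procedure_occurrence", length(pid)),
               person_id = pid, procedure_concept_id = 4032243,
               procedure_date = as.Date(sprintf("%04d-01-01", year)),
               procedure_type_concept_id = 32810, modifier_concept_id = 0,
               procedure_source_value = "blutreinigung",
               procedure_source_concept_id = 0)

  # drugs: PZN has no mapping -> concept 0, PZN as source value, +29-day end
  rx <- f1_view(ctx$ds, "arzneimittel")
  pid <- db$person_ids[rx$psid]
  unknown <- is.na(pid)
  start <- iso_date(rx$verordnungsdatum)
  bad <- !unknown & is.na(start)
  count_skip(ctx, "arzneimittel_unknown_psid", sum(unknown))
  count_skip(ctx, "arzneimittel_bad_date", sum(bad))
  keep <- !unknown & !bad
  rx <- rx[keep, , drop = FALSE]; pid <- unname(pid[keep]); start <- start[keep]
  n <- nrow(rx)
  if (n) {
    iv <- drug_interval(start)
    qty <- as_num(rx$menge) * ifelse(is.na(as_num(rx$faktor)), 1, as_num(rx$faktor))
    did <- next_ids(db, "drug_exposure", n)
    cdm_append(db, "drug_exposure",
               drug_exposure_id = did, person_id = pid, drug_concept_id = 0,
               drug_exposure_start_date = iv$start, drug_exposure_end_date = iv$end,
               drug_type_concept_id = 32810, quantity = qty,
               drug_source_value = rx$pzn, drug_source_concept_id = 0,
               route_concept_id = 0)
    zuz <- as_num(rx$zuzahlung)
    has <- !is.na(zuz)
    if (any(has))
      cdm_append(db, "cost",
                 cost_id = next_ids(db, "cost", sum(has)),
                 cost_event_id = did[has], cost_domain_id = "Drug",
                 cost_type_concept_id = 2005000017, currency_concept_id = 0,
                 paid_patient_copay = zuz[has],
                 payer_plan_period_id = as.numeric(db$payer_ids[rx$vsid[has]]),
                 drug_source_value = rx$pzn[has])
  }

  # expenditures: amount + cost type, linked to the insurance period;
  # negative amounts are billing corrections and are kept
  ag <- f1_view(ctx$ds, "ausgaben")
  ppp <- db$payer_ids[ag$vsid]
  count_skip(ctx, "ausgaben_unknown_vsid", sum(is.na(ppp)))
  ag <- ag[!is.na(ppp), , drop = FALSE]; ppp <- as.numeric(ppp[!is.na(ppp)])
  for (col in names(.f1_cost_types)) {
    v <- as_num(ag[[col]])
    has <- !is.na(v)
    if (!any(has)) next
    cdm_append(db, "cost",
               cost_id = next_ids(db, "cost", sum(has)),
               cost_domain_id = NA_character_,
               cost_type_concept_id = .f1_cost_types[[col]], currency_concept_id = 0,
               total_cost = v[has], payer_plan_period_id = ppp[has])
  }
  invisible(db)
}

#' Run the Format 1 ETL for one reported year
#'
#' Executes the three stages in their mandated order (insured persons and
#' membership, then diagnoses with their visits, then remaining events) and
#' records a run manifest (row counts in, skip counts) on the database.
#' Multiple years are handled by calling this sequentially on the same `db`;
#' persons reappearing across years keep their `person_id` and get their
#' observation period extended.
#'
#' @param dataset a validated Format 1 [source_dataset()].
#' @param store a `vocabulary_store`.
#' @param db a [cdm_new()] database (possibly already holding earlier years).
#' @return `db`, with the manifest entry appended.
#' @export
run_format1 <- function(dataset, store, db) {
  stopifnot(inherits(dataset, "source_dataset"))
  if (!dataset$format_id %in% c(1L, 2L)) abort("dataset is not Format 1/2")
  ctx <- new_f1_context(dataset, store, db)
  etl1_insured(ctx)
  etl1_diagnoses(ctx)
  etl1_events(ctx)
  db$manifest[[sprintf("format1:%d", dataset$reported_year)]] <- list(
    rows_in = vapply(dataset$tables, nrow, 0L),
    skips = as.list(ctx$skips),
    rows_out = vapply(db$tables, nrow, 0L))
  db
}
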