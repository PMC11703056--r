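# Transformation of Format 3. The four schemas are independent of each other;
# within a schema the case IDs (resolved via vsid) link case tables to their
# diagnosis/procedure/cost detail tables. Dates follow the precision cascade
# day > quarter > year: whenever a day-precise date exists it is used exactly.

.f3_uses <- list(
  vers_person = c("gebjahr", "gebmonat", "geschlecht", "verstorben",
                  "sterbedatum", "sterbequartal"),
  vers_zeiten = c("kv_ik", "kassenart", "quartal", "versichertentage",
                  "pflegegrad", "zuzahlungsbefreit_kz", "mitgliedsart"),
  vers_wohnort = c("gkz", "bundesland", "kreis", "plz"),
  vers_dmp = c("dmp_typ", "einschreibedatum", "austrittsdatum", "dmp_status"),
  am_rezepte = c("pzn", "verordnungsdatum", "menge", "faktor", "darreichungsform",
                 "packungsgroesse", "autidem_kz", "verordnender_lanr",
                 "verordnender_fachgruppe", "verordnender_bsnr"),
  am_kosten = c("zuzahlung", "gesamtkosten", "bruttobetrag", "festbetrag",
                "apothekenzuschlag"),
  amb_faelle = c("behandlung_von", "behandlung_bis", "quartal", "unfall_kz",
                 "notfall_kz", "lanr", "fachgruppe", "bsnr", "plz_praxis",
                 "praxisart", "blutreinigung_kz", "blutreinigung_datum",
                 "blutreinigung_anzahl"),
  amb_diagnosen = c("icd_code", "qualifizierung", "lokalisation"),
  amb_ops = c("ops_code", "ops_datum", "lokalisation", "anzahl"),
  amb_leistungen = c("uas_ziffer", "datum", "anzahl", "bruttobetrag",
                     "punktzahl", "eigenanteil"),
  zahn_faelle = c("behandlungstag", "behandlungsende", "quartal", "behandlungsart",
                  "zahnarzt_lanr", "fallkosten", "laborkosten", "fremdlaborkosten",
                  "versichertenanteil"),
  zahn_befunde = c("befund", "befundart", "befunddatum"),
  zahn_leistungen = c("leistungsgruppe", "gebnr", "datum", "anzahl"),
  kh_faelle = c("aufnahmedatum", "entlassungsdatum", "aufnahmegrund", "aufnahmeanlass",
                "entlassungsgrund", "behandlungsart", "ik", "ik_plz", "traegerart",
                "aufnahmegewicht", "beatmungsstunden", "intensiv_tage"),
  kh_khdiag = c("icd_code", "diagnoseart", "lokalisation"),
  kh_ops = c("ops_code", "ops_datum", "lokalisation", "anzahl"),
  kh_entgelte = c("entgeltart", "betrag", "entgeltanzahl")
)

f3_view <- function(ds, table) consumed_view(ds, table, .f3_uses)

# day > quarter > year precision cascade
cascade_date <- function(day_str, year, quarter) {
  d <- iso_date(day_str)
  q <- as_int(quarter)
  fallback <- ifelse(!is.na(q) & q >= 1L & q <= 4L,
                     fmt_date(quarter_start(year, ifelse(is.na(q) | q < 1L | q > 4L, 1L, q))),
                     sprintf("%04d-01-01", year))
  as.Date(ifelse(is.na(d), fallback, fmt_date(d)))
}

# ICD-10-GM with embedded special characters / localisation: map the bare
# code, keep the original (plus a separate localisation field) as source value
f3_icd_parts <- function(code, lokalisation) {
  nm <- normalize_icd_gm(code)
  src <- ifelse(is_blank(lokalisation), code, paste(code, lokalisation))
  list(clean = nm$clean, source = src)
}

vec_providers <- function(db, lanr, specialty_code, care_site_id, store) {
  vapply(seq_along(lanr), function(i) {
    if (is_blank(lanr[i])) return(NA_real_)
    cid <- resolve_local(specialty_code[i], "specialty", store)
    upsert_provider(lanr[i], list(
      specialty_concept_id = as.numeric(cid),
      specialty_source_value = if (is_blank(specialty_code[i])) NA_character_ else specialty_code[i],
      care_site_id = care_site_id[i]), db)
  }, 0)
}

vec_care_sites <- function(db, key, plz, pos_source) {
  vapply(seq_along(key), function(i) {
    if (is_blank(key[i])) return(NA_real_)
    loc <- if (!is_blank(plz[i]))
      upsert_location(paste0("plz:", plz[i]), list(zip = plz[i]), db) else NA_real_
    upsert_care_site(key[i], list(location_id = loc,
                                  place_of_service_source_value = pos_source[i]), db)
  }, 0)
}

#' @rdname run_format3
#' @export
etl3_insured <- function(ctx) {
  db <- ctx$db; year <- ctx$year; store <- ctx$store
  vp <- f3_view(ctx$ds, "vers_person")
  wo <- f3_view(ctx$ds, "vers_wohnort")

  loc_ids <- vapply(seq_len(nrow(wo)), function(i)
    upsert_location(wo$gkz[i], list(state = wo$bundesland[i], county = wo$kreis[i],
                                    zip = wo$plz[i]), db), 0)
  person_loc <- stats::setNames(loc_ids, wo$psid)

  pid <- upsert_persons(data.frame(
    psid = vp$psid, gender = vp$geschlecht,
    year_of_birth = as_num(vp$gebjahr), month_of_birth = as_num(vp$gebmonat),
    location_id = as.numeric(person_loc[vp$psid]),
    stringsAsFactors = FALSE), year, db)

  # death: the day is provided; degrade gracefully to quarter end, then Dec 31
  dead <- vp$verstorben == "1"
  if (any(dead)) {
    d <- iso_date(vp$sterbedatum[dead])
    q <- as_int(vp$sterbequartal[dead])
    fb <- ifelse(!is.na(q) & q >= 1 & q <= 4,
                 fmt_date(quarter_end(year, ifelse(is.na(q) | q < 1 | q > 4, 4L, q))),
                 fmt_date(death_date(year)))
    add_death(db, pid[dead], as.Date(ifelse(is.na(d), fb, fmt_date(d))))
  }

  # insurance relationships: one observation period per health insurance per
  # year spanning first-seen to last-seen quarter (interior quarters assumed
  # covered); overlapping periods of one person are merged on extension
  vz <- f3_view(ctx$ds, "vers_zeiten")
  vzp <- db$person_ids[vz$psid]
  unknown <- is.na(vzp)
  count_skip(ctx, "vers_zeiten_unknown_psid", sum(unknown))
  vz <- vz[!unknown, , drop = FALSE]; vzp <- unname(vzp[!unknown])
  if (nrow(vz)) {
    q <- as_int(vz$quartal)
    ok <- !is.na(q) & q >= 1L & q <= 4L
    count_skip(ctx, "vers_zeiten_bad_quarter", sum(!ok))
    agg <- stats::aggregate(cbind(qmin = q[ok], qmax = q[ok]),
                            by = list(vsid = vz$vsid[ok], person_id = vzp[ok],
                                      kv_ik = vz$kv_ik[ok], kassenart = vz$kassenart[ok],
                                      mitgliedsart = vz$mitgliedsart[ok]),
                            FUN = function(x) x[1])
    qmin <- tapply(q[ok], vz$vsid[ok], min)
    qmax <- tapply(q[ok], vz$vsid[ok], max)
    for (i in seq_len(nrow(agg))) {
      v <- agg$vsid[i]
      get_or_create_payer_plan_period(v, agg$person_id[i], year,
                                      list(payer_source_value = agg$kv_ik[i],
                                           plan_source_value = agg$mitgliedsart[i],
                                           sponsor_source_value = agg$kassenart[i]), db)
      extend_observation_period(agg$person_id[i],
                                quarter_start(year, qmin[[v]]),
                                quarter_end(year, qmax[[v]]), db)
    }
    jan1 <- as.Date(sprintf("%04d-01-01", year))
    # insured days (usable in Format 3), care level, copayment exemption
    days <- tapply(as_num(vz$versichertentage), vz$vsid, sum, na.rm = TRUE)
    vs_person <- tapply(vzp, vz$vsid, function(x) x[1])
    append_value_obs(db, as.numeric(vs_person[names(days)]), 2000000004, jan1,
                     value_num = as.numeric(days), source_value = "HDL-VTAGE")
    pg <- as_num(vz$pflegegrad)
    has <- !is.na(pg)
    append_value_obs(db, vzp[has], 2000000005, jan1, value_num = pg[has],
                     source_value = "HDL-PFLEGE")
    zb <- vz$zuzahlungsbefreit_kz == "1"
    append_value_obs(db, vzp[zb], 2000000006, jan1, value_num = 1,
                     source_value = "HDL-ZUZBEF")
  }

  # disease management programs -> procedures via local mapping (concept 0
  # when no similar procedure code exists)
  dmp <- f3_view(ctx$ds, "vers_dmp")
  dp <- db$person_ids[dmp$psid]
  count_skip(ctx, "vers_dmp_unknown_psid", sum(is.na(dp)))
  dmp <- dmp[!is.na(dp), , drop = FALSE]; dp <- unname(dp[!is.na(dp)])
  n <- nrow(dmp)
  if (n) {
    start <- cascade_date(dmp$einschreibedatum, year, NA)
    end <- iso_date(dmp$austrittsdatum)
    cdm_append(db, "procedure_occurrence",
               procedure_occurrence_id = next_ids(db, "procedure_occurrence", n),
               person_id = dp,
               procedure_concept_id = as.numeric(resolve_local(dmp$dmp_typ, "dmp", store)),
               procedure_date = start, procedure_end_date = end,
               procedure_type_concept_id = 32810, modifier_concept_id = 0,
               procedure_source_value = dmp$dmp_typ, procedure_source_concept_id = 0)
    append_value_obs(db, dp, 2000000010, start, value_str = dmp$dmp_status,
                     source_value = "HDL-DMPST")
  }
  invisible(db)
}

#' @rdname run_format3
#' @export
etl3_hospital <- function(ctx) {
  db <- ctx$db; year <- ctx$year; store <- ctx$store
  kf <- f3_view(ctx$ds, "kh_faelle")
  pid <- db$person_ids[kf$psid]
  unknown <- is.na(pid)
  count_skip(ctx, "kh_faelle_unknown_psid", sum(unknown))
  kf <- kf[!unknown, , drop = FALSE]; pid <- unname(pid[!unknown])
  n <- nrow(kf)
  if (n) {
    start <- cascade_date(kf$aufnahmedatum, year, NA)
    end0 <- iso_date(kf$entlassungsdatum)
    end <- as.Date(ifelse(is.na(end0), fmt_date(start), fmt_date(end0)))
    cs <- vec_care_sites(db, kf$ik, kf$ik_plz, kf$traegerart)
    vtype <- ifelse(is_blank(kf$behandlungsart), "0", kf$behandlungsart)
    vid <- next_ids(db, "visit_occurrence", n)
    cdm_append(db, "visit_occurrence",
               visit_occurrence_id = vid, person_id = pid,
               visit_concept_id = as.numeric(resolve_local(vtype, "visit", store)),
               visit_start_date = start, visit_end_date = end,
               visit_type_concept_id = 32810, care_site_id = cs,
               visit_source_value = vtype, visit_source_concept_id = 0,
               admitted_from_concept_id = 0, admitted_from_source_value = kf$aufnahmegrund,
               discharged_to_concept_id = 0, discharged_to_source_value = kf$entlassungsgrund)
    db$tmp_visit_keys[paste0("kh|", kf$kh_fallnr)] <- vid
    # admission reason kept via local concept; admission occasion as qualifier
    append_value_obs(db, pid, 2000000008, start, value_str = kf$aufnahmegrund,
                     source_value = "HDL-AUFNGR", visit_id = vid,
                     qualifier = kf$aufnahmeanlass)
    for (spec in list(list("aufnahmegewicht", 2002000002, "HDL-AUFNGEW"),
                      list("beatmungsstunden", 2002000001, "HDL-BEATM"))) {
      v <- as_num(kf[[spec[[1]]]])
      has <- !is.na(v)
      if (any(has))
        cdm_append(db, "measurement",
                   measurement_id = next_ids(db, "measurement", sum(has)),
                   person_id = pid[has], measurement_concept_id = spec[[2]],
                   measurement_date = start[has], measurement_type_concept_id = 32810,
                   operator_concept_id = 0, value_as_number = v[has],
                   value_as_concept_id = 0, unit_concept_id = 0,
                   measurement_source_value = spec[[3]], measurement_source_concept_id = 0,
                   visit_occurrence_id = vid[has])
    }
    its <- as_num(kf$intensiv_tage)
    has <- !is.na(its)
    append_value_obs(db, pid[has], 2000000009, start[has], value_num = its[has],
                     source_value = "HDL-ITS", visit_id = vid[has])

    case_start <- stats::setNames(start, kf$kh_fallnr)
    case_end <- stats::setNames(end, kf$kh_fallnr)
    case_pid <- stats::setNames(pid, kf$kh_fallnr)

    # diagnoses from khdiag carry no dates: start/end come from the case table
    dg <- f3_view(ctx$ds, "kh_khdiag")
    vmatch <- db$tmp_visit_keys[paste0("kh|", dg$kh_fallnr)]
    bad <- is.na(vmatch)
    count_skip(ctx, "kh_khdiag_unknown_case", sum(bad))
    dg <- dg[!bad, , drop = FALSE]; vmatch <- unname(vmatch[!bad])
    if (nrow(dg)) {
      parts <- f3_icd_parts(dg$icd_code, dg$lokalisation)
      status_src <- ifelse(is_blank(dg$diagnoseart), "0", dg$diagnoseart)
      r <- route_codes(parts$clean, "ICD10GM", "condition_occurrence", store)
      append_routed(db, r, list(
        person_id = as.numeric(case_pid[dg$kh_fallnr]), visit_id = vmatch,
        start = as.Date(case_start[dg$kh_fallnr]), end = as.Date(case_end[dg$kh_fallnr]),
        status_concept_id = resolve_local(status_src, "condition_status", store),
        status_source_value = status_src, source_value = parts$source,
        source_concept_id = source_concept_ids(parts$clean, "ICD10GM", store)))
    }

    # OPS: domain routing as for diagnoses; localisation only as source value
    op <- f3_view(ctx$ds, "kh_ops")
    vmatch <- db$tmp_visit_keys[paste0("kh|", op$kh_fallnr)]
    bad <- is.na(vmatch)
    count_skip(ctx, "kh_ops_unknown_case", sum(bad))
    op <- op[!bad, , drop = FALSE]; vmatch <- unname(vmatch[!bad])
    if (nrow(op)) {
      d <- iso_date(op$ops_datum)
      start_op <- as.Date(ifelse(is.na(d), fmt_date(as.Date(case_start[op$kh_fallnr])), fmt_date(d)))
      r <- route_codes(op$ops_code, "OPS", "procedure_occurrence", store)
      append_routed(db, r, list(
        person_id = as.numeric(case_pid[op$kh_fallnr]), visit_id = vmatch,
        start = start_op, end = start_op, quantity = as_num(op$anzahl),
        modifier = ifelse(is_blank(op$lokalisation), NA_character_, op$lokalisation),
        source_concept_id = source_concept_ids(op$ops_code, "OPS", store)))
    }

    # case payments -> cost rows linked to the visit
    eg <- f3_view(ctx$ds, "kh_entgelte")
    vmatch <- db$tmp_visit_keys[paste0("kh|", eg$kh_fallnr)]
    bad <- is.na(vmatch)
    count_skip(ctx, "kh_entgelte_unknown_case", sum(bad))
    eg <- eg[!bad, , drop = FALSE]; vmatch <- unname(vmatch[!bad])
    if (nrow(eg)) {
      amt <- as_num(eg$betrag) * ifelse(is.na(as_num(eg$entgeltanzahl)), 1,
                                        as_num(eg$entgeltanzahl))
      cdm_append(db, "cost",
                 cost_id = next_ids(db, "cost", nrow(eg)),
                 cost_event_id = vmatch, cost_domain_id = "Visit",
                 cost_type_concept_id = 2005000012, currency_concept_id = 0,
                 total_cost = amt, revenue_code_concept_id = 0,
                 revenue_code_source_value = eg$entgeltart,
                 payer_plan_period_id = as.numeric(db$payer_ids[eg$vsid]))
    }
  }
  invisible(db)
}

#' @rdname run_format3
#' @export
etl3_ambulatory <- function(ctx) {
  db <- ctx$db; year <- ctx$year; store <- ctx$store
  af <- f3_view(ctx$ds, "amb_faelle")
  pid <- db$person_ids[af$psid]
  unknown <- is.na(pid)
  count_skip(ctx, "amb_faelle_unknown_psid", sum(unknown))
  af <- af[!unknown, , drop = FALSE]; pid <- unname(pid[!unknown])
  n <- nrow(af)
  if (n == 0L) return(invisible(db))
  start <- cascade_date(af$behandlung_von, year, af$quartal)
  end0 <- iso_date(af$behandlung_bis)
  end <- as.Date(ifelse(is.na(end0), fmt_date(start), fmt_date(end0)))
  cs <- vec_care_sites(db, af$bsnr, af$plz_praxis, af$praxisart)
  prov <- vec_providers(db, af$lanr, af$fachgruppe, cs, store)
  vsrc <- ifelse(af$notfall_kz == "1", "NOTFALL", "AMB")
  vid <- next_ids(db, "visit_occurrence", n)
  cdm_append(db, "visit_occurrence",
             visit_occurrence_id = vid, person_id = pid,
             visit_concept_id = as.numeric(resolve_local(vsrc, "visit", store)),
             visit_start_date = start, visit_end_date = end,
             visit_type_concept_id = 32810, provider_id = prov, care_site_id = cs,
             visit_source_value = vsrc, visit_source_concept_id = 0,
             admitted_from_concept_id = 0, discharged_to_concept_id = 0)
  db$tmp_visit_keys[paste0("amb|", af$amb_fallnr)] <- vid
  # accident-caused visits become an observation
  acc <- af$unfall_kz == "1"
  append_value_obs(db, pid[acc], 2000000007, start[acc], value_num = 1,
                   source_value = "HDL-UNFALL", visit_id = vid[acc])
  # blood purification with day-precise date
  bp <- af$blutreinigung_kz == "1"
  if (any(bp)) {
    d <- iso_date(af$blutreinigung_datum[bp])
    bd <- as.Date(ifelse(is.na(d), fmt_date(start[bp]), fmt_date(d)))
    cdm_append(db, "procedure_occurrence",
               procedure_occurrence_id = next_ids(db, "procedure_occurrence", sum(bp)),
               person_id = pid[bp], procedure_concept_id = 4032243,
               procedure_date = bd, procedure_type_concept_id = 32810,
               modifier_concept_id = 0, quantity = as_num(af$blutreinigung_anzahl[bp]),
               procedure_source_value = "blutreinigung", procedure_source_concept_id = 0,
               visit_occurrence_id = vid[bp])
  }
  case_start <- stats::setNames(start, af$amb_fallnr)
  case_pid <- stats::setNames(pid, af$amb_fallnr)

  # diagnoses: special characters and localisation are kept as source value,
  # the bare code is mapped; excluded diagnoses go to observation only
  dg <- f3_view(ctx$ds, "amb_diagnosen")
  vmatch <- db$tmp_visit_keys[paste0("amb|", dg$amb_fallnr)]
  bad <- is.na(vmatch)
  count_skip(ctx, "amb_diagnosen_unknown_case", sum(bad))
  dg <- dg[!bad, , drop = FALSE]; vmatch <- unname(vmatch[!bad])
  if (nrow(dg)) {
    parts <- f3_icd_parts(dg$icd_code, dg$lokalisation)
    dstart <- as.Date(case_start[dg$amb_fallnr])
    dpid <- as.numeric(case_pid[dg$amb_fallnr])
    excl <- dg$qualifizierung == "A"
    append_value_obs(db, dpid[excl], 4129922, dstart[excl],
                     source_value = parts$source[excl], visit_id = vmatch[excl])
    if (any(!excl)) {
      status_src <- ifelse(is_blank(dg$qualifizierung[!excl]), "0", dg$qualifizierung[!excl])
      r <- route_codes(parts$clean[!excl], "ICD10GM", "condition_occurrence", store)
      append_routed(db, r, list(
        person_id = dpid[!excl], visit_id = vmatch[!excl],
        start = dstart[!excl], end = dstart[!excl],
        status_concept_id = resolve_local(status_src, "condition_status", store),
        status_source_value = status_src, source_value = parts$source[!excl],
        source_concept_id = source_concept_ids(parts$clean[!excl], "ICD10GM", store)))
    }
  }

  op <- f3_view(ctx$ds, "amb_ops")
  vmatch <- db$tmp_visit_keys[paste0("amb|", op$amb_fallnr)]
  bad <- is.na(vmatch)
  count_skip(ctx, "amb_ops_unknown_case", sum(bad))
  op <- op[!bad, , drop = FALSE]; vmatch <- unname(vmatch[!bad])
  if (nrow(op)) {
    d <- iso_date(op$ops_datum)
    ostart <- as.Date(ifelse(is.na(d), fmt_date(as.Date(case_start[op$amb_fallnr])), fmt_date(d)))
    r <- route_codes(op$ops_code, "OPS", "procedure_occurrence", store)
    append_routed(db, r, list(
      person_id = as.numeric(case_pid[op$amb_fallnr]), visit_id = vmatch,
      start = ostart, end = ostart, quantity = as_num(op$anzahl),
      modifier = ifelse(is_blank(op$lokalisation), NA_character_, op$lokalisation),
      source_concept_id = source_concept_ids(op$ops_code, "OPS", store)))
  }

  # tariff numbers -> procedures via the pluggable UAS mapping; the total
  # charge per tariff goes to the cost table
  ls <- f3_view(ctx$ds, "amb_leistungen")
  vmatch <- db$tmp_visit_keys[paste0("amb|", ls$amb_fallnr)]
  bad <- is.na(vmatch)
  count_skip(ctx, "amb_leistungen_unknown_case", sum(bad))
  ls <- ls[!bad, , drop = FALSE]; vmatch <- unname(vmatch[!bad])
  if (nrow(ls)) {
    d <- iso_date(ls$datum)
    lstart <- as.Date(ifelse(is.na(d), fmt_date(as.Date(case_start[ls$amb_fallnr])), fmt_date(d)))
    lpid <- as.numeric(case_pid[ls$amb_fallnr])
    prid <- next_ids(db, "procedure_occurrence", nrow(ls))
    cdm_append(db, "procedure_occurrence",
               procedure_occurrence_id = prid, person_id = lpid,
               procedure_concept_id = as.numeric(resolve_local(ls$uas_ziffer, "uas", store)),
               procedure_date = lstart, procedure_type_concept_id = 32810,
               modifier_concept_id = 0, quantity = as_num(ls$anzahl),
               procedure_source_value = ls$uas_ziffer, procedure_source_concept_id = 0,
               visit_occurrence_id = vmatch)
    cdm_append(db, "cost",
               cost_id = next_ids(db, "cost", nrow(ls)),
               cost_event_id = prid, cost_domain_id = "Procedure",
               cost_type_concept_id = 2005000013, currency_concept_id = 0,
               total_charge = as_num(ls$bruttobetrag),
               paid_by_patient = as_num(ls$eigenanteil),
               amount_allowed = as_num(ls$punktzahl),
               revenue_code_concept_id = 0, revenue_code_source_value = ls$uas_ziffer,
               payer_plan_period_id = as.numeric(db$payer_ids[ls$vsid]))
  }
  invisible(db)
}

#' @rdname run_format3
#' @export
etl3_dental <- function(ctx) {
  db <- ctx$db; year <- ctx$year; store <- ctx$store
  zf <- f3_view(ctx$ds, "zahn_faelle")
  pid <- db$person_ids[zf$psid]
  unknown <- is.na(pid)
  count_skip(ctx, "zahn_faelle_unknown_psid", sum(unknown))
  zf <- zf[!unknown, , drop = FALSE]; pid <- unname(pid[!unknown])
  n <- nrow(zf)
  if (n == 0L) return(invisible(db))
  # treatment day if given, else first day of the quarter; a dental visit is
  # assumed to last no longer than one day when no end date is delivered
  start <- cascade_date(zf$behandlungstag, year, zf$quartal)
  end0 <- iso_date(zf$behandlungsende)
  end <- as.Date(ifelse(is.na(end0), fmt_date(start), fmt_date(end0)))
  prov <- vec_providers(db, zf$zahnarzt_lanr, rep("", n), rep(NA_real_, n), store)
  vid <- next_ids(db, "visit_occurrence", n)
  cdm_append(db, "visit_occurrence",
             visit_occurrence_id = vid, person_id = pid,
             visit_concept_id = as.numeric(resolve_local(rep("DENT", n), "visit", store)),
             visit_start_date = start, visit_end_date = end,
             visit_type_concept_id = 32810, provider_id = prov,
             visit_source_value = zf$behandlungsart, visit_source_concept_id = 0,
             admitted_from_concept_id = 0, discharged_to_concept_id = 0)
  db$tmp_visit_keys[paste0("zahn|", zf$zahn_fallnr)] <- vid
  # all dental costs (case + lab + external lab) summed into one row
  costs <- cbind(as_num(zf$fallkosten), as_num(zf$laborkosten), as_num(zf$fremdlaborkosten))
  total <- rowSums(costs, na.rm = TRUE)
  cdm_append(db, "cost",
             cost_id = next_ids(db, "cost", n),
             cost_event_id = vid, cost_domain_id = "Visit",
             cost_type_concept_id = 2005000011, currency_concept_id = 0,
             total_cost = total, paid_by_patient = as_num(zf$versichertenanteil),
             payer_plan_period_id = as.numeric(db$payer_ids[zf$vsid]))
  case_start <- stats::setNames(start, zf$zahn_fallnr)
  case_pid <- stats::setNames(pid, zf$zahn_fallnr)

  # findings: teeth details cannot be represented; the finding itself is kept
  # as a source-value-only observation
  bf <- f3_view(ctx$ds, "zahn_befunde")
  vmatch <- db$tmp_visit_keys[paste0("zahn|", bf$zahn_fallnr)]
  bad <- is.na(vmatch)
  count_skip(ctx, "zahn_befunde_unknown_case", sum(bad))
  bf <- bf[!bad, , drop = FALSE]; vmatch <- unname(vmatch[!bad])
  if (nrow(bf)) {
    d <- iso_date(bf$befunddatum)
    bstart <- as.Date(ifelse(is.na(d), fmt_date(as.Date(case_start[bf$zahn_fallnr])), fmt_date(d)))
    append_value_obs(db, as.numeric(case_pid[bf$zahn_fallnr]), 2000000011, bstart,
                     value_str = bf$befund, source_value = bf$befund,
                     visit_id = vmatch, qualifier = bf$befundart)
  }

  # the five service groups map directly to standard concepts; the original
  # group and fee number are retained as source value
  zl <- f3_view(ctx$ds, "zahn_leistungen")
  vmatch <- db$tmp_visit_keys[paste0("zahn|", zl$zahn_fallnr)]
  bad <- is.na(vmatch)
  count_skip(ctx, "zahn_leistungen_unknown_case", sum(bad))
  zl <- zl[!bad, , drop = FALSE]; vmatch <- unname(vmatch[!bad])
  if (nrow(zl)) {
    d <- iso_date(zl$datum)
    lstart <- as.Date(ifelse(is.na(d), fmt_date(as.Date(case_start[zl$zahn_fallnr])), fmt_date(d)))
    cdm_append(db, "procedure_occurrence",
               procedure_occurrence_id = next_ids(db, "procedure_occurrence", nrow(zl)),
               person_id = as.numeric(case_pid[zl$zahn_fallnr]),
               procedure_concept_id = as.numeric(resolve_local(zl$leistungsgruppe,
                                                               "dental_group", store)),
               procedure_date = lstart, procedure_type_concept_id = 32810,
               modifier_concept_id = 0, quantity = as_num(zl$anzahl),
               procedure_source_value = paste0("G", zl$leistungsgruppe, "/", zl$gebnr),
               procedure_source_concept_id = 0, visit_occurrence_id = vmatch)
  }
  invisible(db)
}

#' @rdname run_format3
#' @export
etl3_drugs <- function(ctx) {
  db <- ctx$db; year <- ctx$year; store <- ctx$store
  rx <- f3_view(ctx$ds, "am_rezepte")
  pid <- db$person_ids[rx$psid]
  unknown <- is.na(pid)
  start <- iso_date(rx$verordnungsdatum)
  bad <- !unknown & is.na(start)
  count_skip(ctx, "am_rezepte_unknown_psid", sum(unknown))
  count_skip(ctx, "am_rezepte_bad_date", sum(bad))
  keep <- !unknown & !bad
  rx <- rx[keep, , drop = FALSE]; pid <- unname(pid[keep]); start <- start[keep]
  n <- nrow(rx)
  if (n == 0L) return(invisible(db))
  cs <- vec_care_sites(db, rx$verordnender_bsnr, rep("", n), rep(NA_character_, n))
  prov <- vec_providers(db, rx$verordnender_lanr, rx$verordnender_fachgruppe, cs, store)
  iv <- drug_interval(start)
  qty <- as_num(rx$menge) * ifelse(is.na(as_num(rx$faktor)), 1, as_num(rx$faktor))
  did <- next_ids(db, "drug_exposure", n)
  cdm_append(db, "drug_exposure",
             drug_exposure_id = did, person_id = pid, drug_concept_id = 0,
             drug_exposure_start_date = iv$start, drug_exposure_end_date = iv$end,
             drug_type_concept_id = 32810, quantity = qty,
             sig = paste0("form=", rx$darreichungsform, ";autidem=", rx$autidem_kz),
             dose_unit_source_value = rx$packungsgroesse,
             provider_id = prov, drug_source_value = rx$pzn,
             drug_source_concept_id = 0, route_concept_id = 0)
  rx_did <- stats::setNames(did, rx$am_fallnr)

  # pharmacy costs: one row each for paid-by-patient, total costs (with
  # reference price and dispensing surcharge), and total charge
  ko <- f3_view(ctx$ds, "am_kosten")
  dmatch <- rx_did[ko$am_fallnr]
  bad <- is.na(dmatch)
  count_skip(ctx, "am_kosten_unknown_case", sum(bad))
  ko <- ko[!bad, , drop = FALSE]; dmatch <- unname(dmatch[!bad])
  m <- nrow(ko)
  if (m) {
    ppp <- as.numeric(db$payer_ids[ko$vsid])
    pzn <- db$tables$drug_exposure$drug_source_value[
      match(dmatch, db$tables$drug_exposure$drug_exposure_id)]
    cdm_append(db, "cost", cost_id = next_ids(db, "cost", m),
               cost_event_id = dmatch, cost_domain_id = "Drug",
               cost_type_concept_id = 2005000014, currency_concept_id = 0,
               paid_by_patient = as_num(ko$zuzahlung),
               payer_plan_period_id = ppp, drug_source_value = pzn)
    cdm_append(db, "cost", cost_id = next_ids(db, "cost", m),
               cost_event_id = dmatch, cost_domain_id = "Drug",
               cost_type_concept_id = 2005000015, currency_concept_id = 0,
               total_cost = as_num(ko$gesamtkosten),
               amount_allowed = as_num(ko$festbetrag),
               paid_dispensing_fee = as_num(ko$apothekenzuschlag),
               payer_plan_period_id = ppp, drug_source_value = pzn)
    cdm_append(db, "cost", cost_id = next_ids(db, "cost", m),
               cost_event_id = dmatch, cost_domain_id = "Drug",
               cost_type_concept_id = 2005000016, currency_concept_id = 0,
               total_charge = as_num(ko$bruttobetrag),
               payer_plan_period_id = ppp, drug_source_value = pzn)
  }
  invisible(db)
}

#' Run the Format 3 ETL for one reported year
#'
#' Executes the schema stages in order (insured person, hospital, ambulatory,
#' dental, drugs) and records a run manifest. Cross-year behaviour matches
#' Format 1: persons are updated in place and observation periods extended.
#'
#' @param dataset a validated Format 3 [source_dataset()].
#' @param store a `vocabulary_store` (optionally with a UAS tariff mapping
#'   registered under context `"uas"`).
#' @param db a [cdm_new()] database.
#' @return `db`, with the manifest entry appended.
#' @export
run_format3 <- function(dataset, store, db) {
  stopifnot(inherits(dataset, "source_dataset"))
  if (dataset$format_id != 3L) abort("dataset is not Format 3")
  ctx <- new_f1_context(dataset, store, db)
  etl3_insured(ctx)
  etl3_hospital(ctx)
  etl3_ambulatory(ctx)
  etl3_dental(ctx)
  etl3_drugs(ctx)
  db$manifest[[sprintf("format3:%d", dataset$reported_year)]] <- list(
    rows_in = vapply(dataset$tables, nrow, 0L),
    skips = as.list(ctx$skips),
    rows_out = vapply(db$tables, nrow, 0L))
  db
}
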