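#' Source data dictionaries for Format 1 and Format 3
#'
#' The HDL delivers claims data as plain tables whose layout is fixed by the
#' data dictionary of the respective format generation. Format 1 (2009-2016;
#' Format 2 of 2017-2018 is structurally identical) consists of 9 tables keyed
#' by the long-term person pseudonym `psid` and the year/insurer-dependent
#' `vsid`. Format 3 (2019 onwards) is organised into four schemas (insured
#' person, drugs, ambulatory incl. dental, inpatient) with additional
#' schema-specific case IDs.
#'
#' Each schema row classifies one field:
#' \describe{
#'   \item{key}{join key (psid, vsid, schema case ID); not counted in coverage.}
#'   \item{transformed}{consumed by the ETL and represented in the CDM.}
#'   \item{omitted}{deliberately not transformed (administrative, redundant,
#'     empty, or dropped in favour of other detail).}
#'   \item{untransformable}{intended for transformation but without a viable
#'     target in CDM v5.4 (e.g. coded teeth positions).}
#' }
#'
#' The `type` column drives generation and validation: `id`, `int`, `year`,
#' `quarter`, `month`, `date` (ISO-8601), `code`, `amount`, `flag`, `text`.
#'
#' @param format_id 1 or 3 (2 is read with the Format 1 schema).
#' @return A data.frame with columns `schema` (Format 3 only, else `""`),
#'   `table`, `field`, `status`, `type`, `reason`.
#' @export
source_schema <- function(format_id) {
  format_id <- as.integer(format_id)
  if (format_id %in% c(1L, 2L)) return(.f1_schema())
  if (format_id == 3L) return(.f3_schema())
  abort("unknown format_id: ", format_id)
}

fld <- function(table, field, status, type, reason = "", schema = "") {
  data.frame(schema = schema, table = table, field = field, status = status,
             type = type, reason = reason, stringsAsFactors = FALSE)
}

.f1_schema <- function() {
  k <- function(tb, f = c("psid", "vsid")) do.call(rbind, lapply(f, fld, table = tb, status = "key", type = "id"))
  t_ <- function(tb, f, ty) fld(tb, f, "transformed", ty)
  o_ <- function(tb, f, ty, why) fld(tb, f, "omitted", ty, why)
  u_ <- function(tb, f, ty, why) fld(tb, f, "untransformable", ty, why)
  rbind(
    # Insured person demographics (per compensation year)
    k("vers_stamm"),
    t_("vers_stamm", "gebjahr", "year"),
    t_("vers_stamm", "geschlecht", "code"),
    t_("vers_stamm", "verstorben", "flag"),
    t_("vers_stamm", "sterbejahr", "year"),
    o_("vers_stamm", "famstand", "code", "not relevant for research"),
    o_("vers_stamm", "berichtsjahr", "year", "redundant: reported year comes from the run configuration"),
    # RSC: reduced-earning-capacity pension / reimbursed insured days (previous year)
    k("vers_rsc"),
    t_("vers_rsc", "em_rente_tage", "int"),
    t_("vers_rsc", "erstattung_tage", "int"),
    t_("vers_rsc", "krankengeld_tage", "int"),
    # Extracorporeal blood purification
    k("blutreinigung"),
    t_("blutreinigung", "blutreinigung_kz", "flag"),
    u_("blutreinigung", "lokalisation", "code", "Localization of procedure code: missing mapping"),
    # Outpatient drugs
    k("arzneimittel"),
    t_("arzneimittel", "pzn", "code"),
    t_("arzneimittel", "verordnungsdatum", "date"),
    t_("arzneimittel", "menge", "int"),
    t_("arzneimittel", "faktor", "int"),
    t_("arzneimittel", "zuzahlung", "amount"),
    o_("arzneimittel", "apotheke_ik", "id", "pharmacy details not kept"),
    # Inpatient diagnoses (discharge month + case enumerator)
    k("kh_diagnosen"),
    t_("kh_diagnosen", "entlassungsmonat", "month"),
    t_("kh_diagnosen", "fall", "int"),
    t_("kh_diagnosen", "aufnahmeart", "code"),
    t_("kh_diagnosen", "verweildauer", "int"),
    t_("kh_diagnosen", "entlassungsgrund", "code"),
    t_("kh_diagnosen", "icd_code", "code"),
    t_("kh_diagnosen", "diagnoseart", "code"),
    # Outpatient diagnoses (by quarter)
    k("amb_diagnosen"),
    t_("amb_diagnosen", "quartal", "quarter"),
    t_("amb_diagnosen", "icd_code", "code"),
    t_("amb_diagnosen", "qualifizierung", "code"),
    u_("amb_diagnosen", "icd_zusatz", "code",
       "Additional special characters of ICD-10 code: no fitting target field"),
    # Expenditures (wide per account category)
    k("ausgaben"),
    t_("ausgaben", "ausg_kh", "amount"),
    t_("ausgaben", "ausg_amb", "amount"),
    t_("ausgaben", "ausg_arznei", "amount"),
    t_("ausgaben", "ausg_zahn", "amount"),
    t_("ausgaben", "ausg_heilmittel", "amount"),
    t_("ausgaben", "ausg_hilfsmittel", "amount"),
    t_("ausgaben", "ausg_krankengeld", "amount"),
    t_("ausgaben", "ausg_fahrkosten", "amount"),
    t_("ausgaben", "ausg_vorsorge", "amount"),
    t_("ausgaben", "ausg_sonstige", "amount"),
    # Insurance membership (vsid registry)
    k("vers_zeiten"),
    t_("vers_zeiten", "kv_ik", "id"),
    t_("vers_zeiten", "kassenart", "code"),
    u_("vers_zeiten", "versichertentage", "int",
       "Insured days: source lacks coverage start/end information"),
    # Municipality code
    k("gemeinde"),
    t_("gemeinde", "gkz", "code"),
    t_("gemeinde", "bundesland", "code"),
    t_("gemeinde", "kreis", "code"),
    o_("gemeinde", "satzart", "code", "administrative record type")
  )
}

.f3_schema <- function() {
  k <- function(tb, sch, f) do.call(rbind, lapply(f, fld, table = tb, status = "key", type = "id", schema = sch))
  t_ <- function(tb, sch, f, ty) fld(tb, f, "transformed", ty, schema = sch)
  o_ <- function(tb, sch, f, ty, why) fld(tb, f, "omitted", ty, why, schema = sch)
  u_ <- function(tb, sch, f, ty, why) fld(tb, f, "untransformable", ty, why, schema = sch)
  no_target <- "no fitting target field"
  rbind(
    ## schema vers: insured person ------------------------------------------
    k("vers_person", "vers", c("psid", "vsid")),
    t_("vers_person", "vers", "gebjahr", "year"),
    t_("vers_person", "vers", "gebmonat", "month"),
    t_("vers_person", "vers", "geschlecht", "code"),
    t_("vers_person", "vers", "verstorben", "flag"),
    t_("vers_person", "vers", "sterbedatum", "date"),
    t_("vers_person", "vers", "sterbequartal", "quarter"),
    u_("vers_person", "vers", "versstatus", "code", "Insurance status: source lacking details"),
    o_("vers_person", "vers", "berichtsjahr", "year", "redundant: reported year from run configuration"),
    o_("vers_person", "vers", "meldedatum", "date", "administrative transmission date"),
    o_("vers_person", "vers", "pruefsumme", "code", "internal check sum"),
    o_("vers_person", "vers", "titel", "text", "empty placeholder"),
    k("vers_zeiten", "vers", c("psid", "vsid")),
    t_("vers_zeiten", "vers", "kv_ik", "id"),
    t_("vers_zeiten", "vers", "kassenart", "code"),
    t_("vers_zeiten", "vers", "quartal", "quarter"),
    t_("vers_zeiten", "vers", "versichertentage", "int"),
    t_("vers_zeiten", "vers", "pflegegrad", "int"),
    t_("vers_zeiten", "vers", "zuzahlungsbefreit_kz", "flag"),
    t_("vers_zeiten", "vers", "mitgliedsart", "code"),
    o_("vers_zeiten", "vers", "beitragsgruppe", "code", "no added value for research"),
    o_("vers_zeiten", "vers", "meldegrund", "code", "no added value for research"),
    o_("vers_zeiten", "vers", "satzart", "code", "administrative record type"),
    o_("vers_zeiten", "vers", "pruefsumme", "code", "internal check sum"),
    k("vers_wohnort", "vers", c("psid", "vsid")),
    t_("vers_wohnort", "vers", "gkz", "code"),
    t_("vers_wohnort", "vers", "bundesland", "code"),
    t_("vers_wohnort", "vers", "kreis", "code"),
    t_("vers_wohnort", "vers", "plz", "code"),
    o_("vers_wohnort", "vers", "umzugsdatum", "date", "dropped in favour of the reported-year residence"),
    o_("vers_wohnort", "vers", "land", "code", "empty placeholder"),
    o_("vers_wohnort", "vers", "satzart", "code", "administrative record type"),
    k("vers_dmp", "vers", c("psid", "vsid")),
    t_("vers_dmp", "vers", "dmp_typ", "code"),
    t_("vers_dmp", "vers", "einschreibedatum", "date"),
    t_("vers_dmp", "vers", "austrittsdatum", "date"),
    t_("vers_dmp", "vers", "dmp_status", "code"),
    o_("vers_dmp", "vers", "austrittsgrund", "code", "dropped in favour of the enrollment interval"),
    o_("vers_dmp", "vers", "pruefsumme", "code", "internal check sum"),
    ## schema am: drugs ------------------------------------------------------
    k("am_rezepte", "am", c("psid", "vsid", "am_fallnr")),
    t_("am_rezepte", "am", "pzn", "code"),
    t_("am_rezepte", "am", "verordnungsdatum", "date"),
    t_("am_rezepte", "am", "menge", "int"),
    t_("am_rezepte", "am", "faktor", "int"),
    t_("am_rezepte", "am", "darreichungsform", "code"),
    t_("am_rezepte", "am", "packungsgroesse", "code"),
    t_("am_rezepte", "am", "autidem_kz", "flag"),
    t_("am_rezepte", "am", "verordnender_lanr", "id"),
    t_("am_rezepte", "am", "verordnender_fachgruppe", "code"),
    t_("am_rezepte", "am", "verordnender_bsnr", "id"),
    u_("am_rezepte", "am", "wirkstoffvo", "code", paste0("Active ingredient regulation: ", no_target)),
    o_("am_rezepte", "am", "abgabedatum", "date", "dropped in favour of the prescription date"),
    o_("am_rezepte", "am", "ddd", "int", "no added value for research"),
    o_("am_rezepte", "am", "normgroesse", "code", "no added value for research"),
    o_("am_rezepte", "am", "tid_kz", "flag", "empty placeholder"),
    o_("am_rezepte", "am", "sonderkennzeichen", "code", "no added value for research"),
    k("am_kosten", "am", c("psid", "vsid", "am_fallnr")),
    t_("am_kosten", "am", "zuzahlung", "amount"),
    t_("am_kosten", "am", "gesamtkosten", "amount"),
    t_("am_kosten", "am", "bruttobetrag", "amount"),
    t_("am_kosten", "am", "festbetrag", "amount"),
    t_("am_kosten", "am", "apothekenzuschlag", "amount"),
    o_("am_kosten", "am", "apotheke_ik", "id", "pharmacy details not kept"),
    o_("am_kosten", "am", "apotheke_plz", "code", "pharmacy details not kept"),
    o_("am_kosten", "am", "abrechnungsdatum", "date", "administrative accounting date"),
    ## schema amb: ambulatory incl. dental -----------------------------------
    k("amb_faelle", "amb", c("psid", "vsid", "amb_fallnr")),
    t_("amb_faelle", "amb", "behandlung_von", "date"),
    t_("amb_faelle", "amb", "behandlung_bis", "date"),
    t_("amb_faelle", "amb", "quartal", "quarter"),
    t_("amb_faelle", "amb", "unfall_kz", "flag"),
    t_("amb_faelle", "amb", "notfall_kz", "flag"),
    t_("amb_faelle", "amb", "lanr", "id"),
    t_("amb_faelle", "amb", "fachgruppe", "code"),
    t_("amb_faelle", "amb", "bsnr", "id"),
    t_("amb_faelle", "amb", "plz_praxis", "code"),
    t_("amb_faelle", "amb", "praxisart", "code"),
    t_("amb_faelle", "amb", "blutreinigung_kz", "flag"),
    t_("amb_faelle", "amb", "blutreinigung_datum", "date"),
    t_("amb_faelle", "amb", "blutreinigung_anzahl", "int"),
    u_("amb_faelle", "amb", "inansprartamb", "code", paste0("Type of claim: ", no_target)),
    u_("amb_faelle", "amb", "tsvgart", "code", paste0("TSVG: ", no_target)),
    u_("amb_faelle", "amb", "tsvgarzt", "code", paste0("TSVG: ", no_target)),
    u_("amb_faelle", "amb", "tsvgbsnrkv", "code", paste0("TSVG: ", no_target)),
    u_("amb_faelle", "amb", "tsvgbsnrpseudo", "code", paste0("TSVG: ", no_target)),
    u_("amb_faelle", "amb", "tsvgdat", "date", paste0("TSVG: ", no_target)),
    u_("amb_faelle", "amb", "zweitmein", "code", paste0("Second opinion identification: ", no_target)),
    u_("amb_faelle", "amb", "abrvondat", "date", paste0("Accounting date: ", no_target)),
    u_("amb_faelle", "amb", "abrbisdat", "date", paste0("Accounting date: ", no_target)),
    o_("amb_faelle", "amb", "ueberweiser_lanr", "id", "only treating instances kept"),
    o_("amb_faelle", "amb", "leistungszeit", "text", "dropped in favour of treatment dates"),
    o_("amb_faelle", "amb", "online_kz", "flag", "empty placeholder"),
    k("amb_diagnosen", "amb", c("psid", "vsid", "amb_fallnr")),
    t_("amb_diagnosen", "amb", "icd_code", "code"),
    t_("amb_diagnosen", "amb", "qualifizierung", "code"),
    t_("amb_diagnosen", "amb", "lokalisation", "code"),
    o_("amb_diagnosen", "amb", "abrechnungsquartal", "quarter", "dropped in favour of the treatment quarter"),
    o_("amb_diagnosen", "amb", "icd_version", "code", "administrative catalog version"),
    k("amb_ops", "amb", c("psid", "vsid", "amb_fallnr")),
    t_("amb_ops", "amb", "ops_code", "code"),
    t_("amb_ops", "amb", "ops_datum", "date"),
    t_("amb_ops", "amb", "lokalisation", "code"),
    t_("amb_ops", "amb", "anzahl", "int"),
    o_("amb_ops", "amb", "ops_version", "code", "administrative catalog version"),
    k("amb_leistungen", "amb", c("psid", "vsid", "amb_fallnr")),
    t_("amb_leistungen", "amb", "uas_ziffer", "code"),
    t_("amb_leistungen", "amb", "datum", "date"),
    t_("amb_leistungen", "amb", "anzahl", "int"),
    t_("amb_leistungen", "amb", "bruttobetrag", "amount"),
    t_("amb_leistungen", "amb", "punktzahl", "int"),
    t_("amb_leistungen", "amb", "eigenanteil", "amount"),
    o_("amb_leistungen", "amb", "abrechnungskz", "code", "administrative accounting flag"),
    o_("amb_leistungen", "amb", "uas_version", "code", "administrative catalog version"),
    k("zahn_faelle", "amb", c("psid", "vsid", "zahn_fallnr")),
    t_("zahn_faelle", "amb", "behandlungstag", "date"),
    t_("zahn_faelle", "amb", "behandlungsende", "date"),
    t_("zahn_faelle", "amb", "quartal", "quarter"),
    t_("zahn_faelle", "amb", "behandlungsart", "code"),
    t_("zahn_faelle", "amb", "zahnarzt_lanr", "id"),
    t_("zahn_faelle", "amb", "fallkosten", "amount"),
    t_("zahn_faelle", "amb", "laborkosten", "amount"),
    t_("zahn_faelle", "amb", "fremdlaborkosten", "amount"),
    t_("zahn_faelle", "amb", "versichertenanteil", "amount"),
    o_("zahn_faelle", "amb", "abrechnungsdatum", "date", "administrative accounting date"),
    o_("zahn_faelle", "amb", "kzv_nr", "id", "only treating instances kept"),
    k("zahn_befunde", "amb", c("psid", "vsid", "zahn_fallnr")),
    t_("zahn_befunde", "amb", "befund", "code"),
    t_("zahn_befunde", "amb", "befundart", "code"),
    t_("zahn_befunde", "amb", "befunddatum", "date"),
    u_("zahn_befunde", "amb", "zahn", "code", paste0("Coded teeth position: ", no_target)),
    u_("zahn_befunde", "amb", "refart", "code", paste0("Subsequent findings: ", no_target)),
    o_("zahn_befunde", "amb", "pruefsumme", "code", "internal check sum"),
    k("zahn_leistungen", "amb", c("psid", "vsid", "zahn_fallnr")),
    t_("zahn_leistungen", "amb", "leistungsgruppe", "code"),
    t_("zahn_leistungen", "amb", "gebnr", "code"),
    t_("zahn_leistungen", "amb", "datum", "date"),
    t_("zahn_leistungen", "amb", "anzahl", "int"),
    u_("zahn_leistungen", "amb", "zahn", "code", paste0("Coded teeth position: ", no_target)),
    o_("zahn_leistungen", "amb", "pruefsumme", "code", "internal check sum"),
    ## schema kh: inpatient and partially inpatient cases --------------------
    k("kh_faelle", "kh", c("psid", "vsid", "kh_fallnr")),
    t_("kh_faelle", "kh", "aufnahmedatum", "date"),
    t_("kh_faelle", "kh", "entlassungsdatum", "date"),
    t_("kh_faelle", "kh", "aufnahmegrund", "code"),
    t_("kh_faelle", "kh", "aufnahmeanlass", "code"),
    t_("kh_faelle", "kh", "entlassungsgrund", "code"),
    t_("kh_faelle", "kh", "behandlungsart", "code"),
    t_("kh_faelle", "kh", "ik", "id"),
    t_("kh_faelle", "kh", "ik_plz", "code"),
    t_("kh_faelle", "kh", "traegerart", "code"),
    t_("kh_faelle", "kh", "aufnahmegewicht", "int"),
    t_("kh_faelle", "kh", "beatmungsstunden", "int"),
    t_("kh_faelle", "kh", "intensiv_tage", "int"),
    u_("kh_faelle", "kh", "fa", "code", paste0("Admitted department: ", no_target)),
    u_("kh_faelle", "kh", "aufnfa", "code", paste0("Admitting specialist department: ", no_target)),
    o_("kh_faelle", "kh", "verweildauer", "int", "dropped in favour of admission/discharge dates"),
    o_("kh_faelle", "kh", "aufnahmeuhrzeit", "text", "dropped in favour of day precision"),
    o_("kh_faelle", "kh", "entlassungsuhrzeit", "text", "dropped in favour of day precision"),
    o_("kh_faelle", "kh", "ik_abrechnung", "id", "administrative billing institution"),
    k("kh_khdiag", "kh", c("psid", "vsid", "kh_fallnr")),
    t_("kh_khdiag", "kh", "icd_code", "code"),
    t_("kh_khdiag", "kh", "diagnoseart", "code"),
    t_("kh_khdiag", "kh", "lokalisation", "code"),
    o_("kh_khdiag", "kh", "icd_version", "code", "administrative catalog version"),
    k("kh_ops", "kh", c("psid", "vsid", "kh_fallnr")),
    t_("kh_ops", "kh", "ops_code", "code"),
    t_("kh_ops", "kh", "ops_datum", "date"),
    t_("kh_ops", "kh", "lokalisation", "code"),
    t_("kh_ops", "kh", "anzahl", "int"),
    o_("kh_ops", "kh", "ops_version", "code", "administrative catalog version"),
    k("kh_entgelte", "kh", c("psid", "vsid", "kh_fallnr")),
    t_("kh_entgelte", "kh", "entgeltart", "code"),
    t_("kh_entgelte", "kh", "betrag", "amount"),
    t_("kh_entgelte", "kh", "entgeltanzahl", "int"),
    o_("kh_entgelte", "kh", "abrechnungskz", "code", "administrative accounting flag")
  )
}

#' Tables of a source format
#' @param format_id 1 or 3.
#' @return character vector of table names (Format 1: the 9 tables).
#' @export
source_tables <- function(format_id) unique(source_schema(format_id)$table)

schema_of_table <- function(format_id, table) {
  sc <- source_schema(format_id)
  unique(sc$schema[sc$table == table])
}

#' The field ledger: classification of every source field
#'
#' Classifies each non-key source field of a format as transformed,
#' intentionally omitted, or untransformable, with a reason. Mirrors the
#' dictionary the ETL itself consumes, so ledger and implementation cannot
#' drift apart. Format 1 carries 38 transformed, 4 omitted and 3
#' untransformable fields; Format 3 carries 100, 40 and 16.
#'
#' @param format_id 1 or 3.
#' @return A data.frame of class `field_ledger` with columns `format_id`,
#'   `table`, `field`, `status` (`transformed`, `omitted_intentional`,
#'   `untransformable`) and `reason`.
#' @seealso [field_coverage()]
#' @export
make_ledger_fixture <- function(format_id) {
  sc <- source_schema(format_id)
  sc <- sc[sc$status != "key", , drop = FALSE]
  status <- c(transformed = "transformed", omitted = "omitted_intentional",
              untransformable = "untransformable")[sc$status]
  reason <- ifelse(sc$status == "transformed", "transformed into the CDM", sc$reason)
  out <- data.frame(format_id = as.integer(format_id), table = sc$table,
                    field = sc$field, status = unname(status),
                    reason = reason, stringsAsFactors = FALSE)
  class(out) <- c("field_ledger", "data.frame")
  out
}

#' @export
print.field_ledger <- function(x, ...) {
  cat(sprintf("<field_ledger format %d: %d transformed, %d omitted, %d untransformable>\n",
              x$format_id[1], sum(x$status == "transformed"),
              sum(x$status == "omitted_intentional"),
              sum(x$status == "untransformable")))
  invisible(x)
}
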