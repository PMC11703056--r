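# OMOP CDM v5.4 subset: table definitions, surrogate-key allocation,
# upsert/extend semantics, CSV persistence.

.cdm_columns <- list(
  person = c("person_id", "gender_concept_id", "year_of_birth", "month_of_birth",
             "day_of_birth", "birth_datetime", "race_concept_id", "ethnicity_concept_id",
             "location_id", "provider_id", "care_site_id", "person_source_value",
             "gender_source_value", "gender_source_concept_id", "race_source_value",
             "race_source_concept_id", "ethnicity_source_value", "ethnicity_source_concept_id"),
  observation_period = c("observation_period_id", "person_id", "observation_period_start_date",
                         "observation_period_end_date", "period_type_concept_id"),
  visit_occurrence = c("visit_occurrence_id", "person_id", "visit_concept_id",
                       "visit_start_date", "visit_start_datetime", "visit_end_date",
                       "visit_end_datetime", "visit_type_concept_id", "provider_id",
                       "care_site_id", "visit_source_value", "visit_source_concept_id",
                       "admitted_from_concept_id", "admitted_from_source_value",
                       "discharged_to_concept_id", "discharged_to_source_value",
                       "preceding_visit_occurrence_id"),
  condition_occurrence = c("condition_occurrence_id", "person_id", "condition_concept_id",
                           "condition_start_date", "condition_start_datetime",
                           "condition_end_date", "condition_end_datetime",
                           "condition_type_concept_id", "condition_status_concept_id",
                           "stop_reason", "provider_id", "visit_occurrence_id",
                           "visit_detail_id", "condition_source_value",
                           "condition_source_concept_id", "condition_status_source_value"),
  procedure_occurrence = c("procedure_occurrence_id", "person_id", "procedure_concept_id",
                           "procedure_date", "procedure_datetime", "procedure_end_date",
                           "procedure_end_datetime", "procedure_type_concept_id",
                           "modifier_concept_id", "quantity", "provider_id",
                           "visit_occurrence_id", "visit_detail_id", "procedure_source_value",
                           "procedure_source_concept_id", "modifier_source_value"),
  drug_exposure = c("drug_exposure_id", "person_id", "drug_concept_id",
                    "drug_exposure_start_date", "drug_exposure_start_datetime",
                    "drug_exposure_end_date", "drug_exposure_end_datetime",
                    "verbatim_end_date", "drug_type_concept_id", "stop_reason", "refills",
                    "quantity", "days_supply", "sig", "route_concept_id", "lot_number",
                    "provider_id", "visit_occurrence_id", "visit_detail_id",
                    "drug_source_value", "drug_source_concept_id", "route_source_value",
                    "dose_unit_source_value"),
  observation = c("observation_id", "person_id", "observation_concept_id", "observation_date",
                  "observation_datetime", "observation_type_concept_id", "value_as_number",
                  "value_as_string", "value_as_concept_id", "qualifier_concept_id",
                  "unit_concept_id", "provider_id", "visit_occurrence_id", "visit_detail_id",
                  "observation_source_value", "observation_source_concept_id",
                  "unit_source_value", "qualifier_source_value", "value_source_value",
                  "observation_event_id", "obs_event_field_concept_id"),
  measurement = c("measurement_id", "person_id", "measurement_concept_id", "measurement_date",
                  "measurement_datetime", "measurement_time", "measurement_type_concept_id",
                  "operator_concept_id", "value_as_number", "value_as_concept_id",
                  "unit_concept_id", "range_low", "range_high", "provider_id",
                  "visit_occurrence_id", "visit_detail_id", "measurement_source_value",
                  "measurement_source_concept_id", "unit_source_value", "value_source_value",
                  "measurement_event_id", "meas_event_field_concept_id"),
  death = c("person_id", "death_date", "death_datetime", "death_type_concept_id",
            "cause_concept_id", "cause_source_value", "cause_source_concept_id"),
  cost = c("cost_id", "cost_event_id", "cost_domain_id", "cost_type_concept_id",
           "currency_concept_id", "total_charge", "total_cost", "total_paid",
           "paid_by_payer", "paid_by_patient", "paid_patient_copay",
           "paid_patient_coinsurance", "paid_patient_deductible", "paid_by_primary",
           "paid_ingredient_cost", "paid_dispensing_fee", "payer_plan_period_id",
           "amount_allowed", "revenue_code_concept_id", "revenue_code_source_value",
           "drug_source_value"),
  payer_plan_period = c("payer_plan_period_id", "person_id", "payer_plan_period_start_date",
                        "payer_plan_period_end_date", "payer_concept_id", "payer_source_value",
                        "payer_source_concept_id", "plan_concept_id", "plan_source_value",
                        "plan_source_concept_id", "sponsor_concept_id", "sponsor_source_value",
                        "sponsor_source_concept_id", "family_source_value",
                        "stop_reason_concept_id", "stop_reason_source_value"),
  provider = c("provider_id", "provider_name", "npi", "dea", "specialty_concept_id",
               "care_site_id", "year_of_birth", "gender_concept_id", "provider_source_value",
               "specialty_source_value", "specialty_source_concept_id", "gender_source_value",
               "gender_source_concept_id"),
  care_site = c("care_site_id", "care_site_name", "place_of_service_concept_id", "location_id",
                "care_site_source_value", "place_of_service_source_value"),
  location = c("location_id", "address_1", "address_2", "city", "state", "zip", "county",
               "location_source_value", "country_concept_id", "country_source_value",
               "latitude", "longitude")
)

.cdm_pk <- c(person = "person_id", observation_period = "observation_period_id",
             visit_occurrence = "visit_occurrence_id",
             condition_occurrence = "condition_occurrence_id",
             procedure_occurrence = "procedure_occurrence_id",
             drug_exposure = "drug_exposure_id", observation = "observation_id",
             measurement = "measurement_id", death = "person_id", cost = "cost_id",
             payer_plan_period = "payer_plan_period_id", provider = "provider_id",
             care_site = "care_site_id", location = "location_id")

# foreign keys checked by the quality layer: child.col -> parent.pk
.cdm_fks <- list(
  list("observation_period", "person_id", "person"),
  list("visit_occurrence", "person_id", "person"),
  list("visit_occurrence", "provider_id", "provider"),
  list("visit_occurrence", "care_site_id", "care_site"),
  list("condition_occurrence", "person_id", "person"),
  list("condition_occurrence", "visit_occurrence_id", "visit_occurrence"),
  list("procedure_occurrence", "person_id", "person"),
  list("procedure_occurrence", "visit_occurrence_id", "visit_occurrence"),
  list("drug_exposure", "person_id", "person"),
  list("drug_exposure", "visit_occurrence_id", "visit_occurrence"),
  list("drug_exposure", "provider_id", "provider"),
  list("observation", "person_id", "person"),
  list("observation", "visit_occurrence_id", "visit_occurrence"),
  list("measurement", "person_id", "person"),
  list("measurement", "visit_occurrence_id", "visit_occurrence"),
  list("death", "person_id", "person"),
  list("cost", "payer_plan_period_id", "payer_plan_period"),
  list("payer_plan_period", "person_id", "person"),
  list("provider", "care_site_id", "care_site"),
  list("care_site", "location_id", "location"),
  list("person", "location_id", "location")
)

cdm_col_class <- function(col) {
  if (col == "cost_domain_id") return("character")
  if (grepl("_datetime$", col) || col == "measurement_time") return("character")
  if (grepl("_date$", col)) return("Date")
  if (grepl("_id$", col)) return("numeric")
  if (col %in% c("year_of_birth", "month_of_birth", "day_of_birth", "quantity",
                 "days_supply", "refills", "value_as_number", "range_low", "range_high",
                 "total_charge", "total_cost", "total_paid", "paid_by_payer",
                 "paid_by_patient", "paid_patient_copay", "paid_patient_coinsurance",
                 "paid_patient_deductible", "paid_by_primary", "paid_ingredient_cost",
                 "paid_dispensing_fee", "amount_allowed", "latitude", "longitude"))
    return("numeric")
  "character"
}

empty_cdm_table <- function(table) {
  cols <- .cdm_columns[[table]]
  out <- lapply(cols, function(cl) {
    switch(cdm_col_class(cl), Date = as.Date(character(0)),
           numeric = numeric(0), character = character(0))
  })
  names(out) <- cols
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Create an empty OMOP CDM database
#'
#' Holds the populated subset of the CDM v5.4 tables as in-memory data frames
#' together with the lookup registries the ETL needs: `psid` to `person_id`,
#' `vsid` to `payer_plan_period_id`, provider and care-site natural keys, and
#' the per-run temporary visit keys (dropped before writing). Primary keys
#' are monotone integer counters, never reused within a run.
#'
#' @return An environment of class `cdm_database`.
#' @export
cdm_new <- function() {
  db <- new.env(parent = emptyenv())
  db$tables <- lapply(stats::setNames(names(.cdm_columns), names(.cdm_columns)), empty_cdm_table)
  db$counters <- stats::setNames(rep(0, length(.cdm_columns)), names(.cdm_columns))
  db$person_ids <- numeric(0)      # named by psid
  db$payer_ids <- numeric(0)       # named by vsid
  db$provider_ids <- numeric(0)    # named by natural key
  db$care_site_ids <- numeric(0)   # named by natural key
  db$location_ids <- numeric(0)    # named by natural key
  db$tmp_visit_keys <- numeric(0)  # named by temp key (psid|year|case or case id)
  db$manifest <- list()
  class(db) <- "cdm_database"
  db
}

#' @export
print.cdm_database <- function(x, ...) {
  cat("<cdm_database>\n")
  for (nm in names(x$tables)) {
    n <- nrow(x$tables[[nm]])
    if (n > 0) cat(sprintf("  %-22s %8d rows\n", nm, n))
  }
  invisible(x)
}

#' @export
summary.cdm_database <- function(object, ...) {
  data.frame(table = names(object$tables),
             rows = vapply(object$tables, nrow, 0L), row.names = NULL)
}

next_ids <- function(db, table, n) {
  if (n == 0L) return(numeric(0))
  ids <- db$counters[[table]] + seq_len(n)
  db$counters[[table]] <- db$counters[[table]] + n
  ids
}

# Append a block of rows; missing columns are filled with NA of the right class.
cdm_append <- function(db, table, ...) {
  cols <- list(...)
  if (length(cols) == 1L && is.data.frame(cols[[1]])) cols <- as.list(cols[[1]])
  n <- max(vapply(cols, length, 0L))
  if (n == 0L) return(invisible(db))
  all_cols <- .cdm_columns[[table]]
  block <- lapply(all_cols, function(cl) {
    if (!is.null(cols[[cl]])) rep_len(cols[[cl]], n)
    else switch(cdm_col_class(cl), Date = as.Date(rep(NA, n)),
                numeric = rep(NA_real_, n), character = rep(NA_character_, n))
  })
  names(block) <- all_cols
  db$tables[[table]] <- rbind(db$tables[[table]],
                              as.data.frame(block, stringsAsFactors = FALSE))
  invisible(db)
}

#' Insert or update a person by source pseudonym
#'
#' The long-term pseudonym `psid` is kept as `person_source_value` and used
#' as the lookup key: the first occurrence allocates a fresh `person_id`,
#' later years update the existing row in place (most insured persons
#' reappear annually). The CDM person table only supports binary genders;
#' anything other than female/male maps to gender concept 0.
#'
#' @param psid non-empty source pseudonym.
#' @param demographics list with any of `gender` (`"w"`/`"f"` female,
#'   `"m"` male, other 0), `year_of_birth`, `month_of_birth`, `location_id`.
#' @param year reported year the demographics come from.
#' @param db a [cdm_new()] database.
#' @return the `person_id` (invisible updates to `db`).
#' @export
upsert_person <- function(psid, demographics, year, db) {
  if (is_blank(psid)) abort("psid must be non-empty")
  upsert_persons(data.frame(psid = psid,
                            gender = demographics$gender %||% NA_character_,
                            year_of_birth = demographics$year_of_birth %||% NA_real_,
                            month_of_birth = demographics$month_of_birth %||% NA_real_,
                            location_id = demographics$location_id %||% NA_real_,
                            stringsAsFactors = FALSE), year, db)
}

gender_concept <- function(g) {
  g <- tolower(as.character(g))
  ifelse(g %in% c("w", "f", "2"), 8532, ifelse(g %in% c("m", "1"), 8507, 0))
}

# vectorised person upsert; one row per distinct psid expected
upsert_persons <- function(demo, year, db) {
  idx <- match(demo$psid, names(db$person_ids))
  new <- is.na(idx)
  if (any(new)) {
    ids <- next_ids(db, "person", sum(new))
    db$person_ids <- c(db$person_ids, stats::setNames(ids, demo$psid[new]))
    cdm_append(db, "person",
               person_id = ids,
               gender_concept_id = gender_concept(demo$gender[new]),
               year_of_birth = as_num(demo$year_of_birth[new]),
               month_of_birth = as_num(demo$month_of_birth[new]),
               race_concept_id = 0, ethnicity_concept_id = 0,
               location_id = as_num(demo$location_id[new]),
               person_source_value = demo$psid[new],
               gender_source_value = as.character(demo$gender[new]))
  }
  if (any(!new)) {
    # update existing rows with the newer year's demographics
    tab <- db$tables$person
    rows <- match(db$person_ids[demo$psid[!new]], tab$person_id)
    tab$gender_concept_id[rows] <- gender_concept(demo$gender[!new])
    tab$year_of_birth[rows] <- as_num(demo$year_of_birth[!new])
    tab$gender_source_value[rows] <- as.character(demo$gender[!new])
    loc <- as_num(demo$location_id[!new])
    tab$location_id[rows] <- ifelse(is.na(loc), tab$location_id[rows], loc)
    db$tables$person <- tab
  }
  unname(db$person_ids[demo$psid])
}

#' Extend or create an observation period
#'
#' One-year observation periods are assumed per reported year; when a person
#' already has a period overlapping or adjacent (gap of at most one day) to
#' the new interval, the existing period is simply extended to the union.
#' Periods of one person therefore never overlap.
#'
#' @param person_id CDM person id.
#' @param start,end `Date` bounds, `start <= end`.
#' @param db the database.
#' @return the `observation_period_id` of the resulting row.
#' @export
extend_observation_period <- function(person_id, start, end, db) {
  start <- as.Date(start); end <- as.Date(end)
  if (start > end) abort("observation period start after end")
  tab <- db$tables$observation_period
  mine <- which(tab$person_id == person_id)
  touch <- mine[tab$observation_period_start_date[mine] <= end + 1L &
                tab$observation_period_end_date[mine] >= start - 1L]
  if (length(touch) == 0L) {
    id <- next_ids(db, "observation_period", 1L)
    cdm_append(db, "observation_period", observation_period_id = id,
               person_id = person_id, observation_period_start_date = start,
               observation_period_end_date = end, period_type_concept_id = 32810)
    return(id)
  }
  # merge all touched periods plus the new interval into one
  new_start <- min(c(tab$observation_period_start_date[touch], start))
  new_end <- max(c(tab$observation_period_end_date[touch], end))
  keep <- touch[1]
  tab$observation_period_start_date[keep] <- new_start
  tab$observation_period_end_date[keep] <- new_end
  id <- tab$observation_period_id[keep]
  if (length(touch) > 1L) tab <- tab[-touch[-1], , drop = FALSE]
  db$tables$observation_period <- tab
  id
}

#' Insurance relationship as payer plan period
#'
#' The year/insurer-dependent pseudonym `vsid` is the natural key of the
#' payer plan period (the only CDM table that keeps a source primary key).
#' Coverage start/end dates are not delivered, so each insurance relationship
#' is assigned a one-year period spanning the reported year.
#'
#' @param vsid non-empty insurance pseudonym.
#' @param person_id owning person.
#' @param year reported year.
#' @param payer list with optional `payer_source_value`, `plan_source_value`,
#'   `sponsor_source_value`.
#' @param db the database.
#' @return the `payer_plan_period_id`.
#' @export
get_or_create_payer_plan_period <- function(vsid, person_id, year, payer = list(), db) {
  if (is_blank(vsid)) abort("vsid must be non-empty")
  existing <- db$payer_ids[vsid]
  if (!is.na(existing)) {
    owner <- db$tables$payer_plan_period$person_id[
      match(existing, db$tables$payer_plan_period$payer_plan_period_id)]
    if (owner != person_id)
      abort("vsid '", vsid, "' reused with a different person")
    return(unname(existing))
  }
  id <- next_ids(db, "payer_plan_period", 1L)
  db$payer_ids[vsid] <- id
  cdm_append(db, "payer_plan_period", payer_plan_period_id = id, person_id = person_id,
             payer_plan_period_start_date = as.Date(sprintf("%04d-01-01", year)),
             payer_plan_period_end_date = as.Date(sprintf("%04d-12-31", year)),
             payer_concept_id = 0, plan_concept_id = 0, sponsor_concept_id = 0,
             payer_source_value = payer$payer_source_value %||% vsid,
             plan_source_value = payer$plan_source_value %||% NA_character_,
             sponsor_source_value = payer$sponsor_source_value %||% NA_character_)
  id
}

#' Get-or-create a provider / care site by natural key
#'
#' The source formats have no summarised provider or care-site tables; each
#' new physician pseudonym or facility id creates one entry, deduplicated on
#' the natural key.
#'
#' @param natural_key physician id (LANR pseudonym) or facility id (IK/BSNR).
#' @param attrs provider: `specialty_concept_id`, `specialty_source_value`,
#'   `care_site_id`; care site: `place_of_service_source_value`, `location_id`.
#' @param db the database.
#' @return the allocated or existing id.
#' @export
upsert_provider <- function(natural_key, attrs = list(), db) {
  if (is_blank(natural_key)) abort("provider natural key must be non-empty")
  existing <- db$provider_ids[natural_key]
  if (!is.na(existing)) return(unname(existing))
  id <- next_ids(db, "provider", 1L)
  db$provider_ids[natural_key] <- id
  cdm_append(db, "provider", provider_id = id,
             specialty_concept_id = attrs$specialty_concept_id %||% 0,
             care_site_id = attrs$care_site_id %||% NA_real_,
             provider_source_value = natural_key,
             specialty_source_value = attrs$specialty_source_value %||% NA_character_)
  id
}

#' @rdname upsert_provider
#' @export
upsert_care_site <- function(natural_key, attrs = list(), db) {
  if (is_blank(natural_key)) abort("care site natural key must be non-empty")
  existing <- db$care_site_ids[natural_key]
  if (!is.na(existing)) return(unname(existing))
  id <- next_ids(db, "care_site", 1L)
  db$care_site_ids[natural_key] <- id
  cdm_append(db, "care_site", care_site_id = id,
             place_of_service_concept_id = 0,
             location_id = attrs$location_id %||% NA_real_,
             care_site_source_value = natural_key,
             place_of_service_source_value = attrs$place_of_service_source_value %||% NA_character_)
  id
}

upsert_location <- function(natural_key, attrs = list(), db) {
  existing <- db$location_ids[natural_key]
  if (!is.na(existing)) return(unname(existing))
  id <- next_ids(db, "location", 1L)
  db$location_ids[natural_key] <- id
  cdm_append(db, "location", location_id = id,
             state = attrs$state %||% NA_character_,
             county = attrs$county %||% NA_character_,
             zip = attrs$zip %||% NA_character_,
             city = attrs$city %||% NA_character_,
             location_source_value = natural_key,
             country_concept_id = 0)
  id
}

# death keeps one row per person (primary key person_id); newer info replaces
add_death <- function(db, person_id, date, db_source = NA_character_) {
  tab <- db$tables$death
  tab <- tab[!(tab$person_id %in% person_id), , drop = FALSE]
  db$tables$death <- tab
  cdm_append(db, "death", person_id = person_id, death_date = as.Date(date),
             death_type_concept_id = 32810, cause_concept_id = 0,
             cause_source_value = db_source)
  invisible(db)
}

fmt_cdm_cell <- function(x) {
  if (inherits(x, "Date")) return(ifelse(is.na(x), NA_character_, format(x, "%Y-%m-%d")))
  if (is.numeric(x)) {
    s <- vapply(x, function(v) {
      if (is.na(v)) return(NA_character_)
      if (v == round(v) && abs(v) < 1e15) sprintf("%.0f", v)
      else format(v, scientific = FALSE, trim = TRUE)
    }, "")
    return(s)
  }
  as.character(x)
}

#' Write the CDM tables as CSV files
#'
#' One CSV per populated table (plus empty files with headers for the rest),
#' OMOP v5.4 column names, rows ordered by primary key ascending so that two
#' runs over the same inputs produce byte-identical outputs. Temporary visit
#' keys and lookup registries are not persisted.
#'
#' @param db the database.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_cdm <- function(db, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort("cannot create output directory ", out_dir)
  for (nm in names(db$tables)) {
    tab <- db$tables[[nm]]
    if (nrow(tab)) tab <- tab[order(tab[[.cdm_pk[[nm]]]]), , drop = FALSE]
    out <- as.data.frame(lapply(tab, fmt_cdm_cell), stringsAsFactors = FALSE,
                         check.names = FALSE)
    names(out) <- names(tab)
    write_table_csv(out, file.path(out_dir, paste0(nm, ".csv")))
  }
  invisible(out_dir)
}

#' Read CDM tables back from CSV files
#'
#' Inverse of [write_cdm()] (registries and counters are rebuilt so far as
#' the quality layer needs them: psid and vsid lookups from source values).
#' @param dir directory written by [write_cdm()].
#' @return a `cdm_database`.
#' @export
read_cdm <- function(dir) {
  db <- cdm_new()
  for (nm in names(db$tables)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(p)) next
    raw <- read_table_csv(p)
    proto <- empty_cdm_table(nm)
    cols <- lapply(names(proto), function(cl) {
      v <- raw[[cl]]
      v[is_blank(v)] <- NA
      switch(cdm_col_class(cl), Date = as.Date(v), numeric = as.numeric(v),
             as.character(v))
    })
    names(cols) <- names(proto)
    db$tables[[nm]] <- as.data.frame(cols, stringsAsFactors = FALSE)
    if (nrow(db$tables[[nm]]))
      db$counters[[nm]] <- max(db$tables[[nm]][[.cdm_pk[[nm]]]], 0)
  }
  p <- db$tables$person
  db$person_ids <- stats::setNames(p$person_id, p$person_source_value)
  ppp <- db$tables$payer_plan_period
  db$payer_ids <- stats::setNames(ppp$payer_plan_period_id, ppp$payer_source_value)
  db
}

#' Dangling foreign keys, as data
#'
#' Constraint checking is deferred to the end of a run; this audits every
#' declared foreign key and reports the dangling-reference counts.
#' @param db a `cdm_database`.
#' @return data.frame with one row per (child table, column): `n_dangling`
#'   out of `n` non-missing references.
#' @export
cdm_fk_violations <- function(db) {
  out <- lapply(.cdm_fks, function(fk) {
    child <- db$tables[[fk[[1]]]]
    v <- child[[fk[[2]]]]
    v <- v[!is.na(v)]
    parents <- db$tables[[fk[[3]]]][[.cdm_pk[[fk[[3]]]]]]
    data.frame(child = fk[[1]], column = fk[[2]], parent = fk[[3]],
               n_dangling = sum(!(v %in% parents)), n = length(v),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
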