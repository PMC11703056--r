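#' Impute a day-precise date from a vague date
#'
#' The first day of the most precise period given is used as the event date:
#' the exact day if known, else the first of the month, else the first of the
#' quarter, else January 1st. (A discharge reported only as "second quarter"
#' is therefore assumed to have occurred on April 1st.)
#'
#' @param v a [vague_date()].
#' @return a `Date`.
#' @examples
#' impute_date(vague_date(2010, quarter = 2))  # 2010-04-01
#' @export
impute_date <- function(v) {
  stopifnot(inherits(v, "vague_date"))
  if (!is.na(v$day))   return(as.Date(sprintf("%04d-%02d-%02d", v$year, v$month, v$day)))
  if (!is.na(v$month)) return(as.Date(sprintf("%04d-%02d-01", v$year, v$month)))
  if (!is.na(v$quarter)) return(quarter_start(v$year, v$quarter))
  as.Date(sprintf("%04d-01-01", v$year))
}

#' Impute a date for an enumerated case
#'
#' Inpatient and partially inpatient diagnoses carry a case enumerator but no
#' exact date. To preserve the order of the cases, one day is added to the
#' imputed period start for each following case: case 1 gets the un-offset
#' date, case k gets `impute_date(v) + (k - 1)` days. The offset is
#' unbounded by the period (the quality layer flags dates that spill past the
#' reported year).
#'
#' @inheritParams impute_date
#' @param case_index 1-based case enumerator.
#' @return a `Date`.
#' @examples
#' impute_case_date(vague_date(2009, quarter = 2), 3)  # 2009-04-03
#' @export
impute_case_date <- function(v, case_index) {
  case_index <- as.integer(case_index)
  if (is.na(case_index) || case_index < 1L)
    abort("case_index must be an integer >= 1, got ", case_index)
  impute_date(v) + (case_index - 1L)
}

#' Death date under the year-only rule
#'
#' Format 1 reports only the year of death; following OHDSI guidance the day
#' of death is set to December 31st of that year.
#'
#' @param year calendar year.
#' @return a `Date`.
#' @export
death_date <- function(year) {
  as.Date(sprintf("%04d-12-31", as.integer(year)))
}

#' Drug exposure interval from a prescription date
#'
#' Prescriptions carry no duration; by OHDSI convention 29 days are added to
#' the start date.
#'
#' @param start prescription `Date` (or ISO string).
#' @return list with elements `start` and `end` (`Date`s, end = start + 29).
#' @examples
#' drug_interval(as.Date("2010-05-03"))  # ends 2010-06-01
#' @export
drug_interval <- function(start) {
  start <- as.Date(start)
  list(start = start, end = start + 29L)
}

# target table by concept domain; anything un-routable falls back to default
domain_table <- c(Condition = "condition_occurrence",
                  Procedure = "procedure_occurrence",
                  Drug = "drug_exposure",
                  Measurement = "measurement",
                  Observation = "observation")

#' Route a coded event to its CDM table(s)
#'
#' In the OMOP CDM the domain of the standard concept decides the table an
#' event lands in: an ICD-10-GM code can belong to a condition, procedure,
#' observation or measurement, and an OPS code additionally to a drug. One
#' event is emitted per "Maps to" target; a code without any mapping yields
#' exactly one event in the context's default table with concept 0 and the
#' source code retained, so that no events are excluded.
#'
#' @param code source code (normalised for ICD-10-GM).
#' @param vocabulary_id source vocabulary (`"ICD10GM"`, `"OPS"`, `"PZN"`, ...).
#' @param default_table table used when the code is unmapped.
#' @param store a `vocabulary_store`.
#' @return data.frame with columns `target_table`, `concept_id`, `domain_id`,
#'   `source_code`, `source_vocabulary`; at least one row.
#' @export
route_event <- function(code, vocabulary_id, default_table, store) {
  r <- route_codes(code, vocabulary_id, default_table, store)
  r[, c("target_table", "concept_id", "domain_id", "source_code", "source_vocabulary")]
}

# Vectorised routing; returns idx (input position) plus routing columns.
route_codes <- function(codes, vocabulary_id, default_table, store) {
  n <- length(codes)
  mapped <- map_codes(codes, vocabulary_id, store)
  mapped$target_table <- domain_table[mapped$domain_id]
  mapped$target_table[is.na(mapped$target_table)] <- default_table
  unmapped_idx <- setdiff(seq_len(n), mapped$idx)
  out <- rbind(
    data.frame(idx = mapped$idx, target_table = mapped$target_table,
               concept_id = mapped$concept_id, domain_id = mapped$domain_id,
               stringsAsFactors = FALSE),
    data.frame(idx = unmapped_idx,
               target_table = rep(default_table, length(unmapped_idx)),
               concept_id = rep(0, length(unmapped_idx)),
               domain_id = rep(NA_character_, length(unmapped_idx)),
               stringsAsFactors = FALSE)
  )
  out <- out[order(out$idx, out$concept_id), , drop = FALSE]
  out$source_code <- codes[out$idx]
  out$source_vocabulary <- vocabulary_id
  rownames(out) <- NULL
  out
}
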