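# Append routed events (output of route_codes) to their target CDM tables.
# `at` holds per-source-row vectors, indexed by r$idx; every routed row keeps
# the source code in the table's *_source_value field, so unmapped codes
# (concept 0) remain searchable by their original code.
append_routed <- function(db, r, at) {
  if (nrow(r) == 0L) return(invisible(db))
  pick <- function(v, idx) if (is.null(v)) NULL else v[idx]
  for (tt in unique(r$target_table)) {
    s <- r[r$target_table == tt, , drop = FALSE]
    idx <- s$idx
    n <- nrow(s)
    ids <- next_ids(db, tt, n)
    src_val <- pick(at$source_value, idx) %||% s$source_code
    src_cid <- pick(at$source_concept_id, idx) %||% rep(0, n)
    start <- at$start[idx]
    end <- pick(at$end, idx)
    common <- list(person_id = at$person_id[idx],
                   visit_occurrence_id = pick(at$visit_id, idx),
                   provider_id = pick(at$provider_id, idx))
    args <- switch(tt,
      condition_occurrence = c(common, list(
        condition_occurrence_id = ids, condition_concept_id = s$concept_id,
        condition_start_date = start, condition_end_date = end,
        condition_type_concept_id = 32810,
        condition_status_concept_id = pick(at$status_concept_id, idx),
        condition_status_source_value = pick(at$status_source_value, idx),
        condition_source_value = src_val, condition_source_concept_id = src_cid)),
      procedure_occurrence = c(common, list(
        procedure_occurrence_id = ids, procedure_concept_id = s$concept_id,
        procedure_date = start, procedure_end_date = end,
        procedure_type_concept_id = 32810,
        quantity = pick(at$quantity, idx), modifier_concept_id = 0,
        modifier_source_value = pick(at$modifier, idx),
        procedure_source_value = src_val, procedure_source_concept_id = src_cid)),
      drug_exposure = c(common, list(
        drug_exposure_id = ids, drug_concept_id = s$concept_id,
        drug_exposure_start_date = start,
        drug_exposure_end_date = end %||% start,
        drug_type_concept_id = 32810, quantity = pick(at$quantity, idx),
        drug_source_value = src_val, drug_source_concept_id = src_cid,
        route_concept_id = 0)),
      observation = c(common, list(
        observation_id = ids, observation_concept_id = s$concept_id,
        observation_date = start, observation_type_concept_id = 32810,
        value_as_concept_id = 0, qualifier_concept_id = 0, unit_concept_id = 0,
        observation_source_value = src_val, observation_source_concept_id = src_cid)),
      measurement = c(common, list(
        measurement_id = ids, measurement_concept_id = s$concept_id,
        measurement_date = start, measurement_type_concept_id = 32810,
        operator_concept_id = 0, value_as_concept_id = 0, unit_concept_id = 0,
        measurement_source_value = src_val, measurement_source_concept_id = src_cid)),
      abort("unroutable target table: ", tt))
    do.call(cdm_append, c(list(db, tt), args))
  }
  invisible(db)
}

# source concept id of a code (0 when the vocabulary does not carry it)
source_concept_ids <- function(codes, vocabulary_id, store) {
  id <- unname(store$code_index[paste(vocabulary_id, codes, sep = "|")])
  ifelse(is.na(id), 0, id)
}

# simple vectorised observation append with a fixed local concept
append_value_obs <- function(db, person_id, concept_id, date, value_num = NULL,
                             value_str = NULL, source_value = NA_character_,
                             visit_id = NULL, qualifier = NULL) {
  n <- length(person_id)
  if (n == 0L) return(invisible(db))
  cdm_append(db, "observation",
             observation_id = next_ids(db, "observation", n),
             person_id = person_id, observation_concept_id = concept_id,
             observation_date = date, observation_type_concept_id = 32810,
             value_as_number = value_num %||% NA_real_,
             value_as_string = value_str %||% NA_character_,
             value_as_concept_id = 0, qualifier_concept_id = 0, unit_concept_id = 0,
             qualifier_source_value = qualifier %||% NA_character_,
             observation_source_value = source_value,
             visit_occurrence_id = visit_id %||% NA_real_)
  invisible(db)
}
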