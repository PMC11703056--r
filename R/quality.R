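# Quality assessment: field coverage, Achilles-style mapping coverage, and a
# DQD-style catalog of conformance/completeness checks with a plausibility
# toggle (plausibility is disabled by default: randomly generated example
# data carries no logical consistency to check).

#' Field coverage of a transformation
#'
#' The ratio of transformed fields to all fields intended for retention:
#' `100 * transformed / (transformed + untransformable)`. Intentional
#' omissions (redundant or irrelevant fields) are excluded from the
#' denominator.
#'
#' @param ledger a [make_ledger_fixture()] field ledger.
#' @param format_id 1 or 3.
#' @return percentage (unrounded; Format 1 ships 38/(38+3) = 92.7 percent to
#'   one decimal, Format 3 100/(100+16) = 86.21 to two).
#' @export
field_coverage <- function(ledger, format_id) {
  l <- ledger[ledger$format_id == as.integer(format_id), , drop = FALSE]
  n_t <- sum(l$status == "transformed")
  n_u <- sum(l$status == "untransformable")
  if (n_t + n_u == 0L) abort("empty coverage denominator for format ", format_id)
  100 * n_t / (n_t + n_u)
}

# (domain, source value, concept id) triples underlying mapping coverage
coverage_pairs <- function(db) {
  grab <- function(domain, tab, src, cid, keep = NULL) {
    t <- db$tables[[tab]]
    s <- t[[src]]; cc <- t[[cid]]
    ok <- !is.na(s)
    if (!is.null(keep)) ok <- ok & keep(t)
    if (!any(ok)) return(NULL)
    data.frame(domain = domain, source = s[ok], concept_id = cc[ok],
               stringsAsFactors = FALSE)
  }
  rbind(
    grab("Condition", "condition_occurrence", "condition_source_value", "condition_concept_id"),
    grab("Condition status", "condition_occurrence", "condition_status_source_value",
         "condition_status_concept_id"),
    grab("Drug", "drug_exposure", "drug_source_value", "drug_concept_id"),
    grab("Measurement", "measurement", "measurement_source_value", "measurement_concept_id"),
    grab("Observation", "observation", "observation_source_value", "observation_concept_id"),
    grab("Procedure", "procedure_occurrence", "procedure_source_value", "procedure_concept_id"),
    grab("Provider Specialty", "provider", "specialty_source_value", "specialty_concept_id"),
    grab("Visit", "visit_occurrence", "visit_source_value", "visit_concept_id")
  )
}

#' Concept-mapping coverage per domain
#'
#' For each domain: the number of distinct source codes, how many of them are
#' assigned a standard concept (concept id not 0), and the same ratio over
#' records (rows). Mirrors the Achilles/CDM-Inspection mapping overview.
#'
#' @param db a `cdm_database`.
#' @return data.frame with columns `domain`, `codes_source`, `codes_mapped`,
#'   `pct_codes`, `records_source`, `records_mapped`, `pct_records`
#'   (percentages half-up to one decimal).
#' @export
mapping_coverage <- function(db) {
  pairs <- coverage_pairs(db)
  domains <- c("Condition", "Condition status", "Drug", "Measurement",
               "Observation", "Procedure", "Provider Specialty", "Visit")
  out <- lapply(domains, function(dm) {
    p <- pairs[pairs$domain == dm, , drop = FALSE]
    if (is.null(p) || nrow(p) == 0L)
      return(data.frame(domain = dm, codes_source = 0L, codes_mapped = 0L,
                        pct_codes = NA_real_, records_source = 0L,
                        records_mapped = 0L, pct_records = NA_real_))
    mapped <- !is.na(p$concept_id) & p$concept_id != 0
    cs <- length(unique(p$source))
    cm <- length(unique(p$source[mapped]))
    data.frame(domain = dm, codes_source = cs, codes_mapped = cm,
               pct_codes = pct(cm, cs), records_source = nrow(p),
               records_mapped = sum(mapped),
               pct_records = pct(sum(mapped), nrow(p)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

check_row <- function(check, category, context, n_failed, n_total) {
  data.frame(check = check, category = category, context = context,
             passed = n_failed == 0L, n_failed = as.integer(n_failed),
             n_total = as.integer(n_total), stringsAsFactors = FALSE)
}

event_tables <- c("condition_occurrence", "procedure_occurrence", "drug_exposure",
                  "observation", "measurement")
event_concept_col <- c(condition_occurrence = "condition_concept_id",
                       procedure_occurrence = "procedure_concept_id",
                       drug_exposure = "drug_concept_id",
                       observation = "observation_concept_id",
                       measurement = "measurement_concept_id",
                       visit_occurrence = "visit_concept_id")
event_date_col <- c(condition_occurrence = "condition_start_date",
                    procedure_occurrence = "procedure_date",
                    drug_exposure = "drug_exposure_start_date",
                    observation = "observation_date",
                    measurement = "measurement_date",
                    visit_occurrence = "visit_start_date")
table_domain <- c(condition_occurrence = "Condition", procedure_occurrence = "Procedure",
                  drug_exposure = "Drug", observation = "Observation",
                  measurement = "Measurement", visit_occurrence = "Visit")

#' Run the data-quality check catalog
#'
#' A compact reimplementation of the check semantics of the OHDSI Data
#' Quality Dashboard: each check carries a category (Conformance,
#' Completeness, Plausibility) and a context (Verification checks test the
#' CDM against its own specification; Validation checks test it against the
#' source data). Plausibility checks only run when enabled; on randomly
#' generated data they carry no signal. Check results are data, never
#' exceptions.
#'
#' @param db a `cdm_database`.
#' @param store the `vocabulary_store` used for the transformation.
#' @param enable_plausibility run the plausibility section (default `FALSE`).
#' @param source optional named list of [source_dataset()]s; when given, the
#'   Validation-context checks run against it.
#' @param concept0_threshold maximum tolerated fraction of concept-0 rows per
#'   concept field before a completeness check fails (default 0.05).
#' @return data.frame with columns `check`, `category`, `context`, `passed`,
#'   `n_failed`, `n_total`.
#' @export
run_checks <- function(db, store, enable_plausibility = FALSE, source = NULL,
                       concept0_threshold = 0.05) {
  res <- list()
  add <- function(...) res[[length(res) + 1L]] <<- check_row(...)

  ## Conformance / Verification ---------------------------------------------
  for (tb in names(.cdm_pk)) {
    pk <- db$tables[[tb]][[.cdm_pk[[tb]]]]
    add(paste0("pk_unique_", tb), "Conformance", "Verification",
        sum(duplicated(pk)), length(pk))
  }
  fk <- cdm_fk_violations(db)
  for (i in seq_len(nrow(fk)))
    add(sprintf("fk_%s_%s", fk$child[i], fk$column[i]), "Conformance",
        "Verification", fk$n_dangling[i], fk$n[i])
  known <- c(0, store$concepts$concept_id)
  std <- c(0, store$concepts$concept_id[store$concepts$standard_concept == "S"])
  for (tb in names(event_concept_col)) {
    cc <- db$tables[[tb]][[event_concept_col[[tb]]]]
    add(paste0("concept_exists_", tb), "Conformance", "Verification",
        sum(!(cc %in% known)), length(cc))
    add(paste0("standard_concept_", tb), "Conformance", "Verification",
        sum(!(cc %in% std)), length(cc))
    dom <- store$concepts$domain_id[match(cc, store$concepts$concept_id)]
    bad <- !is.na(dom) & cc != 0 & dom != table_domain[[tb]] &
      !(tb == "observation" & dom %in% c("Condition Status"))
    add(paste0("domain_match_", tb), "Conformance", "Verification",
        sum(bad), length(cc))
  }
  g <- db$tables$person$gender_concept_id
  add("concept_exists_person_gender", "Conformance", "Verification",
      sum(!(g %in% known)), length(g))
  add("required_person_fields", "Conformance", "Verification",
      sum(is.na(g) | is.na(db$tables$person$year_of_birth) |
            is.na(db$tables$person$person_source_value)), length(g))
  for (tb in names(event_date_col)) {
    t <- db$tables[[tb]]
    add(paste0("required_", tb, "_fields"), "Conformance", "Verification",
        sum(is.na(t$person_id) | is.na(t[[event_date_col[[tb]]]]) |
              is.na(t[[event_concept_col[[tb]]]])), nrow(t))
  }
  date_pairs <- list(visit_occurrence = c("visit_start_date", "visit_end_date"),
                     condition_occurrence = c("condition_start_date", "condition_end_date"),
                     drug_exposure = c("drug_exposure_start_date", "drug_exposure_end_date"),
                     procedure_occurrence = c("procedure_date", "procedure_end_date"),
                     observation_period = c("observation_period_start_date",
                                            "observation_period_end_date"),
                     payer_plan_period = c("payer_plan_period_start_date",
                                           "payer_plan_period_end_date"))
  for (tb in names(date_pairs)) {
    t <- db$tables[[tb]]
    s <- t[[date_pairs[[tb]][1]]]; e <- t[[date_pairs[[tb]][2]]]
    add(paste0("date_order_", tb), "Conformance", "Verification",
        sum(!is.na(s) & !is.na(e) & e < s), nrow(t))
  }
  op <- db$tables$observation_period
  overl <- 0L
  if (nrow(op) > 1L) {
    sp <- split(seq_len(nrow(op)), op$person_id)
    for (ix in sp) {
      if (length(ix) < 2L) next
      o <- ix[order(op$observation_period_start_date[ix])]
      overl <- overl + sum(op$observation_period_start_date[o][-1] <=
                             op$observation_period_end_date[o][-length(o)])
    }
  }
  add("observation_periods_no_overlap", "Conformance", "Verification", overl, nrow(op))

  ## Completeness / Verification --------------------------------------------
  for (tb in names(event_concept_col)) {
    cc <- db$tables[[tb]][[event_concept_col[[tb]]]]
    n0 <- sum(cc == 0, na.rm = TRUE)
    failed <- if (length(cc) > 0 && n0 / length(cc) > concept0_threshold) n0 else 0L
    add(paste0("concept0_below_threshold_", tb), "Completeness", "Verification",
        failed, length(cc))
  }
  for (tb in c("person", "observation_period", "visit_occurrence",
               "condition_occurrence", "drug_exposure", "payer_plan_period", "cost"))
    add(paste0("nonempty_", tb), "Completeness", "Verification",
        as.integer(nrow(db$tables[[tb]]) == 0L), max(1L, nrow(db$tables[[tb]])))

  ## Validation (source-aware) ----------------------------------------------
  if (!is.null(source)) {
    for (ds in source) {
      f <- ds$format_id
      demo_tab <- if (f %in% c(1L, 2L)) "vers_stamm" else "vers_person"
      psids <- unique(ds$tables[[demo_tab]]$psid)
      add(sprintf("source_persons_in_cdm_f%d", f), "Conformance", "Validation",
          sum(!(psids %in% names(db$person_ids))), length(psids))
      memb <- ds$tables$vers_zeiten
      vsids <- unique(memb$vsid)
      add(sprintf("source_insurances_in_cdm_f%d", f), "Conformance", "Validation",
          sum(!(vsids %in% names(db$payer_ids))), length(vsids))
      n_diag <- if (f %in% c(1L, 2L))
        nrow(ds$tables$kh_diagnosen) + nrow(ds$tables$amb_diagnosen)
      else nrow(ds$tables$kh_khdiag) + nrow(ds$tables$amb_diagnosen)
      n_events <- nrow(db$tables$condition_occurrence) +
        sum(db$tables$observation$observation_concept_id == 4129922, na.rm = TRUE) +
        nrow(db$tables$measurement) + nrow(db$tables$procedure_occurrence)
      add(sprintf("diagnoses_produce_events_f%d", f), "Completeness", "Validation",
          as.integer(n_events < n_diag), max(1L, n_diag))
      rx_tab <- if (f %in% c(1L, 2L)) "arzneimittel" else "am_rezepte"
      add(sprintf("prescriptions_produce_exposures_f%d", f), "Completeness", "Validation",
          as.integer(nrow(db$tables$drug_exposure) < nrow(ds$tables[[rx_tab]])),
          max(1L, nrow(ds$tables[[rx_tab]])))
    }
  }

  ## Plausibility (toggle) ---------------------------------------------------
  if (enable_plausibility) {
    op <- db$tables$observation_period
    in_period <- function(pid, d) {
      ok <- logical(length(pid))
      for (i in seq_along(pid)) {
        if (is.na(pid[i]) || is.na(d[i])) next
        rows <- op$person_id == pid[i]
        ok[i] <- any(op$observation_period_start_date[rows] <= d[i] &
                       op$observation_period_end_date[rows] >= d[i])
      }
      ok
    }
    n_fail <- 0L; n_tot <- 0L
    for (tb in event_tables) {
      t <- db$tables[[tb]]
      ok <- in_period(t$person_id, t[[event_date_col[[tb]]]])
      n_fail <- n_fail + sum(!ok); n_tot <- n_tot + nrow(t)
    }
    add("event_in_observation_period", "Plausibility", "Verification", n_fail, n_tot)
    vis <- db$tables$visit_occurrence
    n_fail <- 0L; n_tot <- 0L
    for (tb in event_tables) {
      t <- db$tables[[tb]]
      has <- !is.na(t$visit_occurrence_id)
      m <- match(t$visit_occurrence_id[has], vis$visit_occurrence_id)
      d <- t[[event_date_col[[tb]]]][has]
      bad <- d < vis$visit_start_date[m] - 7L | d > vis$visit_end_date[m] + 7L
      n_fail <- n_fail + sum(bad, na.rm = TRUE); n_tot <- n_tot + sum(has)
    }
    add("event_within_week_of_visit", "Plausibility", "Verification", n_fail, n_tot)
    dth <- db$tables$death
    by <- db$tables$person$year_of_birth[match(dth$person_id, db$tables$person$person_id)]
    add("birth_before_death", "Plausibility", "Verification",
        sum(!is.na(by) & as.integer(format(dth$death_date, "%Y")) < by), nrow(dth))
  }
  do.call(rbind, res)
}

#' Summarise check results per category and context
#'
#' @param checks output of [run_checks()].
#' @return data.frame with pass/fail/total counts and pass percentage per
#'   (category, context), plus a Total row per context.
#' @export
check_totals <- function(checks) {
  agg <- function(sub, cat, ctx) {
    data.frame(category = cat, context = ctx, pass = sum(sub$passed),
               fail = sum(!sub$passed), total = nrow(sub),
               pct_pass = pct(sum(sub$passed), nrow(sub)), stringsAsFactors = FALSE)
  }
  out <- list()
  for (ctx in unique(checks$context)) {
    for (cat in unique(checks$category[checks$context == ctx]))
      out[[length(out) + 1L]] <- agg(checks[checks$category == cat &
                                              checks$context == ctx, ], cat, ctx)
    out[[length(out) + 1L]] <- agg(checks[checks$context == ctx, ], "Total", ctx)
  }
  do.call(rbind, out)
}

#' Assemble the full quality report
#'
#' @inheritParams run_checks
#' @param ledgers list of field ledgers (see [make_ledger_fixture()]) to
#'   report coverage for.
#' @return object of class `quality_report` with elements `field_coverage`,
#'   `mapping_coverage`, `checks`, `totals`.
#' @export
quality_report <- function(db, store, ledgers = list(), source = NULL,
                           enable_plausibility = FALSE) {
  fc <- lapply(ledgers, function(l) {
    f <- l$format_id[1]
    list(format_id = f, pct = field_coverage(l, f),
         n_transformed = sum(l$status == "transformed"),
         n_omitted = sum(l$status == "omitted_intentional"),
         n_untransformable = sum(l$status == "untransformable"))
  })
  checks <- run_checks(db, store, enable_plausibility = enable_plausibility,
                       source = source)
  structure(list(field_coverage = fc, mapping_coverage = mapping_coverage(db),
                 checks = checks, totals = check_totals(checks),
                 plausibility_enabled = enable_plausibility),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat("<quality_report>\n")
  for (fc in x$field_coverage)
    cat(sprintf("  field coverage format %d: %.2f%% (%d/%d)\n", fc$format_id, fc$pct,
                fc$n_transformed, fc$n_transformed + fc$n_untransformable))
  cat(sprintf("  checks: %d (%d failed)\n", nrow(x$checks), sum(!x$checks$passed)))
  invisible(x)
}

#' Write a quality report to disk
#'
#' Emits machine-readable JSON (`report.json`) plus a human-readable Markdown
#' rendering (`report.md`) with the coverage and check summary tables.
#'
#' @param report a [quality_report()].
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
render_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort("cannot create output directory ", out_dir)
  jsonlite::write_json(
    list(field_coverage = report$field_coverage,
         mapping_coverage = report$mapping_coverage,
         checks = report$checks, totals = report$totals,
         plausibility_enabled = report$plausibility_enabled),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA, na = "null")
  md <- c("# Quality report", "")
  for (fc in report$field_coverage)
    md <- c(md, sprintf("Field coverage format %d: **%.2f%%** (%d transformed, %d untransformable, %d intentionally omitted)",
                        fc$format_id, fc$pct, fc$n_transformed, fc$n_untransformable,
                        fc$n_omitted))
  md_tab <- function(df) {
    c(paste0("| ", paste(names(df), collapse = " | "), " |"),
      paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
      vapply(seq_len(nrow(df)), function(i)
        paste0("| ", paste(vapply(df[i, ], function(v) as.character(v), ""),
                           collapse = " | "), " |"), ""))
  }
  md <- c(md, "", "## Mapping coverage", "", md_tab(report$mapping_coverage),
          "", "## Check totals", "", md_tab(report$totals),
          "", "## Failed checks", "")
  failed <- report$checks[!report$checks$passed, , drop = FALSE]
  md <- c(md, if (nrow(failed)) md_tab(failed) else "none")
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(out_dir)
}
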