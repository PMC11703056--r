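# Orchestration: synth -> etl -> qa as one configurable, logged pipeline,
# plus the optional union of the two per-format CDM outputs.

#' Read and validate a pipeline run configuration
#'
#' The configuration mirrors the CLI flags. Top level: `seed`, `out_dir`,
#' `plausibility`, `union`, `vocab` (paths `concept`, `relationship`,
#' `local_mappings`, `uas_mapping`; all optional, the bundled fixture is the
#' default), and `formats`: a list of blocks with `format_id`, `years`
#' (unique, processed ascending), `n_persons`, optional `source_dir` (when
#' given, data is read instead of generated) and optional `anomalies` (passed
#' through to [generator_config()]).
#'
#' @param config a list or the path of a YAML file.
#' @return validated config list.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) abort("config must be a list or a YAML file path")
  config$seed <- as.integer(config$seed %||% 1L)
  if (is.null(config$out_dir)) abort("config error: out_dir is required")
  config$plausibility <- isTRUE(config$plausibility)
  config$union <- isTRUE(config$union)
  if (is.null(config$formats) || !length(config$formats))
    abort("config error: no formats configured")
  for (f in config$formats) {
    if (is.null(f$format_id) || !(as.integer(f$format_id) %in% c(1L, 2L, 3L)))
      abort("config error: format_id must be 1, 2 or 3")
    years <- as.integer(unlist(f$years))
    if (!length(years)) abort("config error: years missing for format ", f$format_id)
    if (anyDuplicated(years))
      abort("config error: duplicate year for format ", f$format_id,
            " (re-loading a year would duplicate its events)")
  }
  vv <- config$vocab %||% list()
  for (p in c("concept", "relationship", "local_mappings", "uas_mapping")) {
    if (!is.null(vv[[p]]) && !file.exists(vv[[p]]))
      abort("config error: vocabulary file not found: ", vv[[p]])
  }
  config
}

pipeline_store <- function(config) {
  vv <- config$vocab %||% list()
  dir <- system.file("extdata", "vocab", package = "hdlomop")
  store <- load_athena(vv$concept %||% file.path(dir, "CONCEPT.csv"),
                       vv$relationship %||% file.path(dir, "CONCEPT_RELATIONSHIP.csv"))
  store <- suppressMessages(load_local_mappings(
    vv$local_mappings %||% file.path(dir, "local_mappings.csv"), store))
  uas <- vv$uas_mapping %||% file.path(dir, "uas_mapping.csv")
  store <- suppressMessages(load_local_mappings(uas, store, context = "uas"))
  store
}

#' Run the full pipeline
#'
#' For each configured format: generate (or read) the source data, validate
#' it, transform the years sequentially in ascending order into one CDM,
#' write the CDM CSVs, and render the quality report. With `union: true` and
#' two formats, additionally writes the union CDM (surrogate keys re-based,
#' persons merged on psid).
#'
#' @param config list or YAML path (see [read_run_config()]).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the per-format `cdm_database`s, quality
#'   reports and output paths.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  config <- read_run_config(config)
  say <- function(...) if (!quiet) message("[hdlomop] ", ...)
  store <- pipeline_store(config)
  out_dir <- config$out_dir
  dbs <- list(); reports <- list()
  for (f in config$formats) {
    fid <- as.integer(f$format_id)
    gen_fid <- if (fid == 2L) 1L else fid
    years <- sort(as.integer(unlist(f$years)))
    db <- cdm_new()
    sources <- list()
    for (year in years) {
      src_dir <- file.path(out_dir, "source", paste0("format", fid), year)
      if (!is.null(f$source_dir)) {
        src_dir <- file.path(f$source_dir, year)
        say("format ", fid, " year ", year, ": reading source from ", src_dir)
        ds <- read_source(src_dir, gen_fid, year)
      } else {
        say("format ", fid, " year ", year, ": generating ", f$n_persons %||% 100,
            " persons (seed ", config$seed, ")")
        cfg <- do.call(generator_config, c(
          list(format_id = gen_fid, n_persons = f$n_persons %||% 100,
               years = years, seed = config$seed), f$anomalies %||% list()))
        ds <- if (gen_fid == 1L) generate_format1(cfg, year) else generate_format3(cfg, year)
        write_source(ds, src_dir)
        ds <- read_source(src_dir, gen_fid, year)
      }
      viol <- validate_source(ds)
      if (!is.null(viol) && nrow(viol))
        abort("source validation failed for format ", fid, " year ", year, ": ",
              nrow(viol), " violation(s); first: ", viol$table[1], " row ",
              viol$row[1], " ", viol$field[1], " (", viol$rule[1], ")")
      say("format ", fid, " year ", year, ": transforming")
      db <- if (gen_fid == 1L) run_format1(ds, store, db) else run_format3(ds, store, db)
      sources[[as.character(year)]] <- ds
    }
    cdm_dir <- file.path(out_dir, "cdm", paste0("format", fid))
    write_cdm(db, cdm_dir)
    say("format ", fid, ": CDM written to ", cdm_dir)
    ledger <- make_ledger_fixture(gen_fid)
    rep <- quality_report(db, store, ledgers = list(ledger), source = sources,
                          enable_plausibility = config$plausibility)
    qa_dir <- file.path(out_dir, "qa", paste0("format", fid))
    render_report(rep, qa_dir)
    say("format ", fid, ": quality report written to ", qa_dir,
        " (", sum(!rep$checks$passed), " failed checks)")
    dbs[[paste0("format", fid)]] <- db
    reports[[paste0("format", fid)]] <- rep
  }
  if (config$union && length(dbs) >= 2L) {
    u <- union_cdm(dbs[[1]], dbs[[2]])
    write_cdm(u, file.path(out_dir, "cdm", "union"))
    say("union CDM written")
    dbs$union <- u
  }
  invisible(list(dbs = dbs, reports = reports, out_dir = out_dir))
}

#' Union of two CDM databases
#'
#' Re-bases the second database's surrogate keys by offsetting them with the
#' first database's counters; persons sharing a psid across the two runs are
#' merged into one person row (psid is a long-term pseudonym, stable across
#' formats). All other rows are preserved.
#'
#' @param db1,db2 `cdm_database`s from independent runs.
#' @return a new `cdm_database`.
#' @export
union_cdm <- function(db1, db2) {
  out <- cdm_new()
  for (nm in names(out$tables)) out$tables[[nm]] <- db1$tables[[nm]]
  out$counters <- db1$counters
  out$person_ids <- db1$person_ids
  out$payer_ids <- db1$payer_ids
  off <- db1$counters

  # person remap: shared psid -> db1 id; new psid -> offset id
  p2 <- db2$tables$person
  shared <- p2$person_source_value %in% names(db1$person_ids)
  pmap <- stats::setNames(
    ifelse(shared, as.numeric(db1$person_ids[p2$person_source_value]),
           p2$person_id + off[["person"]]),
    p2$person_id)
  remap_person <- function(v) ifelse(is.na(v), NA_real_, as.numeric(pmap[as.character(v)]))

  for (nm in names(out$tables)) {
    t2 <- db2$tables[[nm]]
    if (nm == "person") t2 <- t2[!shared, , drop = FALSE]
    if (nrow(t2) == 0L) next
    if ("person_id" %in% names(t2)) t2$person_id <- remap_person(t2$person_id)
    if (!nm %in% c("person", "death"))  # their pk is the (already remapped) person_id
      t2[[.cdm_pk[[nm]]]] <- t2[[.cdm_pk[[nm]]]] + off[[nm]]
    for (fk in list(c("visit_occurrence_id", "visit_occurrence"),
                    c("payer_plan_period_id", "payer_plan_period"),
                    c("provider_id", "provider"), c("care_site_id", "care_site"),
                    c("location_id", "location"),
                    c("preceding_visit_occurrence_id", "visit_occurrence")))
      if (fk[[1]] %in% names(t2) && fk[[1]] != .cdm_pk[[nm]])
        t2[[fk[[1]]]] <- t2[[fk[[1]]]] + off[[fk[[2]]]]
    if (nm == "cost") {
      dom_off <- c(Drug = off[["drug_exposure"]], Visit = off[["visit_occurrence"]],
                   Procedure = off[["procedure_occurrence"]])
      o <- dom_off[t2$cost_domain_id]
      t2$cost_event_id <- t2$cost_event_id + ifelse(is.na(o), 0, o)
    }
    out$tables[[nm]] <- rbind(out$tables[[nm]], t2)
  }
  out$counters <- db1$counters + db2$counters
  new_pids <- pmap[as.character(db2$tables$person$person_id[!shared])]
  out$person_ids <- c(db1$person_ids,
                      stats::setNames(as.numeric(new_pids),
                                      db2$tables$person$person_source_value[!shared]))
  out$payer_ids <- c(db1$payer_ids, db2$payer_ids + off[["payer_plan_period"]])
  out
}
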