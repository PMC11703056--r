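#' Construct an in-memory source dataset
#'
#' @param format_id 1 or 3.
#' @param reported_year the reported year the tables belong to. The reported
#'   year always comes from configuration, never from the rows.
#' @param tables named list of data.frames (all cells character), one per
#'   table of [source_tables()].
#' @return object of class `source_dataset`.
#' @export
source_dataset <- function(format_id, reported_year, tables) {
  expected <- source_tables(format_id)
  missing <- setdiff(expected, names(tables))
  if (length(missing))
    abort("missing source tables: ", paste(missing, collapse = ", "))
  structure(list(format_id = as.integer(format_id),
                 reported_year = as.integer(reported_year),
                 tables = tables[expected]),
            class = "source_dataset")
}

#' @export
print.source_dataset <- function(x, ...) {
  cat(sprintf("<source_dataset format %d, year %d>\n", x$format_id, x$reported_year))
  for (nm in names(x$tables))
    cat(sprintf("  %-16s %6d rows, %2d cols\n", nm, nrow(x$tables[[nm]]), ncol(x$tables[[nm]])))
  invisible(x)
}

table_path <- function(directory, format_id, table) {
  if (format_id == 3L)
    file.path(directory, schema_of_table(3L, table), paste0(table, ".csv"))
  else
    file.path(directory, paste0(table, ".csv"))
}

#' Read a source dataset from a directory of CSV files
#'
#' One CSV per source table (UTF-8, comma-delimited, header row, empty string
#' = absent); Format 3 tables live in per-schema subdirectories. Unknown extra
#' columns are preserved as opaque strings.
#'
#' @param directory path holding the table files for one reported year.
#' @inheritParams source_dataset
#' @return A validated [source_dataset()].
#' @export
read_source <- function(directory, format_id, reported_year) {
  format_id <- as.integer(format_id)
  expected <- source_tables(format_id)
  paths <- vapply(expected, table_path, "", directory = directory, format_id = format_id)
  missing <- expected[!file.exists(paths)]
  if (length(missing))
    abort("missing source table file(s): ", paste(missing, collapse = ", "),
          " under ", directory)
  tables <- lapply(seq_along(expected), function(i) {
    tryCatch(read_table_csv(paths[[i]]),
             error = function(e) abort("malformed table '", expected[[i]], "' (",
                                       paths[[i]], "): ", conditionMessage(e)))
  })
  names(tables) <- expected
  sc <- source_schema(format_id)
  for (tb in expected) {
    need <- sc$field[sc$table == tb]
    miss <- setdiff(need, names(tables[[tb]]))
    if (length(miss))
      abort("table '", tb, "': missing column(s) ", paste(miss, collapse = ", "))
  }
  source_dataset(format_id, reported_year, tables)
}

#' Write a source dataset as CSV files
#'
#' Inverse of [read_source()]; the round trip is lossless cell-by-cell.
#' @param ds a [source_dataset()].
#' @param directory output directory (created if needed).
#' @return `directory`, invisibly.
#' @export
write_source <- function(ds, directory) {
  for (tb in names(ds$tables)) {
    p <- table_path(directory, ds$format_id, tb)
    dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
    write_table_csv(ds$tables[[tb]], p)
  }
  invisible(directory)
}

violation <- function(table, row, field, rule, message) {
  data.frame(table = table, row = as.integer(row), field = field, rule = rule,
             message = message, stringsAsFactors = FALSE)
}

no_violations <- function() violation(character(0), integer(0), character(0),
                                      character(0), character(0))[0, ]

#' Validate a source dataset against its format invariants
#'
#' Checks, per format: presence of all tables, non-empty psid, case
#' enumerators >= 1 and contiguous per person, non-empty diagnosis/procedure
#' codes, quarter/month/date bounds, and (Format 3) that every schema case ID
#' resolves to exactly one vsid. Violations are data, not exceptions.
#'
#' @param ds a [source_dataset()].
#' @return data.frame with columns `table`, `row`, `field`, `rule`, `message`;
#'   zero rows iff the dataset is clean.
#' @export
validate_source <- function(ds) {
  sc <- source_schema(ds$format_id)
  out <- list(no_violations())
  bad_rows <- function(tb, idx, field, rule, msg) {
    if (!any(idx)) return(NULL)
    violation(tb, which(idx), field, rule, msg)
  }
  for (tb in names(ds$tables)) {
    tab <- ds$tables[[tb]]
    fields <- sc[sc$table == tb, ]
    if ("psid" %in% names(tab))
      out[[length(out) + 1L]] <- bad_rows(tb, is_blank(tab$psid), "psid",
                                          "psid_nonempty", "psid must be non-empty")
    for (i in seq_len(nrow(fields))) {
      f <- fields$field[i]; ty <- fields$type[i]
      if (!f %in% names(tab)) next
      v <- as.character(tab[[f]])
      filled <- !is_blank(v)
      if (ty == "quarter") {
        q <- as_int(v)
        out[[length(out) + 1L]] <- bad_rows(tb, filled & (is.na(q) | q < 1L | q > 4L),
                                            f, "quarter_bounds", "quarter must be 1..4")
      } else if (ty == "month") {
        m <- as_int(v)
        out[[length(out) + 1L]] <- bad_rows(tb, filled & (is.na(m) | m < 1L | m > 12L),
                                            f, "month_bounds", "month must be 1..12")
      } else if (ty == "date") {
        d <- iso_date(v)
        out[[length(out) + 1L]] <- bad_rows(tb, filled & is.na(d), f,
                                            "date_iso", "dates must be ISO-8601 YYYY-MM-DD")
      } else if (ty %in% c("int", "year")) {
        n <- as_int(v)
        out[[length(out) + 1L]] <- bad_rows(tb, filled & is.na(n), f,
                                            "integer", "must be an integer")
      } else if (ty == "amount") {
        n <- as_num(v)
        out[[length(out) + 1L]] <- bad_rows(tb, filled & is.na(n), f,
                                            "numeric", "must be numeric")
      }
    }
  }
  if (ds$format_id %in% c(1L, 2L)) {
    kh <- ds$tables$kh_diagnosen
    if (nrow(kh)) {
      fall <- as_int(kh$fall)
      out[[length(out) + 1L]] <- bad_rows("kh_diagnosen", is.na(fall) | fall < 1L,
                                          "fall", "case_enumerator",
                                          "case enumerator must be an integer >= 1")
      out[[length(out) + 1L]] <- bad_rows("kh_diagnosen", is_blank(kh$icd_code),
                                          "icd_code", "code_nonempty",
                                          "diagnosis code must be non-empty")
    }
    amb <- ds$tables$amb_diagnosen
    if (nrow(amb))
      out[[length(out) + 1L]] <- bad_rows("amb_diagnosen", is_blank(amb$icd_code),
                                          "icd_code", "code_nonempty",
                                          "diagnosis code must be non-empty")
  } else {
    # every schema-specific case ID must resolve to exactly one vsid
    case_reg <- list(
      amb_fallnr = c("amb_faelle", "amb_diagnosen", "amb_ops", "amb_leistungen"),
      zahn_fallnr = c("zahn_faelle", "zahn_befunde", "zahn_leistungen"),
      kh_fallnr = c("kh_faelle", "kh_khdiag", "kh_ops", "kh_entgelte"),
      am_fallnr = c("am_rezepte", "am_kosten")
    )
    for (key in names(case_reg)) {
      tabs <- case_reg[[key]]
      anchor <- ds$tables[[tabs[[1]]]]
      vsids <- tapply(anchor$vsid, anchor[[key]], function(v) length(unique(v)))
      dup_ids <- names(vsids)[vsids > 1L]
      if (length(dup_ids))
        out[[length(out) + 1L]] <- violation(tabs[[1]], match(dup_ids, anchor[[key]]),
                                             key, "case_vsid_unique",
                                             "case ID maps to more than one vsid")
      known <- unique(anchor[[key]])
      for (tb in tabs[-1]) {
        child <- ds$tables[[tb]]
        if (!nrow(child)) next
        dangling <- !(child[[key]] %in% known)
        out[[length(out) + 1L]] <- bad_rows(tb, dangling, key, "case_resolves",
                                            "case ID matches no case-table row (no vsid)")
      }
    }
    for (tb in c("kh_khdiag", "amb_diagnosen")) {
      tab <- ds$tables[[tb]]
      if (nrow(tab))
        out[[length(out) + 1L]] <- bad_rows(tb, is_blank(tab$icd_code), "icd_code",
                                            "code_nonempty", "diagnosis code must be non-empty")
    }
    for (tb in c("kh_ops", "amb_ops")) {
      tab <- ds$tables[[tb]]
      if (nrow(tab))
        out[[length(out) + 1L]] <- bad_rows(tb, is_blank(tab$ops_code), "ops_code",
                                            "code_nonempty", "procedure code must be non-empty")
    }
  }
  do.call(rbind, Filter(Negate(is.null), out))
}
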