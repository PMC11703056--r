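# Shared fixtures: the bundled micro-vocabulary (with a UAS context added)
# and small synthetic datasets built in code.

h_store <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) cached <<- load_vocab_fixture()
    cached
  }
})

h_cfg1 <- function(n = 10, seed = 42, years = 2009, ...)
  generator_config(1, n_persons = n, years = years, seed = seed, ...)

h_cfg3 <- function(n = 10, seed = 42, years = 2019, ...)
  generator_config(3, n_persons = n, years = years, seed = seed, ...)

h_ds1 <- function(...) generate_format1(h_cfg1(...))
h_ds3 <- function(...) generate_format3(h_cfg3(...))

h_run1 <- function(..., db = cdm_new()) run_format1(h_ds1(...), h_store(), db)
h_run3 <- function(..., db = cdm_new()) run_format3(h_ds3(...), h_store(), db)

# hand-built one-person Format 1 dataset for worked examples
h_manual_f1 <- function(kh = NULL, amb = NULL, rx = NULL, bp = NULL,
                        year = 2009, dead = FALSE, dead_year = year,
                        rsc = NULL) {
  empty <- function(tb) {
    f <- source_schema(1)$field[source_schema(1)$table == tb]
    stats::setNames(as.data.frame(matrix(character(0), 0, length(f)),
                                  stringsAsFactors = FALSE), f)
  }
  tabs <- lapply(source_tables(1), empty)
  names(tabs) <- source_tables(1)
  tabs$vers_stamm[1, ] <- list(psid = "A1", vsid = "V1", gebjahr = "1960",
                               geschlecht = "w", verstorben = if (dead) "1" else "0",
                               sterbejahr = if (dead) as.character(dead_year) else "",
                               famstand = "", berichtsjahr = as.character(year))
  tabs$vers_zeiten[1, ] <- list(psid = "A1", vsid = "V1", kv_ik = "101",
                                kassenart = "AOK", versichertentage = "365")
  tabs$gemeinde[1, ] <- list(psid = "A1", vsid = "V1", gkz = "01001000",
                             bundesland = "01", kreis = "001", satzart = "10")
  fill <- function(proto, rows) {
    for (i in seq_along(rows)) {
      r <- rows[[i]]
      proto[i, ] <- lapply(names(proto), function(f) r[[f]] %||% "")
    }
    proto
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  if (!is.null(kh)) tabs$kh_diagnosen <- fill(tabs$kh_diagnosen, kh)
  if (!is.null(amb)) tabs$amb_diagnosen <- fill(tabs$amb_diagnosen, amb)
  if (!is.null(rx)) tabs$arzneimittel <- fill(tabs$arzneimittel, rx)
  if (!is.null(bp)) tabs$blutreinigung <- fill(tabs$blutreinigung, bp)
  if (!is.null(rsc)) tabs$vers_rsc <- fill(tabs$vers_rsc, rsc)
  source_dataset(1, year, tabs)
}

# hand-built one-person Format 3 dataset; `rows` is a named list of
# lists-of-rows to inject into specific tables
h_manual_f3 <- function(rows = list(), year = 2019, quarters = 1:4,
                        dead = FALSE, sterbedatum = "", sterbequartal = "") {
  `%||%` <- function(a, b) if (is.null(a)) b else a
  sc <- source_schema(3)
  empty <- function(tb) {
    f <- sc$field[sc$table == tb]
    stats::setNames(as.data.frame(matrix(character(0), 0, length(f)),
                                  stringsAsFactors = FALSE), f)
  }
  tabs <- lapply(source_tables(3), empty)
  names(tabs) <- source_tables(3)
  fill <- function(proto, rws) {
    for (i in seq_along(rws))
      proto[i, ] <- lapply(names(proto), function(f) rws[[i]][[f]] %||% "")
    proto
  }
  tabs$vers_person <- fill(tabs$vers_person, list(list(
    psid = "A1", vsid = "V1", gebjahr = "1955", gebmonat = "6", geschlecht = "m",
    verstorben = if (dead) "1" else "0", sterbedatum = sterbedatum,
    sterbequartal = sterbequartal, versstatus = "1",
    berichtsjahr = as.character(year))))
  tabs$vers_zeiten <- fill(tabs$vers_zeiten, lapply(quarters, function(q) list(
    psid = "A1", vsid = "V1", kv_ik = "101", kassenart = "AOK",
    quartal = as.character(q), versichertentage = "90", mitgliedsart = "M",
    zuzahlungsbefreit_kz = "0")))
  tabs$vers_wohnort <- fill(tabs$vers_wohnort, list(list(
    psid = "A1", vsid = "V1", gkz = "01001000", bundesland = "01",
    kreis = "001", plz = "24103")))
  for (tb in names(rows)) tabs[[tb]] <- fill(tabs[[tb]], rows[[tb]])
  source_dataset(3, year, tabs)
}
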