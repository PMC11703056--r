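# Synthetic HDL-shaped claims data. The HDL example data the ETL was designed
# against is itself randomly generated without realistic distributions; this
# generator reproduces its structural properties (keys, case enumerators,
# date precision, fictional code pools) at configurable size, so every
# downstream stage is testable without any data access.

## Code pools -----------------------------------------------------------------
# ICD pool split into "in fixture vocabulary" and syntactically valid but
# non-existing codes (the example data contains artificially created
# ICD-10-GM codes), so mapping-coverage behaviour is controllable.
icd_pool_mapped <- function() c("E11.9", "I10", "J44.9", "M05.44", "U07.1",
                                "F32.1", "K52.9", "N18.5", "Z99.2", "Z01.7", "Z34")

icd_pool_invalid <- function() {
  g <- expand.grid(d = c(1, 3, 5, 7), n = 10 + 3 * (0:12), L = c("V", "W", "X", "Y"),
                   stringsAsFactors = FALSE)
  head(sprintf("%s%02d.%d", g$L, g$n, g$d), 49)
}

ops_pool_mapped <- function() c("5-511.1", "8-854.2", "6-002.1", "1-208.0", "9-984.7")

ops_pool_invalid <- function() {
  g <- expand.grid(n = 0:54, p = c(3, 5, 8, 9), stringsAsFactors = FALSE)
  sprintf("%d-9%02d.9", g$p, g$n)
}

uas_pool <- function() c("01100", "01411", "03230", "04514", "32012", "35110",
                         "01700", "09345", "13250", "27310")

specialty_pool_mapped <- function() c("01", "02", "03", "04", "05", "06", "07",
                                      "08", "10", "11", "12", "13", "14")
specialty_pool_unmapped <- function() c("90", "91", "92", "99")

## Configuration --------------------------------------------------------------

#' Configuration of the synthetic claims generator
#'
#' Defaults mirror the structure of the HDL example data for the format:
#' Format 1 example data carries mostly fictional ICD-10-GM codes (default
#' invalid-code fraction 0.8) and no visit-type code on outpatient rows,
#' Format 3 example data has almost entirely valid ICD codes (0.002) but
#' mostly artificial OPS codes (mapped-row fraction 0.3) and mostly
#' day-precise dates (missing-date fraction 0.2). Sizes are configurable; a
#' fixed seed makes the output byte-deterministic.
#'
#' @param format_id 1 or 3.
#' @param n_persons persons per year (>= 1).
#' @param years integer vector of reported years.
#' @param seed integer random seed; each table draws from its own stream
#'   seeded by `(seed, table, year)`.
#' @param mean_inpatient_cases,mean_outpatient_dx,mean_prescriptions,mean_amb_cases,mean_dental_cases
#'   Poisson means per person-year for the event tables.
#' @param p_dialysis,p_rsc,p_dmp,p_death Bernoulli probabilities per person.
#' @param frac_invalid_code fraction of diagnosis rows drawing a code absent
#'   from the vocabulary.
#' @param frac_ops_mapped fraction of procedure rows drawing a mapped OPS code.
#' @param frac_missing_date fraction of optional day-precise dates degraded to
#'   quarter/year precision (Format 3).
#' @param frac_empty_visit_type fraction of inpatient rows with an empty
#'   visit-type code (an obligatory CDM field, filled with concept 0).
#' @param frac_empty_status fraction of diagnosis rows with an empty
#'   qualifier/status code.
#' @param frac_specialty_mapped fraction of provider rows drawing a mapped
#'   specialty code.
#' @param multi_insurance fraction of persons with a second insurance
#'   relationship (second vsid) in a year.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(format_id, n_persons = 100, years = NULL, seed = 1,
                             mean_inpatient_cases = NULL, mean_outpatient_dx = 1,
                             mean_prescriptions = 2, mean_amb_cases = 2,
                             mean_dental_cases = 0.5,
                             p_dialysis = 0.2, p_rsc = 0.3, p_dmp = 0.1, p_death = 0.02,
                             frac_invalid_code = NULL, frac_ops_mapped = 0.3,
                             frac_missing_date = 0.2, frac_empty_visit_type = 0,
                             frac_empty_status = 0.1, frac_specialty_mapped = 0.52,
                             multi_insurance = 0.1) {
  format_id <- as.integer(format_id)
  if (!format_id %in% c(1L, 3L)) abort("format_id must be 1 or 3")
  cfg <- list(
    format_id = format_id,
    n_persons = as.integer(n_persons),
    years = as.integer(years %||% if (format_id == 1L) 2009L else 2019L),
    seed = as.integer(seed),
    mean_inpatient_cases = mean_inpatient_cases %||% if (format_id == 1L) 3 else 0.5,
    mean_outpatient_dx = mean_outpatient_dx,
    mean_prescriptions = mean_prescriptions,
    mean_amb_cases = mean_amb_cases,
    mean_dental_cases = mean_dental_cases,
    p_dialysis = p_dialysis, p_rsc = p_rsc, p_dmp = p_dmp, p_death = p_death,
    frac_invalid_code = frac_invalid_code %||% if (format_id == 1L) 0.8 else 0.002,
    frac_ops_mapped = frac_ops_mapped,
    frac_missing_date = frac_missing_date,
    frac_empty_visit_type = frac_empty_visit_type,
    frac_empty_status = frac_empty_status,
    frac_specialty_mapped = frac_specialty_mapped,
    multi_insurance = multi_insurance
  )
  if (cfg$n_persons < 1L) abort("invalid config: n_persons must be >= 1")
  for (p in c("p_dialysis", "p_rsc", "p_dmp", "p_death", "frac_invalid_code",
              "frac_ops_mapped", "frac_missing_date", "frac_empty_visit_type",
              "frac_empty_status", "frac_specialty_mapped", "multi_insurance")) {
    v <- cfg[[p]]
    if (!is.numeric(v) || is.na(v) || v < 0 || v > 1)
      abort("invalid config: ", p, " must be a fraction in [0, 1]")
  }
  for (p in c("mean_inpatient_cases", "mean_outpatient_dx", "mean_prescriptions",
              "mean_amb_cases", "mean_dental_cases"))
    if (cfg[[p]] < 0) abort("invalid config: ", p, " must be >= 0")
  if (anyDuplicated(cfg$years)) abort("invalid config: years must be unique")
  class(cfg) <- "generator_config"
  cfg
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("<generator_config format %d: %d persons, years %s, seed %d>\n",
              x$format_id, x$n_persons, paste(x$years, collapse = ","), x$seed))
  invisible(x)
}

## Shared person frame --------------------------------------------------------
# Demographics are drawn from a year-independent stream so that the same psid
# keeps its birth year and gender across reported years.
synth_persons <- function(cfg, prefix) {
  n <- cfg$n_persons
  with_stream(cfg$seed, paste0(prefix, ":persons"), {
    dead <- stats::runif(n) < cfg$p_death
    dy <- cfg$years[sample.int(length(cfg$years), n, replace = TRUE)]
    data.frame(
      psid = sprintf("%s%07d", prefix, seq_len(n)),
      gebjahr = as.character(sample(1930:2014, n, replace = TRUE)),
      gebmonat = as.character(sample(1:12, n, replace = TRUE)),
      geschlecht = sample(c("m", "w", "d"), n, replace = TRUE, prob = c(.49, .49, .02)),
      dead_year = ifelse(dead, dy, NA_integer_),
      multi = stats::runif(n) < cfg$multi_insurance,
      stringsAsFactors = FALSE)
  })
}

rand_day <- function(year, n) {
  fmt_date(as.Date(sprintf("%04d-01-01", year)) + sample(0:364, n, replace = TRUE))
}

rand_quarter_day <- function(year, quarter, n) {
  fmt_date(quarter_start(year, quarter) + sample(0:88, n, replace = TRUE))
}

amount <- function(n, scale = 300) sprintf("%.2f", round(stats::rexp(n, 1 / scale) + 1, 2))

draw_icd <- function(n, frac_invalid) {
  pool_m <- icd_pool_mapped(); pool_i <- icd_pool_invalid()
  inv <- stats::runif(n) < frac_invalid
  out <- character(n)
  out[inv] <- sample(pool_i, sum(inv), replace = TRUE)
  out[!inv] <- sample(pool_m, sum(!inv), replace = TRUE)
  out
}

draw_ops <- function(n, frac_mapped) {
  mp <- stats::runif(n) < frac_mapped
  out <- character(n)
  out[mp] <- sample(ops_pool_mapped(), sum(mp), replace = TRUE)
  out[!mp] <- sample(ops_pool_invalid(), sum(!mp), replace = TRUE)
  out
}

draw_specialty <- function(n, frac_mapped) {
  mp <- stats::runif(n) < frac_mapped
  out <- character(n)
  out[mp] <- sample(specialty_pool_mapped(), sum(mp), replace = TRUE)
  out[!mp] <- sample(specialty_pool_unmapped(), sum(!mp), replace = TRUE)
  out
}

blank_out <- function(x, frac) {
  x[stats::runif(length(x)) < frac] <- ""
  x
}

# order columns exactly as the schema defines them
schema_frame <- function(format_id, table, cols) {
  sc <- source_schema(format_id)
  fields <- sc$field[sc$table == table]
  n <- length(cols[["psid"]])
  out <- lapply(fields, function(f) {
    v <- cols[[f]]
    if (is.null(v)) rep("", n) else rep_len(as.character(v), n)
  })
  names(out) <- fields
  as.data.frame(out, stringsAsFactors = FALSE, check.names = FALSE)
}

## Format 1 -------------------------------------------------------------------

#' Generate one reported year of Format 1 source data
#'
#' @param cfg a [generator_config()] with `format_id = 1`.
#' @param year the reported year (defaults to the first configured year).
#' @return a [source_dataset()] with the 9 Format 1 tables. Demographics has
#'   exactly `n_persons` rows; every psid in a child table exists in the
#'   demographics table; inpatient case enumerators are contiguous 1..k per
#'   person.
#' @export
generate_format1 <- function(cfg, year = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  if (cfg$format_id != 1L) abort("config is for format ", cfg$format_id)
  year <- as.integer(year %||% cfg$years[[1]])
  per <- synth_persons(cfg, "P1")
  n <- nrow(per)
  vsid1 <- sprintf("V%d%07d", year, seq_len(n))
  vsid2 <- ifelse(per$multi, sprintf("W%d%07d", year, seq_len(n)), NA_character_)
  st <- function(name, expr) with_stream(cfg$seed, paste0("f1:", name, ":", year), expr)

  vers_stamm <- st("vers_stamm", {
    dead <- !is.na(per$dead_year) & per$dead_year == year
    data.frame(psid = per$psid, vsid = vsid1,
               gebjahr = per$gebjahr, geschlecht = per$geschlecht,
               verstorben = ifelse(dead, "1", "0"),
               sterbejahr = ifelse(dead, as.character(year), ""),
               famstand = sample(c("1", "2", "3", ""), n, replace = TRUE),
               berichtsjahr = as.character(year), stringsAsFactors = FALSE)
  })

  vers_rsc <- st("vers_rsc", {
    idx <- which(stats::runif(n) < cfg$p_rsc)
    data.frame(psid = per$psid[idx], vsid = vsid1[idx],
               em_rente_tage = as.character(sample(0:90, length(idx), replace = TRUE)),
               erstattung_tage = as.character(sample(0:30, length(idx), replace = TRUE)),
               krankengeld_tage = as.character(sample(0:60, length(idx), replace = TRUE)),
               stringsAsFactors = FALSE)
  })

  blutreinigung <- st("blutreinigung", {
    idx <- which(stats::runif(n) < cfg$p_dialysis)
    data.frame(psid = per$psid[idx], vsid = vsid1[idx],
               blutreinigung_kz = rep("1", length(idx)),
               lokalisation = sample(c("", "L", "R", "B"), length(idx), replace = TRUE),
               stringsAsFactors = FALSE)
  })

  arzneimittel <- st("arzneimittel", {
    k <- stats::rpois(n, cfg$mean_prescriptions)
    i <- rep(seq_len(n), k); m <- length(i)
    data.frame(psid = per$psid[i], vsid = vsid1[i],
               pzn = sprintf("%08d", sample(10000000:99999999, m, replace = TRUE)),
               verordnungsdatum = rand_day(year, m),
               menge = as.character(sample(1:3, m, replace = TRUE)),
               faktor = rep("1", m),
               zuzahlung = sprintf("%.2f", sample(c(5, 10), m, replace = TRUE)),
               apotheke_ik = sprintf("30%06d", sample(1:20, m, replace = TRUE)),
               stringsAsFactors = FALSE)
  })

  kh_diagnosen <- st("kh_diagnosen", {
    k <- stats::rpois(n, cfg$mean_inpatient_cases)
    i <- rep(seq_len(n), k); m <- length(i)
    data.frame(psid = per$psid[i], vsid = vsid1[i],
               entlassungsmonat = as.character(sample(1:12, m, replace = TRUE)),
               fall = as.character(sequence(k)),
               aufnahmeart = blank_out(sample(c("1", "2"), m, replace = TRUE),
                                       cfg$frac_empty_visit_type),
               verweildauer = as.character(sample(0:20, m, replace = TRUE)),
               entlassungsgrund = sprintf("%02d", sample(1:19, m, replace = TRUE)),
               icd_code = draw_icd(m, cfg$frac_invalid_code),
               diagnoseart = blank_out(sample(c("H", "N"), m, replace = TRUE, prob = c(.6, .4)),
                                       cfg$frac_empty_status),
               stringsAsFactors = FALSE)
  })

  amb_diagnosen <- st("amb_diagnosen", {
    k <- stats::rpois(n, cfg$mean_outpatient_dx)
    i <- rep(seq_len(n), k); m <- length(i)
    data.frame(psid = per$psid[i], vsid = vsid1[i],
               quartal = as.character(sample(1:4, m, replace = TRUE)),
               icd_code = draw_icd(m, cfg$frac_invalid_code),
               qualifizierung = blank_out(sample(c("G", "V", "Z", "A"), m, replace = TRUE,
                                                 prob = c(.6, .2, .15, .05)),
                                          cfg$frac_empty_status),
               icd_zusatz = sample(c("", "!", "†", "*"), m, replace = TRUE,
                                   prob = c(.7, .1, .1, .1)),
               stringsAsFactors = FALSE)
  })

  ausgaben <- st("ausgaben", {
    all_vsid <- c(vsid1, vsid2[!is.na(vsid2)])
    all_psid <- c(per$psid, per$psid[!is.na(vsid2)])
    m <- length(all_vsid)
    cols <- list(psid = all_psid, vsid = all_vsid)
    for (f in c("ausg_kh", "ausg_amb", "ausg_arznei", "ausg_zahn", "ausg_heilmittel",
                "ausg_hilfsmittel", "ausg_krankengeld", "ausg_fahrkosten",
                "ausg_vorsorge", "ausg_sonstige"))
      cols[[f]] <- blank_out(amount(m), 0.3)
    as.data.frame(cols, stringsAsFactors = FALSE)
  })

  vers_zeiten <- st("vers_zeiten", {
    all_vsid <- c(vsid1, vsid2[!is.na(vsid2)])
    all_psid <- c(per$psid, per$psid[!is.na(vsid2)])
    m <- length(all_vsid)
    data.frame(psid = all_psid, vsid = all_vsid,
               kv_ik = sprintf("10%06d", sample(1:5, m, replace = TRUE)),
               kassenart = sample(c("AOK", "BKK", "EK", "IKK", "LKK"), m, replace = TRUE),
               versichertentage = as.character(sample(180:365, m, replace = TRUE)),
               stringsAsFactors = FALSE)
  })

  gemeinde <- st("gemeinde", {
    bl <- sprintf("%02d", sample(1:16, n, replace = TRUE))
    kr <- sprintf("%03d", sample(1:440, n, replace = TRUE))
    data.frame(psid = per$psid, vsid = vsid1,
               gkz = paste0(bl, kr, sprintf("%03d", sample(1:999, n, replace = TRUE))),
               bundesland = bl, kreis = kr, satzart = rep("10", n), stringsAsFactors = FALSE)
  })

  tabs <- list(vers_stamm = vers_stamm, vers_rsc = vers_rsc,
               blutreinigung = blutreinigung, arzneimittel = arzneimittel,
               kh_diagnosen = kh_diagnosen, amb_diagnosen = amb_diagnosen,
               ausgaben = ausgaben, vers_zeiten = vers_zeiten, gemeinde = gemeinde)
  tabs <- lapply(names(tabs), function(tb) {
    keys <- tabs[[tb]][intersect(c("psid", "vsid"), names(tabs[[tb]]))]
    cbind(keys, schema_frame(1L, tb, as.list(tabs[[tb]]))[
      , setdiff(source_schema(1L)$field[source_schema(1L)$table == tb], c("psid", "vsid")),
      drop = FALSE])
  })
  names(tabs) <- c("vers_stamm", "vers_rsc", "blutreinigung", "arzneimittel",
                   "kh_diagnosen", "amb_diagnosen", "ausgaben", "vers_zeiten", "gemeinde")
  source_dataset(1L, year, tabs)
}

## Format 3 -------------------------------------------------------------------

#' Generate one reported year of Format 3 source data
#'
#' Four schemas (insured person, drugs, ambulatory incl. dental, inpatient)
#' with schema-specific case IDs that all resolve to a vsid. Dates are mostly
#' day-precise; a configured fraction is degraded to quarter precision.
#'
#' @inheritParams generate_format1
#' @return a [source_dataset()] with the 17 Format 3 tables.
#' @export
generate_format3 <- function(cfg, year = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  if (cfg$format_id != 3L) abort("config is for format ", cfg$format_id)
  year <- as.integer(year %||% cfg$years[[1]])
  per <- synth_persons(cfg, "P3")
  n <- nrow(per)
  vsid1 <- sprintf("V%d%07d", year, seq_len(n))
  vsid2 <- ifelse(per$multi, sprintf("W%d%07d", year, seq_len(n)), NA_character_)
  st <- function(name, expr) with_stream(cfg$seed, paste0("f3:", name, ":", year), expr)
  sf <- function(tb, cols) {
    sc <- source_schema(3L)
    keys <- sc$field[sc$table == tb & sc$status == "key"]
    rest <- setdiff(sc$field[sc$table == tb], keys)
    kdf <- as.data.frame(cols[keys], stringsAsFactors = FALSE)
    cbind(kdf, schema_frame(3L, tb, cols)[, rest, drop = FALSE])
  }

  vers_person <- st("vers_person", {
    dead <- !is.na(per$dead_year) & per$dead_year == year
    sterbedatum <- character(n); sterbequartal <- character(n)
    if (any(dead)) {
      d <- rand_day(year, sum(dead))
      degrade <- stats::runif(sum(dead)) < cfg$frac_missing_date
      q <- as.character((as.integer(format(iso_date(d), "%m")) - 1L) %/% 3L + 1L)
      sterbedatum[dead] <- ifelse(degrade, "", d)
      sterbequartal[dead] <- q
    }
    sf("vers_person", list(
      psid = per$psid, vsid = vsid1, gebjahr = per$gebjahr, gebmonat = per$gebmonat,
      geschlecht = per$geschlecht, verstorben = ifelse(dead, "1", "0"),
      sterbedatum = sterbedatum, sterbequartal = sterbequartal,
      versstatus = sample(c("1", "3", "5"), n, replace = TRUE),
      berichtsjahr = as.character(year),
      meldedatum = rand_day(year + 1L, n),
      pruefsumme = sprintf("%05d", sample(1:99999, n, replace = TRUE))))
  })

  vers_zeiten <- st("vers_zeiten", {
    # single-insurance persons: one insurer over a contiguous quarter span;
    # multi-insurance persons: vsid1 covers the first part, vsid2 the rest
    qa <- sample(1:2, n, replace = TRUE, prob = c(.9, .1))
    qb <- pmax(qa, sample(3:4, n, replace = TRUE, prob = c(.1, .9)))
    split_q <- ifelse(per$multi, pmax(qa, sample(1:3, n, replace = TRUE)), qb)
    rows <- list()
    for (i in seq_len(n)) {
      q1 <- qa[i]:split_q[i]
      rows[[length(rows) + 1L]] <- data.frame(psid = per$psid[i], vsid = vsid1[i],
                                              quartal = q1, stringsAsFactors = FALSE)
      if (per$multi[i] && split_q[i] < qb[i])
        rows[[length(rows) + 1L]] <- data.frame(psid = per$psid[i], vsid = vsid2[i],
                                                quartal = (split_q[i] + 1L):qb[i],
                                                stringsAsFactors = FALSE)
    }
    z <- do.call(rbind, rows); m <- nrow(z)
    ins <- sample(1:9, m, replace = TRUE)
    sf("vers_zeiten", list(
      psid = z$psid, vsid = z$vsid, kv_ik = sprintf("10%06d", ins),
      kassenart = c("AOK", "BKK", "EK", "IKK", "LKK", "AOK", "BKK", "EK", "IKK")[ins],
      quartal = as.character(z$quartal),
      versichertentage = as.character(sample(60:92, m, replace = TRUE)),
      pflegegrad = blank_out(as.character(sample(1:5, m, replace = TRUE)), 0.9),
      zuzahlungsbefreit_kz = sample(c("0", "1"), m, replace = TRUE, prob = c(.9, .1)),
      mitgliedsart = sample(c("M", "F", "R"), m, replace = TRUE),
      beitragsgruppe = sprintf("%04d", sample(1:9999, m, replace = TRUE)),
      meldegrund = sample(c("10", "11", "30"), m, replace = TRUE),
      satzart = "20",
      pruefsumme = sprintf("%05d", sample(1:99999, m, replace = TRUE))))
  })

  vers_wohnort <- st("vers_wohnort", {
    bl <- sprintf("%02d", sample(1:16, n, replace = TRUE))
    kr <- sprintf("%03d", sample(1:440, n, replace = TRUE))
    sf("vers_wohnort", list(
      psid = per$psid, vsid = vsid1,
      gkz = paste0(bl, kr, sprintf("%03d", sample(1:999, n, replace = TRUE))),
      bundesland = bl, kreis = kr,
      plz = sprintf("%05d", sample(1067:99998, n, replace = TRUE)),
      satzart = "30"))
  })

  vers_dmp <- st("vers_dmp", {
    idx <- which(stats::runif(n) < cfg$p_dmp)
    m <- length(idx)
    ein <- rand_day(year, m)
    aus <- fmt_date(iso_date(ein) + sample(30:300, m, replace = TRUE))
    sf("vers_dmp", list(
      psid = per$psid[idx], vsid = vsid1[idx],
      dmp_typ = sample(c("COPD", "DM2", "KHK"), m, replace = TRUE),
      einschreibedatum = ein,
      austrittsdatum = blank_out(aus, 0.8),
      dmp_status = sample(c("A", "P"), m, replace = TRUE, prob = c(.9, .1)),
      pruefsumme = sprintf("%05d", sample(1:99999, m, replace = TRUE))))
  })

  rx <- st("am_rezepte_n", stats::rpois(n, cfg$mean_prescriptions))
  i_rx <- rep(seq_len(n), rx); m_rx <- length(i_rx)
  am_fallnr <- sprintf("AM%d%07d", year, seq_len(m_rx))
  am_rezepte <- st("am_rezepte", {
    sf("am_rezepte", list(
      psid = per$psid[i_rx], vsid = vsid1[i_rx], am_fallnr = am_fallnr,
      pzn = sprintf("%08d", sample(10000000:99999999, m_rx, replace = TRUE)),
      verordnungsdatum = rand_day(year, m_rx),
      menge = as.character(sample(1:3, m_rx, replace = TRUE)), faktor = "1",
      darreichungsform = sample(c("TAB", "KAP", "TRO", "SAL"), m_rx, replace = TRUE),
      packungsgroesse = sample(c("N1", "N2", "N3"), m_rx, replace = TRUE),
      autidem_kz = sample(c("0", "1"), m_rx, replace = TRUE, prob = c(.8, .2)),
      verordnender_lanr = sprintf("L%06d", sample(1:50, m_rx, replace = TRUE)),
      verordnender_fachgruppe = draw_specialty(m_rx, cfg$frac_specialty_mapped),
      verordnender_bsnr = sprintf("B%06d", sample(1:20, m_rx, replace = TRUE)),
      abgabedatum = blank_out(rand_day(year, m_rx), 0.5),
      ddd = as.character(sample(10:90, m_rx, replace = TRUE)),
      normgroesse = sample(c("N1", "N2", "N3"), m_rx, replace = TRUE),
      sonderkennzeichen = blank_out(sample(c("02567024"), m_rx, replace = TRUE), 0.9)))
  })
  am_kosten <- st("am_kosten", {
    ges <- as_num(amount(m_rx, 40))
    sf("am_kosten", list(
      psid = per$psid[i_rx], vsid = vsid1[i_rx], am_fallnr = am_fallnr,
      zuzahlung = sprintf("%.2f", sample(c(5, 10), m_rx, replace = TRUE)),
      gesamtkosten = sprintf("%.2f", ges),
      bruttobetrag = sprintf("%.2f", ges * 1.1),
      festbetrag = blank_out(sprintf("%.2f", ges * 0.9), 0.5),
      apothekenzuschlag = sprintf("%.2f", rep(2.5, m_rx)),
      apotheke_ik = sprintf("30%06d", sample(1:20, m_rx, replace = TRUE)),
      apotheke_plz = sprintf("%05d", sample(1067:99998, m_rx, replace = TRUE)),
      abrechnungsdatum = rand_day(year, m_rx)))
  })

  ## ambulatory general cases
  amb_n <- st("amb_n", stats::rpois(n, cfg$mean_amb_cases))
  i_amb <- rep(seq_len(n), amb_n); m_amb <- length(i_amb)
  amb_fallnr <- sprintf("AB%d%07d", year, seq_len(m_amb))
  amb_q <- st("amb_q", sample(1:4, m_amb, replace = TRUE))
  amb_faelle <- st("amb_faelle", {
    von <- rand_quarter_day(year, amb_q, m_amb)
    von <- blank_out(von, cfg$frac_missing_date)
    bis <- ifelse(is_blank(von), "",
                  fmt_date(iso_date(von) + sample(0:5, m_amb, replace = TRUE)))
    bis <- blank_out(bis, 0.3)
    blut <- stats::runif(m_amb) < 0.05
    sf("amb_faelle", list(
      psid = per$psid[i_amb], vsid = vsid1[i_amb], amb_fallnr = amb_fallnr,
      behandlung_von = von, behandlung_bis = bis, quartal = as.character(amb_q),
      unfall_kz = sample(c("0", "1"), m_amb, replace = TRUE, prob = c(.95, .05)),
      notfall_kz = sample(c("0", "1"), m_amb, replace = TRUE, prob = c(.95, .05)),
      lanr = sprintf("L%06d", sample(1:50, m_amb, replace = TRUE)),
      fachgruppe = draw_specialty(m_amb, cfg$frac_specialty_mapped),
      bsnr = sprintf("B%06d", sample(1:20, m_amb, replace = TRUE)),
      plz_praxis = sprintf("%05d", sample(1067:99998, m_amb, replace = TRUE)),
      praxisart = sample(c("EP", "BAG", "MVZ"), m_amb, replace = TRUE),
      blutreinigung_kz = ifelse(blut, "1", "0"),
      blutreinigung_datum = ifelse(blut, rand_quarter_day(year, amb_q, m_amb), ""),
      blutreinigung_anzahl = ifelse(blut, as.character(sample(1:12, m_amb, replace = TRUE)), ""),
      ueberweiser_lanr = blank_out(sprintf("L%06d", sample(1:50, m_amb, replace = TRUE)), 0.7),
      leistungszeit = blank_out(sprintf("%02d:%02d", sample(8:17, m_amb, replace = TRUE),
                                        sample(0:59, m_amb, replace = TRUE)), 0.5)))
  })
  amb_diagnosen <- st("amb_diagnosen", {
    k <- sample(1:2, m_amb, replace = TRUE)
    j <- rep(seq_len(m_amb), k); m <- length(j)
    code <- paste0(draw_icd(m, cfg$frac_invalid_code),
                   sample(c("", "!", "†", "*"), m, replace = TRUE,
                          prob = c(.7, .1, .1, .1)))
    sf("amb_diagnosen", list(
      psid = per$psid[i_amb][j], vsid = vsid1[i_amb][j], amb_fallnr = amb_fallnr[j],
      icd_code = code,
      qualifizierung = blank_out(sample(c("G", "V", "Z", "A"), m, replace = TRUE,
                                        prob = c(.6, .2, .15, .05)),
                                 cfg$frac_empty_status),
      lokalisation = sample(c("", "L", "R", "B"), m, replace = TRUE, prob = c(.7, .1, .1, .1)),
      abrechnungsquartal = as.character(amb_q[j]), icd_version = "2019"))
  })
  amb_ops <- st("amb_ops", {
    has <- which(stats::runif(m_amb) < 0.3)
    m <- length(has)
    sf("amb_ops", list(
      psid = per$psid[i_amb][has], vsid = vsid1[i_amb][has], amb_fallnr = amb_fallnr[has],
      ops_code = draw_ops(m, cfg$frac_ops_mapped),
      ops_datum = blank_out(rand_quarter_day(year, amb_q[has], m), cfg$frac_missing_date),
      lokalisation = sample(c("", "L", "R", "B"), m, replace = TRUE, prob = c(.7, .1, .1, .1)),
      anzahl = as.character(sample(1:2, m, replace = TRUE)), ops_version = "2019"))
  })
  amb_leistungen <- st("amb_leistungen", {
    sf("amb_leistungen", list(
      psid = per$psid[i_amb], vsid = vsid1[i_amb], amb_fallnr = amb_fallnr,
      uas_ziffer = sample(uas_pool(), m_amb, replace = TRUE),
      datum = blank_out(rand_quarter_day(year, amb_q, m_amb), cfg$frac_missing_date),
      anzahl = as.character(sample(1:3, m_amb, replace = TRUE)),
      bruttobetrag = amount(m_amb, 60),
      punktzahl = as.character(sample(50:900, m_amb, replace = TRUE)),
      eigenanteil = blank_out(amount(m_amb, 10), 0.6),
      abrechnungskz = "0", uas_version = "2019"))
  })

  ## dental cases
  za_n <- st("za_n", stats::rpois(n, cfg$mean_dental_cases))
  i_za <- rep(seq_len(n), za_n); m_za <- length(i_za)
  zahn_fallnr <- sprintf("ZA%d%07d", year, seq_len(m_za))
  za_q <- st("za_q", sample(1:4, m_za, replace = TRUE))
  zahn_faelle <- st("zahn_faelle", {
    tag <- blank_out(rand_quarter_day(year, za_q, m_za), cfg$frac_missing_date)
    sf("zahn_faelle", list(
      psid = per$psid[i_za], vsid = vsid1[i_za], zahn_fallnr = zahn_fallnr,
      behandlungstag = tag,
      behandlungsende = blank_out(tag, 0.5),
      quartal = as.character(za_q),
      behandlungsart = sample(c("RB", "FU", "KFO"), m_za, replace = TRUE),
      zahnarzt_lanr = sprintf("Z%06d", sample(1:30, m_za, replace = TRUE)),
      fallkosten = amount(m_za, 120), laborkosten = blank_out(amount(m_za, 50), 0.5),
      fremdlaborkosten = blank_out(amount(m_za, 30), 0.7),
      versichertenanteil = blank_out(amount(m_za, 40), 0.5),
      abrechnungsdatum = rand_day(year, m_za),
      kzv_nr = sprintf("%02d", sample(1:17, m_za, replace = TRUE))))
  })
  zahn_befunde <- st("zahn_befunde", {
    sf("zahn_befunde", list(
      psid = per$psid[i_za], vsid = vsid1[i_za], zahn_fallnr = zahn_fallnr,
      befund = sample(c("K", "F", "Z", "E", "PK"), m_za, replace = TRUE),
      befundart = sample(c("01", "02"), m_za, replace = TRUE),
      befunddatum = blank_out(rand_quarter_day(year, za_q, m_za), cfg$frac_missing_date),
      zahn = as.character(sample(c(11:18, 21:28, 31:38, 41:48), m_za, replace = TRUE)),
      refart = blank_out(sample(c("1", "2"), m_za, replace = TRUE), 0.8),
      pruefsumme = sprintf("%05d", sample(1:99999, m_za, replace = TRUE))))
  })
  zahn_leistungen <- st("zahn_leistungen", {
    k <- sample(1:2, m_za, replace = TRUE)
    j <- rep(seq_len(m_za), k); m <- length(j)
    sf("zahn_leistungen", list(
      psid = per$psid[i_za][j], vsid = vsid1[i_za][j], zahn_fallnr = zahn_fallnr[j],
      leistungsgruppe = as.character(sample(1:5, m, replace = TRUE)),
      gebnr = sprintf("%03d%s", sample(1:999, m, replace = TRUE),
                      sample(c("", "a", "b"), m, replace = TRUE)),
      datum = blank_out(rand_quarter_day(year, za_q[j], m), cfg$frac_missing_date),
      anzahl = as.character(sample(1:2, m, replace = TRUE)),
      zahn = as.character(sample(c(11:18, 21:28, 31:38, 41:48), m, replace = TRUE)),
      pruefsumme = sprintf("%05d", sample(1:99999, m, replace = TRUE))))
  })

  ## inpatient cases
  kh_n <- st("kh_n", stats::rpois(n, cfg$mean_inpatient_cases))
  i_kh <- rep(seq_len(n), kh_n); m_kh <- length(i_kh)
  kh_fallnr <- sprintf("KH%d%07d", year, seq_len(m_kh))
  kh_adm <- st("kh_adm", iso_date(rand_day(year, m_kh)))
  kh_los <- st("kh_los", sample(1:20, m_kh, replace = TRUE))
  kh_faelle <- st("kh_faelle", {
    gew <- stats::runif(m_kh) < 0.05
    beat <- stats::runif(m_kh) < 0.1
    its <- stats::runif(m_kh) < 0.1
    sf("kh_faelle", list(
      psid = per$psid[i_kh], vsid = vsid1[i_kh], kh_fallnr = kh_fallnr,
      aufnahmedatum = fmt_date(kh_adm),
      entlassungsdatum = fmt_date(kh_adm + kh_los),
      aufnahmegrund = sprintf("%02d", sample(1:7, m_kh, replace = TRUE)),
      aufnahmeanlass = sample(c("E", "N", "V"), m_kh, replace = TRUE),
      entlassungsgrund = sprintf("%02d", sample(1:19, m_kh, replace = TRUE)),
      behandlungsart = blank_out(sample(c("V", "T"), m_kh, replace = TRUE, prob = c(.85, .15)),
                                 cfg$frac_empty_visit_type),
      ik = sprintf("26%07d", sample(1:15, m_kh, replace = TRUE)),
      ik_plz = sprintf("%05d", sample(1067:99998, m_kh, replace = TRUE)),
      traegerart = sample(c("oeff", "frei", "priv"), m_kh, replace = TRUE),
      aufnahmegewicht = ifelse(gew, as.character(sample(500:4500, m_kh, replace = TRUE)), ""),
      beatmungsstunden = ifelse(beat, as.character(sample(1:480, m_kh, replace = TRUE)), ""),
      intensiv_tage = ifelse(its, as.character(sample(1:15, m_kh, replace = TRUE)), ""),
      fa = sprintf("%04d", sample(c(100, 300, 1500, 2300), m_kh, replace = TRUE)),
      aufnfa = sprintf("%04d", sample(c(100, 300, 1500, 2300), m_kh, replace = TRUE)),
      verweildauer = as.character(kh_los),
      aufnahmeuhrzeit = sprintf("%02d:%02d", sample(0:23, m_kh, replace = TRUE),
                                sample(0:59, m_kh, replace = TRUE)),
      entlassungsuhrzeit = sprintf("%02d:%02d", sample(0:23, m_kh, replace = TRUE),
                                   sample(0:59, m_kh, replace = TRUE)),
      ik_abrechnung = sprintf("26%07d", sample(1:15, m_kh, replace = TRUE))))
  })
  kh_khdiag <- st("kh_khdiag", {
    k <- sample(1:3, m_kh, replace = TRUE)
    j <- rep(seq_len(m_kh), k); m <- length(j)
    first <- !duplicated(j)
    code <- paste0(draw_icd(m, cfg$frac_invalid_code),
                   sample(c("", "!", "†", "*"), m, replace = TRUE,
                          prob = c(.8, .07, .07, .06)))
    sf("kh_khdiag", list(
      psid = per$psid[i_kh][j], vsid = vsid1[i_kh][j], kh_fallnr = kh_fallnr[j],
      icd_code = code,
      diagnoseart = ifelse(first, "H", sample(c("N", "A"), m, replace = TRUE, prob = c(.7, .3))),
      lokalisation = sample(c("", "L", "R", "B"), m, replace = TRUE, prob = c(.8, .07, .07, .06)),
      icd_version = "2019"))
  })
  kh_ops <- st("kh_ops", {
    has <- which(stats::runif(m_kh) < 0.5)
    m <- length(has)
    sf("kh_ops", list(
      psid = per$psid[i_kh][has], vsid = vsid1[i_kh][has], kh_fallnr = kh_fallnr[has],
      ops_code = draw_ops(m, cfg$frac_ops_mapped),
      ops_datum = blank_out(fmt_date(kh_adm[has] + sample(0:3, m, replace = TRUE)), 0.1),
      lokalisation = sample(c("", "L", "R", "B"), m, replace = TRUE, prob = c(.7, .1, .1, .1)),
      anzahl = as.character(sample(1:2, m, replace = TRUE)), ops_version = "2019"))
  })
  kh_entgelte <- st("kh_entgelte", {
    sf("kh_entgelte", list(
      psid = per$psid[i_kh], vsid = vsid1[i_kh], kh_fallnr = kh_fallnr,
      entgeltart = sample(c("DRG", "ZUS", "PFL"), m_kh, replace = TRUE),
      betrag = amount(m_kh, 3000),
      entgeltanzahl = as.character(sample(1:3, m_kh, replace = TRUE, prob = c(.8, .15, .05))),
      abrechnungskz = "0"))
  })

  source_dataset(3L, year, list(
    vers_person = vers_person, vers_zeiten = vers_zeiten, vers_wohnort = vers_wohnort,
    vers_dmp = vers_dmp, am_rezepte = am_rezepte, am_kosten = am_kosten,
    amb_faelle = amb_faelle, amb_diagnosen = amb_diagnosen, amb_ops = amb_ops,
    amb_leistungen = amb_leistungen, zahn_faelle = zahn_faelle,
    zahn_befunde = zahn_befunde, zahn_leistungen = zahn_leistungen,
    kh_faelle = kh_faelle, kh_khdiag = kh_khdiag, kh_ops = kh_ops,
    kh_entgelte = kh_entgelte))
}
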