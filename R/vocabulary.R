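#' Load OMOP-style vocabulary tables in the ATHENA export dialect
#'
#' Reads `CONCEPT` and `CONCEPT_RELATIONSHIP` files (tab-delimited, header
#' row) and builds an in-memory vocabulary store. Only "Maps to"
#' relationships are retained; every Maps-to target must exist and be a
#' standard concept. A bundled micro-fixture vocabulary (see
#' [load_vocab_fixture()]) stands in for the full ATHENA download, which is
#' supported as input but never required.
#'
#' @param concept_csv path to the CONCEPT file.
#' @param relationship_csv path to the CONCEPT_RELATIONSHIP file.
#' @return An object of class `vocabulary_store`.
#' @export
load_athena <- function(concept_csv, relationship_csv) {
  con <- utils::read.delim(concept_csv, sep = "\t", quote = "", colClasses = "character",
                           check.names = FALSE, fileEncoding = "UTF-8")
  need <- c("concept_id", "concept_code", "vocabulary_id", "domain_id", "standard_concept")
  miss <- setdiff(need, names(con))
  if (length(miss)) abort("CONCEPT file lacks required column(s): ", paste(miss, collapse = ", "))
  con$concept_id <- as.numeric(con$concept_id)
  if (anyDuplicated(con$concept_id))
    abort("duplicate concept_id in CONCEPT file: ",
          paste(unique(con$concept_id[duplicated(con$concept_id)]), collapse = ", "))
  if (any(con$concept_id == 0))
    abort("concept_id 0 is reserved for 'no matching concept'")
  rel <- utils::read.delim(relationship_csv, sep = "\t", quote = "", colClasses = "character",
                           check.names = FALSE, fileEncoding = "UTF-8")
  need_rel <- c("concept_id_1", "concept_id_2", "relationship_id")
  miss <- setdiff(need_rel, names(rel))
  if (length(miss))
    abort("CONCEPT_RELATIONSHIP file lacks required column(s): ", paste(miss, collapse = ", "))
  rel <- rel[rel$relationship_id == "Maps to", , drop = FALSE]
  maps_to <- data.frame(source_id = as.numeric(rel$concept_id_1),
                        target_id = as.numeric(rel$concept_id_2))
  bad <- !(maps_to$target_id %in% con$concept_id)
  if (any(bad))
    abort("Maps-to target(s) absent from CONCEPT: ",
          paste(unique(maps_to$target_id[bad]), collapse = ", "))
  std <- con$concept_id[con$standard_concept == "S"]
  bad <- !(maps_to$target_id %in% std)
  if (any(bad))
    abort("Maps-to target(s) are not standard concepts: ",
          paste(unique(maps_to$target_id[bad]), collapse = ", "))
  store <- list(
    concepts = con[, c("concept_id", "concept_name", "domain_id", "vocabulary_id",
                       "standard_concept", "concept_code")],
    maps_to = maps_to,
    code_index = stats::setNames(con$concept_id, paste(con$vocabulary_id, con$concept_code, sep = "|")),
    local = data.frame(context = character(0), code = character(0),
                       concept_id = numeric(0), stringsAsFactors = FALSE)
  )
  class(store) <- "vocabulary_store"
  store
}

#' @export
print.vocabulary_store <- function(x, ...) {
  cat(sprintf("<vocabulary_store: %d concepts, %d Maps-to rows, %d local mappings>\n",
              nrow(x$concepts), nrow(x$maps_to), nrow(x$local)))
  invisible(x)
}

#' Register local (Usagi-export style) concept mappings
#'
#' Local codes without a published vocabulary (specialist categories, disease
#' management programs, dental service groups, visit/status categories,
#' insurance claims) are mapped by hand in a Usagi-style CSV with columns
#' `source_code`, `source_description`, `source_context`, `target_concept_id`,
#' `mapping_status`. Only rows with status `APPROVED` are registered; the
#' number of ignored rows is reported via `message()`.
#'
#' @param usagi_csv path to the mapping CSV.
#' @param store a `vocabulary_store`.
#' @param context optional context label overriding the file's
#'   `source_context` column (used for single-context files such as a UAS
#'   tariff mapping).
#' @return The store with the mappings registered.
#' @export
load_local_mappings <- function(usagi_csv, store, context = NULL) {
  m <- read_table_csv(usagi_csv)
  need <- c("source_code", "target_concept_id", "mapping_status")
  miss <- setdiff(need, names(m))
  if (length(miss)) abort("local mapping file lacks column(s): ", paste(miss, collapse = ", "))
  keep <- m$mapping_status == "APPROVED"
  if (any(!keep))
    message(sum(!keep), " local mapping row(s) not APPROVED; ignored")
  m <- m[keep, , drop = FALSE]
  if (nrow(m)) {
    tid <- as.numeric(m$target_concept_id)
    bad <- !(tid %in% store$concepts$concept_id)
    if (any(bad))
      abort("local mapping target concept_id(s) absent from store: ",
            paste(unique(tid[bad]), collapse = ", "))
    ctx <- if (!is.null(context)) rep(context, nrow(m)) else m$source_context
    store$local <- rbind(store$local,
                         data.frame(context = ctx, code = m$source_code,
                                    concept_id = tid, stringsAsFactors = FALSE))
  }
  store
}

#' Load the bundled micro-fixture vocabulary
#'
#' A pinned, desk-scale stand-in for the ATHENA vocabulary (local concepts in
#' the 2,000,000,000+ custom range following OHDSI convention), covering
#' ICD-10-GM to SNOMED maps across all four event domains, OPS maps across
#' Procedure/Drug/Measurement/Observation, visit and condition-status
#' concepts, and the local concepts the ETL emits.
#'
#' @param local also register the bundled Usagi-style local mappings
#'   (default `TRUE`).
#' @return A `vocabulary_store`.
#' @export
load_vocab_fixture <- function(local = TRUE) {
  dir <- system.file("extdata", "vocab", package = "hdlomop")
  store <- load_athena(file.path(dir, "CONCEPT.csv"),
                       file.path(dir, "CONCEPT_RELATIONSHIP.csv"))
  if (local)
    store <- suppressMessages(
      load_local_mappings(file.path(dir, "local_mappings.csv"), store))
  store
}

#' Normalise an ICD-10-GM code
#'
#' ICD-10-GM codes may carry trailing special characters (dagger, asterisk,
#' exclamation mark marking primary/secondary/optional codes) and a
#' localisation letter (L/R/B). The OMOP vocabulary maps the bare code, so
#' the modifiers are split off and retained separately; the original string
#' is always `paste0(clean, modifiers)`. Idempotent on already-clean codes;
#' strings that do not look like an ICD code pass through unchanged.
#'
#' @param code character vector of raw codes.
#' @return data.frame with columns `clean` and `modifiers`.
#' @examples
#' normalize_icd_gm("U07.1!")   # clean "U07.1", modifiers "!"
#' normalize_icd_gm("M05.44†")
#' @export
normalize_icd_gm <- function(code) {
  code <- as.character(code)
  m <- regmatches(code, regexec("^([A-Z][0-9]{2}(?:\\.[0-9]{1,2})?)(.*)$", code))
  clean <- vapply(m, function(g) if (length(g)) g[[2]] else NA_character_, "")
  mods <- vapply(m, function(g) if (length(g)) g[[3]] else NA_character_, "")
  nomatch <- is.na(clean)
  clean[nomatch] <- code[nomatch]
  mods[nomatch] <- ""
  data.frame(clean = clean, modifiers = mods, stringsAsFactors = FALSE)
}

#' Resolve a source code to its standard concepts
#'
#' Returns every "Maps to" target of the code together with its domain; an
#' empty result means the code is unknown or unmapped. PZN codes always
#' return empty: no public PZN-to-RxNorm mapping exists, so drugs keep
#' standard concept 0 with the PZN as source value.
#'
#' @param code a single source code (already normalised for ICD-10-GM).
#' @param vocabulary_id e.g. `"ICD10GM"`, `"OPS"`, `"PZN"`.
#' @param store a `vocabulary_store`.
#' @return data.frame with columns `concept_id`, `domain_id` (zero rows when
#'   unmapped).
#' @export
map_to_standard <- function(code, vocabulary_id, store) {
  out <- map_codes(code, vocabulary_id, store)
  out[!is.na(out$concept_id), c("concept_id", "domain_id")]
}

# Vectorised source-code resolution with Maps-to fan-out.
# Returns one row per (input index, target); concept_id NA when unmapped.
map_codes <- function(codes, vocabulary_id, store) {
  n <- length(codes)
  if (vocabulary_id == "PZN" || n == 0L)
    return(data.frame(idx = integer(0), concept_id = numeric(0),
                      domain_id = character(0), stringsAsFactors = FALSE))
  src_id <- unname(store$code_index[paste(vocabulary_id, codes, sep = "|")])
  hit <- data.frame(idx = seq_len(n), source_id = src_id)
  hit <- hit[!is.na(hit$source_id), , drop = FALSE]
  out <- merge(hit, store$maps_to, by = "source_id")
  if (nrow(out)) {
    dom <- store$concepts$domain_id[match(out$target_id, store$concepts$concept_id)]
    out <- data.frame(idx = out$idx, concept_id = out$target_id, domain_id = dom,
                      stringsAsFactors = FALSE)
    out <- out[order(out$idx, out$concept_id), , drop = FALSE]
  } else {
    out <- data.frame(idx = integer(0), concept_id = numeric(0),
                      domain_id = character(0), stringsAsFactors = FALSE)
  }
  out
}

# Vectorised local-concept resolution: context-scoped code -> concept_id (0 if absent)
resolve_local <- function(codes, context, store) {
  loc <- store$local[store$local$context == context, , drop = FALSE]
  id <- loc$concept_id[match(as.character(codes), loc$code)]
  ifelse(is.na(id), 0, id)
}

concept_name <- function(id, store) {
  store$concepts$concept_name[match(id, store$concepts$concept_id)]
}
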