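# Small shared helpers: deterministic per-table seeding, CSV dialect, rounding.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
is_blank <- function(x) is.na(x) | !nzchar(as.character(x))

#' Deterministic sub-seed for a named random stream
#'
#' Each generated table draws from its own stream seeded by `(seed, name)`, so
#' adding or reordering tables never perturbs the rows of another table.
#' @noRd
stream_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(seed) %% 2147483647 + h * 2654435) %% 2147483647)
}

with_stream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stream_seed(seed, name))
  force(expr)
}

# Fixed CSV dialect: UTF-8, comma, quoted fields, header row, "" = absent.
read_table_csv <- function(path) {
  utils::read.csv(path, colClasses = "character", check.names = FALSE,
                  fileEncoding = "UTF-8", na.strings = character(0))
}

write_table_csv <- function(df, path) {
  for (nm in names(df)) df[[nm]] <- as.character(df[[nm]])
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = TRUE, na = "")
  invisible(path)
}

#' Round half up (commercial rounding), used for reported percentages
#' @noRd
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

pct <- function(num, den, digits = 1) {
  if (den == 0) return(NA_real_)
  round_half_up(100 * num / den, digits)
}

as_num <- function(x) suppressWarnings(as.numeric(x))
as_int <- function(x) suppressWarnings(as.integer(x))

quarter_start <- function(year, quarter) {
  as.Date(sprintf("%04d-%02d-01", as.integer(year), (as.integer(quarter) - 1L) * 3L + 1L))
}

quarter_end <- function(year, quarter) {
  q <- as.integer(quarter)
  as.Date(sprintf("%04d-%02d-%02d", as.integer(year), q * 3L, c(31L, 30L, 30L, 31L)[q]))
}

#' Parse ISO dates, returning NA (not an error) for blanks
#' @noRd
iso_date <- function(x) {
  x <- as.character(x)
  x[is_blank(x)] <- NA_character_
  as.Date(x, format = "%Y-%m-%d")
}

fmt_date <- function(d) format(d, "%Y-%m-%d")

#' rbind that tolerates all-NA/empty blocks and fills missing columns
#' @noRd
rbind_fill <- function(a, b) {
  if (is.null(b) || nrow(b) == 0) return(a)
  miss <- setdiff(names(a), names(b))
  for (nm in miss) b[[nm]] <- rep(NA, nrow(b))
  rbind(a, b[, names(a), drop = FALSE])
}

abort <- function(..., class = "hdlomop_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
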