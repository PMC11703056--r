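#' Vague calendar dates
#'
#' Claims events are reported at mixed precision: outpatient diagnoses by
#' quarter, inpatient diagnoses by discharge month, prescriptions by day, and
#' most other events only by year. A `vague_date` records the components that
#' are actually known; imputation to a day-precise date is a separate,
#' explicit step (see [impute_date()]).
#'
#' @param year calendar year (integer, required).
#' @param quarter quarter 1-4, or `NA` when unknown.
#' @param month month 1-12, or `NA` when unknown.
#' @param day day of month, or `NA` when unknown (requires `month`).
#'
#' @return An object of class `vague_date`.
#' @examples
#' vague_date(2010, quarter = 2)
#' vague_date(2010, month = 7, day = 15)
#' @export
vague_date <- function(year, quarter = NA, month = NA, day = NA) {
  year <- as.integer(year); quarter <- as.integer(quarter)
  month <- as.integer(month); day <- as.integer(day)
  if (is.na(year)) abort("vague_date: year is required")
  if (!is.na(quarter) && (quarter < 1L || quarter > 4L))
    abort("vague_date: quarter must be in 1..4, got ", quarter)
  if (!is.na(month) && (month < 1L || month > 12L))
    abort("vague_date: month must be in 1..12, got ", month)
  if (!is.na(day) && is.na(month))
    abort("vague_date: day given without month")
  if (!is.na(day) && (day < 1L || day > 31L))
    abort("vague_date: day must be in 1..31, got ", day)
  if (!is.na(quarter) && !is.na(month) && ((month - 1L) %/% 3L + 1L) != quarter)
    abort("vague_date: month ", month, " contradicts quarter ", quarter)
  structure(list(year = year, quarter = quarter, month = month, day = day),
            class = "vague_date")
}

#' @export
print.vague_date <- function(x, ...) {
  parts <- c(sprintf("year=%d", x$year),
             if (!is.na(x$quarter)) sprintf("Q%d", x$quarter),
             if (!is.na(x$month)) sprintf("month=%d", x$month),
             if (!is.na(x$day)) sprintf("day=%d", x$day))
  cat("<vague_date ", paste(parts, collapse = " "), ">\n", sep = "")
  invisible(x)
}

#' @export
format.vague_date <- function(x, ...) {
  if (!is.na(x$day)) sprintf("%04d-%02d-%02d", x$year, x$month, x$day)
  else if (!is.na(x$month)) sprintf("%04d-%02d", x$year, x$month)
  else if (!is.na(x$quarter)) sprintf("%04d-Q%d", x$year, x$quarter)
  else sprintf("%04d", x$year)
}
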