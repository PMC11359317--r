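#' Parse FAERS dates with explicit precision
#'
#' FAERS date fields arrive as `YYYYMMDD`, `YYYYMM` or `YYYY` strings;
#' partially specified and missing dates are common. Instead of discarding
#' them at parse time, each value is kept with an explicit precision so that
#' downstream analyses (e.g. time-to-onset) can decide what is usable.
#'
#' Day-precision values must be valid calendar dates; anything unparseable
#' (wrong length, non-digits, impossible dates such as `"20230230"`) becomes
#' `precision = "missing"` rather than an error.
#'
#' @param x Character (or numeric) vector of raw FAERS date values.
#'
#' @return A tibble with columns `date` (class `Date`; partial dates are
#'   anchored at the first day of their period, `NA` when missing) and
#'   `precision` (one of `"day"`, `"month"`, `"year"`, `"missing"`).
#' @examples
#' parse_faers_date(c("20230115", "202301", "2023", "", "20230230"))
#' @export
parse_faers_date <- function(x) {
  x <- stringr::str_trim(as.character(x))
  x[is.na(x)] <- ""
  n <- nchar(x)
  digits <- stringr::str_detect(x, "^[0-9]+$")

  precision <- rep("missing", length(x))
  date <- rep(as.Date(NA), length(x))

  is_day <- digits & n == 8L
  if (any(is_day)) {
    d <- as.Date(x[is_day], format = "%Y%m%d")  # invalid -> NA
    date[is_day] <- d
    precision[is_day][!is.na(d)] <- "day"
  }
  is_month <- digits & n == 6L
  if (any(is_month)) {
    d <- as.Date(paste0(x[is_month], "01"), format = "%Y%m%d")
    date[is_month] <- d
    precision[is_month][!is.na(d)] <- "month"
  }
  is_year <- digits & n == 4L
  if (any(is_year)) {
    d <- as.Date(paste0(x[is_year], "0101"), format = "%Y%m%d")
    date[is_year] <- d
    precision[is_year][!is.na(d)] <- "year"
  }
  date[precision == "missing"] <- NA
  tibble(date = date, precision = precision)
}

# Render a Date + precision pair back to the FAERS string form.
format_faers_date <- function(date, precision) {
  out <- character(length(date))
  day <- !is.na(date) & precision == "day"
  mon <- !is.na(date) & precision == "month"
  yr <- !is.na(date) & precision == "year"
  out[day] <- format(date[day], "%Y%m%d")
  out[mon] <- format(date[mon], "%Y%m")
  out[yr] <- format(date[yr], "%Y")
  out
}
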