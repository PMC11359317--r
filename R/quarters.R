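#' Parse FAERS quarter labels
#'
#' A FAERS quarterly packet is identified by a label of the form `"YYYYQn"`
#' (e.g. `"2017Q4"`). `parse_quarter()` splits labels into numeric year and
#' quarter components.
#'
#' @param x Character vector of quarter labels (`"YYYYQn"`, case-insensitive).
#'
#' @return A tibble with columns `label`, `year`, `quarter`.
#' @examples
#' parse_quarter(c("2017Q4", "2024q1"))
#' @export
parse_quarter <- function(x) {
  m <- stringr::str_match(stringr::str_to_upper(stringr::str_trim(x)),
                          "^([0-9]{4})Q([1-4])$")
  bad <- is.na(m[, 1]) & !is.na(x)
  if (any(bad)) {
    pv_abort(
      paste0("Invalid quarter label(s): ",
             paste(unique(x[bad]), collapse = ", "),
             ". Expected \"YYYYQn\" with n in 1..4."),
      class = "faerspv_error_quarter"
    )
  }
  tibble(
    label = m[, 1],
    year = as.integer(m[, 2]),
    quarter = as.integer(m[, 3])
  )
}

#' Enumerate an inclusive range of FAERS quarters
#'
#' Expands a start and end quarter into the contiguous, ascending sequence of
#' quarterly packets between them (both endpoints included). The span used
#' throughout the package examples, 2017Q4 to 2024Q1, covers 26 quarters.
#'
#' @param start,end Quarter labels (`"YYYYQn"`), with `start <= end`.
#'
#' @return A tibble with one row per quarter: `label`, `year`, `quarter`,
#'   ordered ascending.
#' @examples
#' faers_quarters("2017Q4", "2024Q1") # 26 rows
#' @export
faers_quarters <- function(start, end) {
  s <- parse_quarter(start)
  e <- parse_quarter(end)
  stopifnot(nrow(s) == 1, nrow(e) == 1)
  s_idx <- s$year * 4L + (s$quarter - 1L)
  e_idx <- e$year * 4L + (e$quarter - 1L)
  if (s_idx > e_idx) {
    pv_abort(
      sprintf("Quarter range start (%s) is after end (%s).", s$label, e$label),
      class = "faerspv_error_quarter_order"
    )
  }
  idx <- seq(s_idx, e_idx)
  tibble(
    year = idx %/% 4L,
    quarter = idx %% 4L + 1L
  ) |>
    mutate(label = sprintf("%04dQ%d", .data$year, .data$quarter),
           .before = 1L)
}

# "2017Q4" -> "17Q4" as used in FAERS file names (DEMO17Q4.txt)
quarter_file_tag <- function(label) {
  q <- parse_quarter(label)
  sprintf("%02dQ%d", q$year %% 100L, q$quarter)
}
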