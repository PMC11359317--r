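#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom generics tidy glance
NULL

# Normalize a drug or term string for matching: upper case, trim, collapse
# internal whitespace. All name matching in the package goes through this so
# matching stays deterministic and auditable.
norm_string <- function(x) {
  stringr::str_squish(stringr::str_to_upper(x))
}

#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

pv_abort <- function(message, class, ...) {
  abort(message, class = c(class, "faerspv_error"), ...)
}
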