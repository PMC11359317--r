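#' Time from therapy start to adverse-event onset
#'
#' Onset is the interval in whole days between the therapy start date
#' (`START_DT`) and the event date (`EVENT_DT`). A pair is usable only when
#' both dates carry day precision and the event does not precede the start;
#' otherwise the pair is excluded with an explicit reason rather than an
#' error: `"missing"` (either date absent), `"partial"` (either date has
#' only month or year precision) or `"negative"` (event before start —
#' incorrect data). Retained pairs have `status = "retained"`.
#'
#' @param start_date,event_date `Date` vectors.
#' @param start_precision,event_precision Precision strings from
#'   [parse_faers_date()].
#' @return A tibble with columns `days` (integer, `NA` when excluded) and
#'   `status` (`"retained"`, `"missing"`, `"partial"`, `"negative"`).
#' @examples
#' time_to_onset(as.Date("2023-01-01"), "day", as.Date("2023-01-15"), "day")
#' @export
time_to_onset <- function(start_date, start_precision,
                          event_date, event_precision) {
  n <- max(length(start_date), length(event_date))
  start_precision <- rep_len(start_precision, n)
  event_precision <- rep_len(event_precision, n)
  start_date <- rep_len(start_date, n)
  event_date <- rep_len(event_date, n)

  status <- dplyr::case_when(
    start_precision == "missing" | event_precision == "missing" ~ "missing",
    start_precision != "day" | event_precision != "day" ~ "partial",
    event_date < start_date ~ "negative",
    .default = "retained"
  )
  days <- ifelse(status == "retained",
                 as.integer(event_date - start_date), NA_integer_)
  tibble(days = as.integer(days), status = status)
}

#' Per-case onset intervals for a product cohort
#'
#' For each case attributed to a product, anchors onset at the earliest
#' primary-suspect therapy start for that product's exposures (the infusion
#' date) and computes [time_to_onset()] against the case's event date.
#'
#' @param data A deduplicated `faers_data`.
#' @param product_cases Tibble `product`, `case_id`.
#' @return A tibble `product`, `case_id`, `days`, `status`.
#' @export
case_onset <- function(data, product_cases) {
  starts <- data$exposures |>
    dplyr::filter(.data$role == "PS") |>
    dplyr::semi_join(product_cases, by = "case_id") |>
    dplyr::inner_join(product_cases, by = "case_id",
                      relationship = "many-to-many") |>
    dplyr::group_by(.data$product, .data$case_id) |>
    dplyr::arrange(.data$start_date_precision != "day",
                   .data$start_date, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::select("product", "case_id", "start_date", "start_date_precision")
  joined <- starts |>
    dplyr::inner_join(
      dplyr::select(data$cases, "case_id", "event_date", "event_date_precision"),
      by = "case_id")
  tto <- time_to_onset(joined$start_date, joined$start_date_precision,
                       joined$event_date, joined$event_date_precision)
  dplyr::bind_cols(dplyr::select(joined, "product", "case_id"), tto)
}

#' Bin onset days into post-infusion windows
#'
#' Default edges 7, 30, 60 give the windows 0-7, 8-30, 31-60 and >60 days.
#' Edges are upper-inclusive (day 7 falls in "0-7", honouring "within 7
#' days"). Fractions are over the non-missing input; empty input yields
#' all-zero counts.
#'
#' @param days Integer vector of onset days (`NA`s are dropped).
#' @param edges Strictly increasing positive cut points.
#' @return A tibble `bin`, `n`, `fraction` with one row per window, in
#'   order.
#' @examples
#' onset_binning(c(0, 7, 8, 45, 61))
#' @export
onset_binning <- function(days, edges = c(7, 30, 60)) {
  if (any(diff(edges) <= 0) || any(edges < 0)) {
    pv_abort("Bin edges must be strictly increasing and non-negative.",
             class = "faerspv_error_config")
  }
  labels <- c(
    paste0("0-", edges[1]),
    if (length(edges) > 1)
      paste0(edges[-length(edges)] + 1, "-", edges[-1]),
    paste0(">", edges[length(edges)])
  )
  days <- days[!is.na(days)]
  idx <- findInterval(days, c(edges + 0.5), left.open = FALSE) + 1L
  counts <- tabulate(idx, nbins = length(labels))
  tibble(
    bin = factor(labels, levels = labels),
    n = counts,
    fraction = if (length(days)) counts / length(days) else rep(0, length(labels))
  )
}

#' Overlap of an adverse event with cytokine release syndrome
#'
#' Among the cases reporting `event_label`, the fraction that also report
#' any of the CRS labels (by default the grouped "Cytokine release
#' syndrome" composite covering cytokine release syndrome and cytokine
#' storm).
#'
#' @param universe Case-by-event incidence tibble (`case_id`,
#'   `event_label`).
#' @param event_label Target event label (vectorized: give several to get
#'   one row each).
#' @param crs_labels Character vector of labels counted as CRS.
#' @return A tibble `event_label`, `n_event`, `n_with_crs`, `rate`
#'   (`rate = NA` with a message when no case reports the event).
#' @export
crs_overlap <- function(universe, event_label,
                        crs_labels = "Cytokine release syndrome") {
  crs_ids <- unique(universe$case_id[universe$event_label %in% crs_labels])
  purrr::map(event_label, function(ev) {
    ids <- unique(universe$case_id[universe$event_label == ev])
    n_event <- length(ids)
    n_with <- sum(ids %in% crs_ids)
    if (n_event == 0) {
      inform(sprintf("No case reports '%s'; overlap rate undefined.", ev))
    }
    tibble(event_label = ev, n_event = n_event, n_with_crs = n_with,
           rate = if (n_event) n_with / n_event else NA_real_)
  }) |>
    dplyr::bind_rows()
}

#' System-organ-class distribution of positive signals
#'
#' Per product, the share of its positive signals falling in each SOC
#' (shares sum to 1 within each product with at least one positive signal;
#' products with none are omitted with a message). With
#' `denominator = "reports"` the shares are instead weighted by report
#' counts (`n`) of positive signals.
#'
#' @param screen A `pv_screen` result from [screen_signals()].
#' @param soc_map Tibble `event_label`, `soc` mapping every screened label;
#'   unmapped labels among positive signals are a configuration error. Not
#'   needed if the screen already carries a `soc` column.
#' @param denominator `"signals"` (default) or `"reports"`.
#' @return A tibble `product`, `soc`, `n`, `share`.
#' @export
soc_signal_distribution <- function(screen, soc_map = NULL,
                                    denominator = c("signals", "reports")) {
  denominator <- rlang::arg_match(denominator)
  df <- tidy(screen) |> dplyr::filter(.data$is_signal)
  if (!"soc" %in% names(df)) {
    if (is.null(soc_map)) {
      pv_abort("Provide `soc_map` or screen with `soc_map =` set.",
               class = "faerspv_error_config")
    }
    df <- dplyr::left_join(df, dplyr::distinct(soc_map),
                           by = c(event = "event_label"))
  }
  unmapped <- unique(df$event[is.na(df$soc)])
  if (length(unmapped)) {
    pv_abort(paste0("Event label(s) with no SOC mapping: ",
                    paste(unmapped, collapse = ", ")),
             class = "faerspv_error_config")
  }
  dropped <- setdiff(unique(tidy(screen)$product), unique(df$product))
  if (length(dropped)) {
    inform(paste0("Product(s) with zero positive signals omitted: ",
                  paste(dropped, collapse = ", ")))
  }
  df |>
    dplyr::group_by(.data$product, .data$soc) |>
    dplyr::summarise(n = if (denominator == "signals") dplyr::n() else sum(.data$n),
                     .groups = "drop_last") |>
    mutate(share = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}

# Default country -> region lookup shipped with the package.
default_region_map <- function() {
  readr::read_csv(system.file("extdata", "region_map.csv", package = "faerspv"),
                  col_types = "cc", progress = FALSE)
}

age_bin <- function(age_years) {
  dplyr::case_when(
    is.na(age_years) ~ "Not specified",
    age_years < 18 ~ "<18",
    age_years < 65 ~ "18-64",
    .default = ">=65"
  )
}

#' Cohort characterization table
#'
#' Per product: counts and percentages over sex, age bins (<18, 18-64,
#' >=65, not specified), reporter occupation, region, indication,
#' seriousness and outcome codes. Within each categorical block except
#' outcomes (a case can carry several outcome codes) the counts sum to the
#' product's case total and the percentages to 100 before rounding.
#'
#' @param data A deduplicated `faers_data`.
#' @param product_cases Tibble `product`, `case_id`.
#' @param region_map Tibble `country`, `region`; defaults to the shipped
#'   lookup (editable, since region assignment is a reporting convention).
#' @return A tibble `product`, `block`, `category`, `n`, `pct`.
#' @export
demographics_table <- function(data, product_cases, region_map = NULL) {
  region_map <- region_map %||% default_region_map()
  cases <- data$cases |>
    dplyr::inner_join(product_cases, by = "case_id",
                      relationship = "many-to-many") |>
    dplyr::left_join(region_map, by = "country") |>
    mutate(
      region = dplyr::coalesce(.data$region, "Not specified/other"),
      age_group = age_bin(.data$age_years),
      sex_group = dplyr::recode(.data$sex, female = "Female", male = "Male",
                                unknown = "Not specified"),
      reporter_group = dplyr::recode(.data$reporter,
                                     health_professional = "Health professional",
                                     consumer = "Consumer",
                                     unknown = "Not specified")
    )
  serious <- case_seriousness(cases$case_id, data$outcomes)
  cases <- dplyr::left_join(cases, serious, by = "case_id") |>
    mutate(severity = ifelse(.data$serious, "Serious", "Non-serious"))

  indi <- data$indications |>
    dplyr::distinct(.data$case_id, .data$indication) |>
    dplyr::inner_join(product_cases, by = "case_id",
                      relationship = "many-to-many")

  block <- function(df, col, block_name) {
    df |>
      dplyr::count(.data$product, category = .data[[col]], name = "n") |>
      mutate(block = block_name)
  }
  blocks <- dplyr::bind_rows(
    block(cases, "sex_group", "Sex"),
    block(cases, "age_group", "Age, years"),
    block(cases, "reporter_group", "Reporter"),
    block(cases, "region", "Reporting region"),
    block(cases, "severity", "AE severity")
  )
  totals <- dplyr::count(cases, .data$product, name = "total")
  blocks <- blocks |>
    dplyr::left_join(totals, by = "product") |>
    mutate(pct = 100 * .data$n / .data$total)

  outcome_block <- data$outcomes |>
    dplyr::distinct(.data$case_id, .data$outcome_code) |>
    dplyr::inner_join(product_cases, by = "case_id",
                      relationship = "many-to-many") |>
    dplyr::count(.data$product, category = .data$outcome_code, name = "n") |>
    mutate(block = "Outcome") |>
    dplyr::left_join(totals, by = "product") |>
    mutate(pct = 100 * .data$n / .data$total)

  indi_block <- indi |>
    dplyr::count(.data$product, category = .data$indication, name = "n") |>
    mutate(block = "Indication") |>
    dplyr::left_join(totals, by = "product") |>
    mutate(pct = 100 * .data$n / .data$total)

  dplyr::bind_rows(blocks, indi_block, outcome_block) |>
    dplyr::select("product", "block", "category", "n", "pct") |>
    dplyr::arrange(.data$product, .data$block, dplyr::desc(.data$n))
}

#' Bar chart of onset-time windows
#'
#' @param bins A tibble from [onset_binning()], optionally with a grouping
#'   column `event_label` or `product`.
#' @return A ggplot object.
#' @export
plot_onset_bins <- function(bins) {
  p <- ggplot2::ggplot(bins, ggplot2::aes(x = .data$bin, y = .data$fraction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Days from infusion to onset", y = "Fraction of cases") +
    ggplot2::theme_minimal()
  if ("event_label" %in% names(bins)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$event_label))
  }
  p
}

#' Bar chart of CRS overlap rates
#'
#' @param overlap A tibble from [crs_overlap()].
#' @return A ggplot object.
#' @export
plot_crs_overlap <- function(overlap) {
  ggplot2::ggplot(overlap,
                  ggplot2::aes(x = stats::reorder(.data$event_label, .data$rate),
                               y = .data$rate)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x),
                                limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Overlap with CRS") +
    ggplot2::theme_minimal()
}

#' Stacked bar chart of SOC shares of positive signals
#'
#' @param soc_dist A tibble from [soc_signal_distribution()].
#' @return A ggplot object.
#' @export
plot_soc_distribution <- function(soc_dist) {
  ggplot2::ggplot(soc_dist, ggplot2::aes(x = .data$product, y = .data$share,
                                         fill = .data$soc)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Share of positive signals", fill = "SOC") +
    ggplot2::theme_minimal()
}
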