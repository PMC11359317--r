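# Disproportionality statistics on the drug-event 2x2 table
#
#               target event   other events
#  target drug       a              b
#  other drugs       c              d
#
# ROR = (a*d)/(b*c) with a log-normal 95% CI; PRR = [a/(a+b)]/[c/(c+d)];
# chi-squared on the 2x2 with optional Yates continuity correction.

check_cells <- function(a, b, c, d) {
  # double precision: margin products overflow 32-bit integers
  cells <- cbind(a = as.numeric(a), b = as.numeric(b),
                 c = as.numeric(c), d = as.numeric(d))
  if (any(is.na(cells))) {
    pv_abort("Contingency cells contain NA.", class = "faerspv_error_validation")
  }
  if (any(cells < 0)) {
    pv_abort("Contingency cells must be non-negative.",
             class = "faerspv_error_validation")
  }
  cells
}

#' Build the 2x2 contingency table for one (product, event) pair
#'
#' Cells count unique deduplicated cases in the analysis universe:
#' `a` = cases on the target product reporting the target event,
#' `b` = product cases with other events only, `c` = comparator cases with
#' the event, `d` = the rest. Each case contributes at most one count to
#' exactly one cell, so the margins are conserved:
#' `a + b` is the product's case total and `a + b + c + d` the universe size.
#'
#' @param universe Tibble of case-by-event incidence with columns `case_id`,
#'   `event_label` (already grouped and deduplicated).
#' @param product_case_ids Character vector of case ids attributed to the
#'   target product (must be non-empty and a subset of the universe).
#' @param event Target event label.
#' @param universe_ids Optional character vector of every case id in the
#'   analysis universe; defaults to the distinct case ids of `universe`.
#'   Supply it when some cases report no screened event.
#' @return A one-row tibble with columns `a`, `b`, `c`, `d`.
#' @export
contingency_table <- function(universe, product_case_ids, event,
                              universe_ids = NULL) {
  universe_ids <- unique(universe_ids %||% universe$case_id)
  if (length(universe_ids) == 0) {
    pv_abort("Empty analysis universe.", class = "faerspv_error_validation")
  }
  product_case_ids <- unique(product_case_ids)
  n_prod <- sum(product_case_ids %in% universe_ids)
  if (n_prod == 0) {
    pv_abort("Product has zero cases in the universe (degenerate margin).",
             class = "faerspv_error_margin")
  }
  event_ids <- unique(universe$case_id[universe$event_label == event])
  a <- sum(event_ids %in% product_case_ids)
  c_ <- length(event_ids) - a
  b <- n_prod - a
  d <- length(universe_ids) - a - b - c_
  tibble(a = a, b = b, c = c_, d = d)
}

#' Reporting odds ratio with log-normal confidence interval
#'
#' `ROR = (a d)/(b c)`, with the two-sided `1 - alpha` interval
#' `exp(log ROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))` where `z` is the exact
#' normal quantile (about 1.959964 at `alpha = 0.05`, not 1.96 rounded).
#' With `correction = "none"` any zero cell is a hard error naming the cell;
#' `correction = "haldane"` adds the Haldane-Anscombe 0.5 to every cell
#' first. Silent corrections are avoided because they would distort ranked
#' RORs.
#'
#' Vectorized over cells: pass equal-length vectors to score many tables at
#' once.
#'
#' @param a,b,c,d Cell counts (non-negative, vectorized).
#' @param alpha Two-sided type-I level for the CI (default 0.05).
#' @param correction `"none"` (default) or `"haldane"`.
#' @return A tibble with columns `ror`, `ci_low`, `ci_high`.
#' @examples
#' ror(10, 90, 100, 9900) # ROR = 11, CI approx (5.56, 21.8)
#' @export
ror <- function(a, b, c, d, alpha = 0.05,
                correction = c("none", "haldane")) {
  correction <- rlang::arg_match(correction)
  cells <- check_cells(a, b, c, d)
  a <- unname(cells[, "a"]); b <- unname(cells[, "b"])
  c <- unname(cells[, "c"]); d <- unname(cells[, "d"])
  if (correction == "none") {
    zero_cell(a, b, c, d)
  } else {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  est <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(1 - alpha / 2)
  tibble(ror = est,
         ci_low = exp(log(est) - z * se),
         ci_high = exp(log(est) + z * se))
}

zero_cell <- function(a, b, c, d) {
  cells <- cbind(a = a, b = b, c = c, d = d)
  zc <- which(cells == 0, arr.ind = TRUE)
  if (nrow(zc)) {
    pv_abort(
      sprintf("Zero cell(s) %s with correction = \"none\"; use \"haldane\".",
              paste(unique(colnames(cells)[zc[, "col"]]), collapse = ", ")),
      class = "faerspv_error_zero_cell"
    )
  }
}

#' Proportional reporting ratio
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`: the proportion of the product's reports
#' that mention the event, relative to the same proportion among comparator
#' reports. Undefined when the comparator never reports the event (`c = 0`).
#' Vectorized over cells.
#'
#' @inheritParams ror
#' @return Numeric vector of PRR values.
#' @examples
#' prr(10, 90, 100, 9900) # 10
#' @export
prr <- function(a, b, c, d) {
  cells <- check_cells(a, b, c, d)
  a <- unname(cells[, "a"]); b <- unname(cells[, "b"])
  c <- unname(cells[, "c"]); d <- unname(cells[, "d"])
  if (any(a + b == 0) || any(c + d == 0)) {
    pv_abort("PRR requires non-empty margins (a+b > 0 and c+d > 0).",
             class = "faerspv_error_margin")
  }
  if (any(c == 0)) {
    pv_abort("PRR undefined when c = 0 (comparator never reports the event).",
             class = "faerspv_error_undefined_prr")
  }
  (a / (a + b)) / (c / (c + d))
}

#' Pearson chi-squared statistic for the 2x2 table
#'
#' Uncorrected: `chi2 = n (ad - bc)^2 / [(a+b)(c+d)(a+c)(b+d)]` with
#' `n = a+b+c+d`. With `yates = TRUE`, `|ad - bc|` is replaced by
#' `max(0, |ad - bc| - n/2)` (continuity correction), which can only lower
#' the statistic. All four margins must be positive. Vectorized over cells.
#'
#' @inheritParams ror
#' @param yates Apply Yates' continuity correction (default `FALSE`).
#' @return Numeric vector of chi-squared values.
#' @examples
#' chi_square(10, 90, 100, 9900)              # approx 74.45
#' chi_square(10, 90, 100, 9900, yates = TRUE) # approx 66.33
#' @export
chi_square <- function(a, b, c, d, yates = FALSE) {
  cells <- check_cells(a, b, c, d)
  a <- unname(cells[, "a"]); b <- unname(cells[, "b"])
  c <- unname(cells[, "c"]); d <- unname(cells[, "d"])
  n <- a + b + c + d
  margins <- cbind(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) {
    pv_abort("Chi-squared undefined with a zero margin.",
             class = "faerspv_error_margin")
  }
  dev <- abs(a * d - b * c)
  if (yates) dev <- pmax(0, dev - n / 2)
  n * dev^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

#' Signal criteria (combined ROR / MHRA rule)
#'
#' The default thresholds flag a (product, event) pair as a positive signal
#' when the report count is at least 3, the lower 95% confidence limit of
#' the ROR exceeds 1, PRR exceeds 2 and chi-squared exceeds 4. All
#' comparisons except the count are strict.
#'
#' @param min_n Minimum report count (inclusive; default 3).
#' @param ror_ci_low_gt ROR CI lower-limit threshold (strict; default 1).
#' @param prr_gt PRR threshold (strict; default 2).
#' @param chi2_gt Chi-squared threshold (strict; default 4).
#' @return A `signal_criteria` list.
#' @export
signal_criteria <- function(min_n = 3, ror_ci_low_gt = 1, prr_gt = 2,
                            chi2_gt = 4) {
  vals <- c(min_n = min_n, ror_ci_low_gt = ror_ci_low_gt,
            prr_gt = prr_gt, chi2_gt = chi2_gt)
  if (any(vals <= 0)) {
    pv_abort("All signal-criteria thresholds must be positive.",
             class = "faerspv_error_config")
  }
  structure(as.list(vals), class = "signal_criteria")
}

#' Evaluate the signal rule on computed statistics
#'
#' `TRUE` iff `n >= min_n` and `ci_low > ror_ci_low_gt` and `prr > prr_gt`
#' and `chi2 > chi2_gt`. Vectorized; `NA` statistics yield `FALSE` (a pair
#' whose statistics cannot be computed is never flagged).
#'
#' @param n Report count (the `a` cell).
#' @param ci_low Lower 95% confidence limit of the ROR.
#' @param prr Proportional reporting ratio.
#' @param chi2 Chi-squared statistic.
#' @param criteria A [signal_criteria()] object.
#' @return Logical vector.
#' @export
evaluate_signal <- function(n, ci_low, prr, chi2,
                            criteria = signal_criteria()) {
  stopifnot(inherits(criteria, "signal_criteria"))
  out <- n >= criteria$min_n &
    ci_low > criteria$ror_ci_low_gt &
    prr > criteria$prr_gt &
    chi2 > criteria$chi2_gt
  out & !is.na(out)
}

#' Screen every (product, event) pair for disproportionality
#'
#' Builds the 2x2 table for each product against each event label with at
#' least one co-report, computes ROR with 95% CI, PRR and chi-squared, and
#' applies the signal criteria. Pairs whose statistics are undefined (zero
#' cell with `correction = "none"`, or `c = 0` for PRR) are retained with a
#' `status` note and `NA` statistics, never silently dropped. Within each
#' product, rows are ordered by descending ROR (ties broken by event label);
#' rows failing the criteria are kept with `is_signal = FALSE`.
#'
#' @param universe Case-by-event incidence tibble (`case_id`, `event_label`),
#'   deduplicated and term-grouped.
#' @param product_cases Tibble with columns `product`, `case_id` from
#'   [filter_primary_suspect()].
#' @param criteria A [signal_criteria()] object.
#' @param comparator `"full"` (default): the background for each product is
#'   every other report in the ingested universe. `"within-class"`: the
#'   background is restricted to the other screened products' cases
#'   (sensitivity analysis).
#' @param correction Zero-cell handling for the ROR, `"none"` or
#'   `"haldane"`; see [ror()].
#' @param yates Use Yates-corrected chi-squared (default `FALSE`, the
#'   classic uncorrected statistic of the PRR criterion).
#' @param universe_ids Optional vector of all case ids in the universe (for
#'   cases reporting no screened event).
#' @param soc_map Optional tibble `event_label`, `soc` carried through to
#'   the output.
#' @return A `pv_screen` tibble: `product`, `event`, `a`, `b`, `c`, `d`,
#'   `n`, `ror`, `ci_low`, `ci_high`, `prr`, `chi2`, `is_signal`, `status`
#'   (plus `soc` when `soc_map` is given).
#' @export
screen_signals <- function(universe, product_cases,
                           criteria = signal_criteria(),
                           comparator = c("full", "within-class"),
                           correction = c("none", "haldane"),
                           yates = FALSE,
                           universe_ids = NULL, soc_map = NULL) {
  comparator <- rlang::arg_match(comparator)
  correction <- rlang::arg_match(correction)
  universe_ids <- unique(universe_ids %||% universe$case_id)
  if (length(universe_ids) == 0) {
    pv_abort("Empty analysis universe.", class = "faerspv_error_validation")
  }
  if (comparator == "within-class") {
    universe_ids <- intersect(universe_ids, unique(product_cases$case_id))
    universe <- dplyr::filter(universe, .data$case_id %in% universe_ids)
  }
  universe <- dplyr::distinct(universe, .data$case_id, .data$event_label) |>
    dplyr::filter(.data$case_id %in% universe_ids)
  product_cases <- dplyr::distinct(product_cases, .data$product, .data$case_id) |>
    dplyr::filter(.data$case_id %in% universe_ids)

  n_universe <- length(universe_ids)
  prod_totals <- dplyr::count(product_cases, .data$product, name = "n_prod")
  event_totals <- dplyr::count(universe, .data$event_label, name = "n_event")

  cells <- universe |>
    dplyr::inner_join(product_cases, by = "case_id",
                      relationship = "many-to-many") |>
    dplyr::count(.data$product, .data$event_label, name = "a") |>
    dplyr::left_join(prod_totals, by = "product") |>
    dplyr::left_join(event_totals, by = "event_label") |>
    mutate(b = .data$n_prod - .data$a,
           c = .data$n_event - .data$a,
           d = n_universe - .data$a - .data$b - .data$c) |>
    dplyr::select("product", event = "event_label", "a", "b", "c", "d")

  out <- score_pairs(cells, criteria, correction, yates)
  if (!is.null(soc_map)) {
    out <- dplyr::left_join(out, dplyr::distinct(soc_map), by = c(event = "event_label")) |>
      dplyr::relocate("soc", .after = "event")
  }
  out <- out |>
    dplyr::group_by(.data$product) |>
    dplyr::arrange(dplyr::desc(.data$ror), .data$event, .by_group = TRUE) |>
    dplyr::ungroup()
  attr(out, "criteria") <- criteria
  attr(out, "comparator") <- comparator
  attr(out, "correction") <- correction
  attr(out, "n_universe") <- n_universe
  class(out) <- c("pv_screen", class(out))
  out
}

# Score a tibble of (product, event, a, b, c, d) rows, tolerating undefined
# statistics row-wise. The same ror()/prr()/chi_square() code path is used;
# rows it cannot handle get NA + a status note.
score_pairs <- function(cells, criteria, correction, yates) {
  with_cells <- function(f) {
    purrr::pmap(cells[c("a", "b", "c", "d")], function(a, b, c, d) {
      tryCatch(f(a, b, c, d), error = function(e) NULL)
    })
  }
  ror_res <- with_cells(function(a, b, c, d) ror(a, b, c, d, correction = correction))
  prr_res <- with_cells(function(a, b, c, d) prr(a, b, c, d))
  chi_res <- with_cells(function(a, b, c, d) chi_square(a, b, c, d, yates = yates))
  pull_num <- function(lst, field = NULL) {
    purrr::map_dbl(lst, function(x) {
      if (is.null(x)) return(NA_real_)
      if (is.null(field)) as.numeric(x) else x[[field]]
    })
  }
  cells |>
    mutate(
      n = .data$a,
      ror = pull_num(ror_res, "ror"),
      ci_low = pull_num(ror_res, "ci_low"),
      ci_high = pull_num(ror_res, "ci_high"),
      prr = pull_num(prr_res),
      chi2 = pull_num(chi_res),
      is_signal = evaluate_signal(.data$n, .data$ci_low, .data$prr,
                                  .data$chi2, criteria),
      status = dplyr::case_when(
        is.na(.data$ror) & is.na(.data$prr) ~ "undefined",
        is.na(.data$ror) ~ "zero-cell",
        is.na(.data$prr) ~ "prr-undefined",
        .default = "ok"
      )
    )
}

#' @export
print.pv_screen <- function(x, ...) {
  crit <- attr(x, "criteria")
  cat(sprintf(
    "<pv_screen> %d product-event pair(s), %d signal(s); comparator = %s\n",
    nrow(x), sum(x$is_signal), attr(x, "comparator") %||% "full"))
  if (!is.null(crit)) {
    cat(sprintf("criteria: n >= %g, ROR CI low > %g, PRR > %g, chi2 > %g\n",
                crit$min_n, crit$ror_ci_low_gt, crit$prr_gt, crit$chi2_gt))
  }
  NextMethod()
}

#' Tidy a screening result
#'
#' @param x A `pv_screen` object.
#' @param ... Unused.
#' @return A plain tibble of the per-pair statistics.
#' @method tidy pv_screen
#' @export
tidy.pv_screen <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "pv_screen")
  out
}

#' One-row summary of a screening result
#'
#' @param x A `pv_screen` object.
#' @param ... Unused.
#' @return A one-row tibble: pairs screened, signals flagged, products,
#'   events, universe size.
#' @method glance pv_screen
#' @export
glance.pv_screen <- function(x, ...) {
  tibble(
    n_pairs = nrow(x),
    n_signals = sum(x$is_signal),
    n_products = dplyr::n_distinct(x$product),
    n_events = dplyr::n_distinct(x$event),
    n_universe = attr(x, "n_universe") %||% NA_integer_
  )
}

#' Forest-style plot of screened signals
#'
#' ROR point estimates with 95% confidence intervals per event, faceted by
#' product, on a log scale; positive signals are highlighted.
#'
#' @param object A `pv_screen` object.
#' @param top Keep at most this many events per product, by descending ROR.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pv_screen
#' @export
autoplot.pv_screen <- function(object, top = 20, ...) {
  df <- tidy(object) |>
    dplyr::filter(!is.na(.data$ror)) |>
    dplyr::group_by(.data$product) |>
    dplyr::slice_max(.data$ror, n = top, with_ties = FALSE) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ror,
                                   y = stats::reorder(.data$event, .data$ror),
                                   colour = .data$is_signal)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$product), scales = "free_y") +
    ggplot2::labs(x = "Reporting odds ratio (95% CI, log scale)", y = NULL,
                  colour = "Signal") +
    ggplot2::theme_minimal()
}

#' Write a screening result as TSV
#'
#' Two files: a display table with statistics rounded to 2 decimals, and a
#' full-precision machine-readable companion (`*_full.tsv`).
#'
#' @param x A `pv_screen` object.
#' @param path Output path for the display TSV.
#' @return Invisibly, the two paths written.
#' @export
write_signal_tsv <- function(x, path) {
  full <- tidy(x)
  disp <- full |>
    mutate(dplyr::across(c("ror", "ci_low", "ci_high", "prr", "chi2"),
                         ~ round(.x, 2)))
  readr::write_tsv(disp, path)
  full_path <- sub("(\\.tsv)?$", "_full.tsv", path)
  readr::write_tsv(full, full_path)
  invisible(c(path, full_path))
}
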