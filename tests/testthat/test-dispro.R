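test_that("contingency cells match a brute-force hand count", {
  # 6 cases: 2 product+event, 1 product only, 1 event only, 2 neither
  universe <- tibble::tibble(
    case_id = c("1", "2", "3", "4", "5", "6"),
    event_label = c("E", "E", "X", "E", "X", "X")
  )
  ct <- contingency_table(universe, c("1", "2", "3"), "E")
  expect_equal(ct, tibble::tibble(a = 2L, b = 1L, c = 1L, d = 2L))
  expect_equal(ct$a + ct$b + ct$c + ct$d, 6L)

  # event reported by no case
  ct0 <- contingency_table(universe, c("1", "2"), "ZZZ")
  expect_equal(ct0$a, 0L)
  expect_equal(ct0$c, 0L)

  expect_error(contingency_table(universe[0, ], "1", "E"),
               class = "faerspv_error_validation")
  expect_error(contingency_table(universe, "99", "E"),
               class = "faerspv_error_margin")
})

test_that("ROR, PRR and chi-squared match their closed-form oracles", {
  r <- ror(10, 90, 100, 9900)
  expect_equal(r$ror, 11)
  o <- oracle_ror(10, 90, 100, 9900)
  expect_equal(r$ci_low, o$ci_low, tolerance = 1e-12)
  expect_equal(r$ci_high, o$ci_high, tolerance = 1e-12)
  expect_equal(round(r$ci_low, 2), 5.56)
  expect_equal(round(r$ci_high, 1), 21.8)

  expect_equal(prr(10, 90, 100, 9900), 10)
  expect_equal(prr(3, 0, 10, 990), 100)

  expect_equal(chi_square(10, 90, 100, 9900), oracle_chi2(10, 90, 100, 9900))
  expect_equal(round(chi_square(10, 90, 100, 9900), 2), 74.45)
  expect_equal(round(chi_square(10, 90, 100, 9900, yates = TRUE), 1), 66.3)

  # symmetric table: ROR exactly 1, CI straddles it
  sym <- ror(10, 10, 10, 10)
  expect_equal(sym$ror, 1)
  expect_lt(sym$ci_low, 1)
  expect_gt(sym$ci_high, 1)

  # independence: chi2 exactly zero when ad = bc, PRR exactly 1
  expect_equal(chi_square(5, 10, 50, 100), 0)
  expect_equal(prr(5, 10, 50, 100), 1)
})

test_that("chi-squared agrees with stats::chisq.test as an independent check", {
  tabs <- random_tables(50, seed = 101)
  for (i in seq_len(nrow(tabs))) {
    m <- matrix(c(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i]), 2, byrow = TRUE)
    expect_equal(chi_square(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i]),
                 unname(suppressWarnings(
                   stats::chisq.test(m, correct = FALSE)$statistic)),
                 tolerance = 1e-12)
    expect_equal(chi_square(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i],
                            yates = TRUE),
                 unname(suppressWarnings(
                   stats::chisq.test(m, correct = TRUE)$statistic)),
                 tolerance = 1e-12)
  }
})

test_that("zero cells are hard errors unless Haldane correction is requested", {
  expect_error(ror(3, 0, 10, 990), class = "faerspv_error_zero_cell")
  expect_error(ror(0, 3, 10, 990), class = "faerspv_error_zero_cell")
  h <- ror(3, 0, 10, 990, correction = "haldane")
  o <- oracle_ror(3.5, 0.5, 10.5, 990.5)
  expect_equal(h$ror, o$ror)
  expect_equal(h$ci_low, o$ci_low)
  expect_equal(h$ci_high, o$ci_high)
  expect_error(prr(3, 1, 0, 990), class = "faerspv_error_undefined_prr")
  expect_error(chi_square(0, 0, 5, 5), class = "faerspv_error_margin")
})

test_that("sign equivalence: ror > 1 iff prr > 1 iff ad > bc (property)", {
  tabs <- random_tables(1000, seed = 7)
  r <- ror(tabs$a, tabs$b, tabs$c, tabs$d)$ror
  p <- prr(tabs$a, tabs$b, tabs$c, tabs$d)
  ad_gt_bc <- tabs$a * tabs$d > tabs$b * tabs$c
  expect_equal(r > 1, ad_gt_bc)
  expect_equal(p > 1, ad_gt_bc)
})

test_that("Yates correction never increases the statistic (property)", {
  tabs <- random_tables(500, seed = 8)
  expect_true(all(chi_square(tabs$a, tabs$b, tabs$c, tabs$d, yates = TRUE) <=
                    chi_square(tabs$a, tabs$b, tabs$c, tabs$d) + 1e-12))
})

test_that("signal rule matches its boundary definition", {
  crit <- signal_criteria()
  expect_false(evaluate_signal(2, 5, 10, 50, crit))      # n below 3
  expect_true(evaluate_signal(3, 1.01, 2.1, 4.1, crit))  # just over each
  expect_false(evaluate_signal(3, 1.0, 2.1, 4.1, crit))  # strict > on CI
  expect_false(evaluate_signal(3, 1.01, 2.0, 4.1, crit)) # strict > on PRR
  expect_false(evaluate_signal(3, 1.01, 2.1, 4.0, crit)) # strict > on chi2
  expect_true(evaluate_signal(3, 1.01, 2.1, 4.1, crit))
  expect_false(evaluate_signal(3, NA, 2.1, 4.1, crit))   # NA never flags
  expect_error(signal_criteria(min_n = 0), class = "faerspv_error_config")
})

test_that("signal rule is monotone in every statistic (property)", {
  crit <- signal_criteria()
  set.seed(9)
  n <- sample(0:10, 2000, replace = TRUE)
  ci_low <- runif(2000, 0, 3)
  p <- runif(2000, 0, 5)
  x2 <- runif(2000, 0, 10)
  base <- evaluate_signal(n, ci_low, p, x2, crit)
  bump <- function(v, i) { v2 <- v; v2[i] <- v2[i] + runif(length(i), 0, 2); v2 }
  i <- seq_len(2000)
  for (variant in list(
    evaluate_signal(n + sample(0:3, 2000, TRUE), ci_low, p, x2, crit),
    evaluate_signal(n, bump(ci_low, i), p, x2, crit),
    evaluate_signal(n, ci_low, bump(p, i), x2, crit),
    evaluate_signal(n, ci_low, p, bump(x2, i), crit)
  )) {
    expect_true(all(variant >= base))  # TRUE never flips to FALSE
  }
})

test_that("screen_all orders by descending ROR and keeps non-signals flagged", {
  tu <- tiny_universe()
  scr <- screen_signals(tu$universe, tu$product_cases,
                        universe_ids = tu$universe_ids)
  # tiny fixture hand numbers for (ACMECEL, CRS)
  row <- dplyr::filter(tidy(scr), product == "ACMECEL",
                       event == "Cytokine release syndrome")
  expect_equal(unlist(row[c("a", "b", "c", "d")], use.names = FALSE),
               c(3L, 1L, 3L, 5L))
  expect_equal(row$ror, 5)
  expect_equal(row$prr, 2)
  expect_equal(row$chi2, 1.5)
  expect_false(row$is_signal)

  # ROR-descending within product, ties broken by event label
  for (p in unique(scr$product)) {
    sub <- dplyr::filter(tidy(scr), product == p)
    expect_true(all(diff(sub$ror) <= 1e-12))
    ties <- split(sub$event, sub$ror)
    expect_true(all(vapply(ties, function(e) !is.unsorted(e), logical(1))))
  }
  # every row has at least one co-report
  expect_true(all(scr$a >= 1))
})

test_that("a strongly planted pair ranks first for its product", {
  sim <- make_fixture("planted-signals")
  inc <- dplyr::rename(sim$universe$case_events, event_label = pt)
  pc <- dplyr::rename(sim$truth$case_products, product = product)
  scr <- screen_signals(inc, pc, universe_ids = sim$universe$cases$case_id)
  top <- tidy(scr) |>
    dplyr::group_by(product) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
  expect_equal(top$event[top$product == "ACMECEL"],
               "Cytokine release syndrome")
  expect_equal(top$event[top$product == "BETACEL"], "Neurotoxicity")
  expect_true(all(top$is_signal))
})

test_that("screening a single-event universe yields one row per product", {
  universe <- tibble::tibble(case_id = as.character(1:10),
                             event_label = "Only event")
  pc <- tibble::tibble(product = c("P1", "P1", "P2"),
                       case_id = c("1", "2", "3"))
  scr <- screen_signals(universe, pc)
  expect_equal(nrow(scr), 2L)
  expect_true(all(scr$a >= 1))
  # PRR undefined pairs are retained with a status, not dropped: here c > 0
  expect_true(all(scr$status %in% c("ok", "zero-cell", "prr-undefined",
                                    "undefined")))
})

test_that("zero-cell pairs are retained with a status note", {
  universe <- tibble::tibble(case_id = c("1", "2", "3", "4"),
                             event_label = c("E", "E", "X", "X"))
  pc <- tibble::tibble(product = "P", case_id = c("1", "2"))
  scr <- screen_signals(universe, pc)  # (P, E): b = 0 and c = 0
  row <- dplyr::filter(tidy(scr), event == "E")
  expect_equal(row$status, "undefined")
  expect_true(is.na(row$ror))
  expect_false(row$is_signal)
  # with Haldane the ROR becomes finite
  scr_h <- screen_signals(universe, pc, correction = "haldane")
  expect_false(is.na(dplyr::filter(tidy(scr_h), event == "E")$ror))
})

test_that("tidy and glance summarise a screen", {
  tu <- tiny_universe()
  scr <- screen_signals(tu$universe, tu$product_cases,
                        universe_ids = tu$universe_ids)
  td <- tidy(scr)
  expect_false(inherits(td, "pv_screen"))
  g <- glance(scr)
  expect_equal(g$n_pairs, nrow(scr))
  expect_equal(g$n_universe, 12L)
  expect_s3_class(autoplot(scr), "ggplot")
})
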