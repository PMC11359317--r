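test_that("time to onset handles every precision/ordering branch", {
  out <- time_to_onset(as.Date("2023-01-01"), "day",
                       as.Date("2023-01-15"), "day")
  expect_equal(out$days, 14L)
  expect_equal(out$status, "retained")

  expect_equal(time_to_onset(as.Date("2023-01-01"), "day",
                             as.Date("2023-01-01"), "day")$days, 0L)

  neg <- time_to_onset(as.Date("2023-02-01"), "day",
                       as.Date("2023-01-15"), "day")
  expect_equal(neg$status, "negative")
  expect_true(is.na(neg$days))

  part <- time_to_onset(as.Date("2023-01-01"), "month",
                        as.Date("2023-01-15"), "day")
  expect_equal(part$status, "partial")

  miss <- time_to_onset(as.Date(NA), "missing", as.Date("2023-01-15"), "day")
  expect_equal(miss$status, "missing")
})

test_that("every exclusion branch fires exactly once on the messy-dates fixture", {
  fx <- make_fixture("messy-dates")
  dd <- dedup_faers(normalize_faers(fx$bundle))
  pc <- filter_primary_suspect(dd$exposures, list(ACMECEL = "ACMECEL"))
  onset <- case_onset(dd, pc)
  expect_equal(sort(onset$status),
               sort(c("retained", "missing", "partial", "negative")))
  expect_equal(onset$days[onset$status == "retained"], 14L)
  # exclusion accounting telescopes to the candidate total
  expect_equal(sum(table(onset$status)), nrow(onset))
  expect_equal(nrow(onset), 4L)
})

test_that("onset binning is upper-inclusive with the stated default windows", {
  b <- onset_binning(c(0, 7))
  expect_equal(b$n[b$bin == "0-7"], 2L)

  expect_equal(onset_binning(61)$n, c(0L, 0L, 0L, 1L))  # ">60"
  expect_equal(onset_binning(60)$n, c(0L, 0L, 1L, 0L))  # boundary stays 31-60

  empty <- onset_binning(integer())
  expect_equal(empty$n, rep(0L, 4))
  expect_equal(empty$fraction, rep(0, 4))

  full <- onset_binning(c(3, 10, 40, 100, 2))
  expect_equal(sum(full$fraction), 1)
  expect_error(onset_binning(1:5, edges = c(10, 5)),
               class = "faerspv_error_config")
})

test_that("CRS overlap reproduces hand counts and edge rates", {
  # 8 crafted cases with the event, 4 of them also reporting CRS
  universe <- dplyr::bind_rows(
    tibble::tibble(case_id = as.character(1:8), event_label = "Hypoxia"),
    tibble::tibble(case_id = as.character(1:4),
                   event_label = "Cytokine release syndrome")
  )
  ov <- crs_overlap(universe, "Hypoxia")
  expect_equal(ov$n_event, 8L)
  expect_equal(ov$n_with_crs, 4L)
  expect_equal(ov$rate, 0.5)

  # no CRS anywhere -> 0; all overlap -> 1
  no_crs <- universe[universe$event_label == "Hypoxia", ]
  expect_equal(crs_overlap(no_crs, "Hypoxia")$rate, 0)
  all_crs <- dplyr::bind_rows(
    no_crs, tibble::tibble(case_id = as.character(1:8),
                           event_label = "Cytokine release syndrome"))
  expect_equal(crs_overlap(all_crs, "Hypoxia")$rate, 1)

  # undefined rate when no case has the event
  expect_message(none <- crs_overlap(no_crs, "Absent event"))
  expect_true(is.na(none$rate))

  # invariant: relabeling non-CRS, non-target events leaves the rate alone
  relabeled <- universe
  relabeled$event_label[relabeled$event_label == "Hypoxia" &
                          relabeled$case_id %in% as.character(5:6)] <- "Hypoxia"
  extra <- dplyr::bind_rows(
    universe, tibble::tibble(case_id = "3", event_label = "Renamed thing"))
  expect_equal(crs_overlap(extra, "Hypoxia")$rate, 0.5)
})

test_that("SOC distribution shares sum to one per product", {
  tu <- tiny_universe()
  scr <- screen_signals(tu$universe, tu$product_cases,
                        universe_ids = tu$universe_ids,
                        soc_map = build_soc_map(test_dict(), test_groups()))
  fake <- tidy(scr)
  # force a known signal pattern: 2 nervous + 2 immune for one product
  fake$is_signal <- FALSE
  fake$is_signal[fake$product == "ACMECEL"] <- TRUE
  fake$soc[fake$product == "ACMECEL"] <-
    c("Nervous system disorders", "Nervous system disorders",
      "Immune system disorders", "Immune system disorders")
  class(fake) <- c("pv_screen", class(fake))
  expect_message(dist <- soc_signal_distribution(fake), "BETACEL")
  expect_equal(sort(dist$share), c(0.5, 0.5))
  expect_equal(sum(dist$share), 1)

  # single-SOC product has share 1
  fake2 <- fake
  fake2$soc[fake2$product == "ACMECEL"] <- "Immune system disorders"
  dist2 <- suppressMessages(soc_signal_distribution(fake2))
  expect_equal(dist2$share, 1)

  # unmapped labels are a configuration error
  fake3 <- fake
  fake3$soc[2] <- NA
  expect_error(soc_signal_distribution(fake3), class = "faerspv_error_config")
})

test_that("demographics blocks count and percentage correctly", {
  tu <- tiny_universe()
  demo <- demographics_table(tu$data, tu$product_cases)
  # ACMECEL ages: 10 (case 1), 30 (case 2), 70 (case 3), NA (case 5)
  ages <- dplyr::filter(demo, product == "ACMECEL", block == "Age, years")
  expect_equal(sum(ages$n), 4L)
  expect_equal(ages$n[match(c("<18", "18-64", ">=65", "Not specified"),
                            ages$category)],
               rep(1L, 4))
  # percentages recompute exactly from counts
  expect_equal(ages$pct, 100 * ages$n / 4)

  # every block except Outcome/Indication sums to the cohort size per product
  for (p in c("ACMECEL", "BETACEL")) {
    tot <- length(tu$product_cases$case_id[tu$product_cases$product == p])
    for (blk in c("Sex", "Age, years", "Reporter", "Reporting region",
                  "AE severity")) {
      sub <- dplyr::filter(demo, product == p, block == blk)
      expect_equal(sum(sub$n), tot)
      expect_equal(sum(sub$pct), 100)
    }
  }

  # outcome code DE counts under both Death code and Serious severity
  sev <- dplyr::filter(demo, product == "ACMECEL", block == "AE severity")
  expect_equal(sev$n[sev$category == "Serious"], 2L)  # cases 1 (HO), 2 (DE)
  outc <- dplyr::filter(demo, product == "ACMECEL", block == "Outcome")
  expect_equal(outc$n[outc$category == "DE"], 1L)
})

test_that("profile plot helpers return ggplot objects", {
  b <- onset_binning(c(1, 5, 12, 70))
  expect_s3_class(plot_onset_bins(b), "ggplot")
  ov <- tibble::tibble(event_label = c("A", "B"), n_event = c(4L, 8L),
                       n_with_crs = c(2L, 6L), rate = c(0.5, 0.75))
  expect_s3_class(plot_crs_overlap(ov), "ggplot")
  sd <- tibble::tibble(product = "P", soc = c("S1", "S2"), n = c(1L, 1L),
                       share = c(0.5, 0.5))
  expect_s3_class(plot_soc_distribution(sd), "ggplot")
})
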