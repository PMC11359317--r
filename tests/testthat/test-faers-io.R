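write_tmp_table <- function(lines) {
  path <- withr::local_tempfile(fileext = ".txt",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("dollar-delimited tables parse against a hand parse", {
  path <- write_tmp_table(c(
    "PRIMARYID$CASEID$FDA_DT$EVENT_DT$SEX$AGE$AGE_COD",
    "101$1$20230101$20230115$F$34$YR",
    "201$2$20230215$202301$M$400$MON",
    "301$3$20230301$$$$"
  ))
  tbl <- read_faers_table(path, "demo")
  expect_equal(nrow(tbl), 3L)
  expect_equal(tbl$PRIMARYID, c("101", "201", "301"))
  expect_equal(tbl$EVENT_DT, c("20230115", "202301", NA))

  cases <- faers_cases(list(demo = tbl))
  expect_equal(cases$fda_date,
               as.Date(c("2023-01-01", "2023-02-15", "2023-03-01")))
  expect_equal(cases$event_date_precision, c("day", "month", "missing"))
  expect_equal(cases$sex, c("female", "male", "unknown"))
  # 400 months / 12 = 33.33 years; missing age stays missing
  expect_equal(cases$age_years, c(34, 400 / 12, NA))
})

test_that("header-only files give zero records; schema errors are raised", {
  empty <- write_tmp_table("PRIMARYID$CASEID$FDA_DT")
  expect_equal(nrow(read_faers_table(empty, "demo")), 0L)

  bad <- write_tmp_table(c("PRIMARYID$CASEID", "1$2"))
  expect_error(read_faers_table(bad, "demo"), class = "faerspv_error_schema")
  expect_error(read_faers_table(tempfile(), "demo"), class = "faerspv_error_io")
})

test_that("unparseable dates degrade to missing precision, never crash", {
  parsed <- parse_faers_date(c("20230115", "202301", "2023", "20230230",
                               "notadate", "", NA))
  expect_equal(parsed$precision,
               c("day", "month", "year", "missing", "missing", "missing",
                 "missing"))
  expect_equal(parsed$date[1], as.Date("2023-01-15"))
  expect_true(all(is.na(parsed$date[4:7])))
})

test_that("age normalization honours unit codes and the plausibility range", {
  demo <- tibble::tibble(
    PRIMARYID = as.character(1:7), CASEID = as.character(1:7),
    FDA_DT = rep("20230101", 7),
    AGE = c("5", "34", "18", "104", "730", "26280", "200"),
    AGE_COD = c("DEC", "YR", "MON", "WK", "DY", "HR", "YR")
  )
  cases <- faers_cases(list(demo = demo))
  expect_equal(cases$age_years,
               c(50, 34, 1.5, 2, 2, 3, NA))  # 200 YR -> out of range
})

test_that("writing and re-reading a bundle reproduces it field-for-field", {
  fx <- make_fixture("tiny-hand-checked")
  dir <- withr::local_tempdir()
  write_faers(fx$bundle, dir, "2023Q1")
  back <- read_faers_quarter(dir, "2023Q1", quiet = TRUE)
  for (kind in c("demo", "drug", "reac", "ther", "outc", "indi")) {
    expect_equal(as.data.frame(back[[kind]]),
                 as.data.frame(fx$bundle[[kind]]), ignore_attr = TRUE)
  }
})

test_that("deduplication keeps latest FDA_DT then highest PRIMARYID and is idempotent", {
  fx <- make_fixture("tiny-hand-checked")
  cases <- faers_cases(fx$bundle)
  dd <- deduplicate_cases(cases)
  expect_setequal(dd$primary_id, fx$expected$kept_primary_ids)
  expect_equal(nrow(dd), length(unique(cases$case_id)))
  # idempotent
  expect_equal(deduplicate_cases(dd), dd)

  # single-version case passes through unchanged
  one <- cases[cases$case_id == "3", ]
  expect_equal(deduplicate_cases(one), one)

  # non-numeric PRIMARYID is only an error when a tiebreak needs it
  tie <- tibble::tibble(primary_id = c("X1", "X2"), case_id = c("9", "9"),
                        fda_date = as.Date(c("2023-01-01", "2023-01-01")))
  expect_error(deduplicate_cases(tie), class = "faerspv_error_validation")
})

test_that("deduplication count equals the number of distinct case ids (property)", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    cases <- tibble::tibble(
      case_id = as.character(sample.int(20, n, replace = TRUE)),
      fda_date = as.Date("2023-01-01") + sample.int(300, n, replace = TRUE)
    )
    cases$primary_id <- as.character(seq_len(n) * 7L)
    dd <- deduplicate_cases(cases)
    expect_equal(nrow(dd), dplyr::n_distinct(cases$case_id))
    expect_equal(deduplicate_cases(dd), dd)
  }
})

test_that("primary-suspect attribution requires a PS role and normalizes names", {
  fx <- make_fixture("tiny-hand-checked")
  dd <- dedup_faers(normalize_faers(fx$bundle))
  pc <- filter_primary_suspect(dd$exposures,
                               list(ACMECEL = "acmecel",
                                    BETACEL = c("betacel", "BETA-CEL")))
  expect_setequal(pc$case_id[pc$product == "ACMECEL"], c("1", "2", "3", "5"))
  expect_setequal(pc$case_id[pc$product == "BETACEL"], c("6", "7"))
  # case 4 has ACMECEL only as SS: excluded
  expect_false("4" %in% pc$case_id)

  # brute-force invariant: every attributed case has a matching PS exposure
  ps <- dd$exposures[dd$exposures$role == "PS", ]
  for (i in seq_len(nrow(pc))) {
    rows <- ps[ps$case_id == pc$case_id[i], ]
    hit <- toupper(trimws(rows$drug_name)) == toupper(pc$product[i]) |
      (!is.na(rows$active_ingredient) &
         toupper(trimws(rows$active_ingredient)) == toupper(pc$product[i]))
    expect_true(any(hit))
  }

  expect_error(filter_primary_suspect(dd$exposures, list(ACMECEL = character())),
               class = "faerspv_error_config")
  empty <- filter_primary_suspect(dd$exposures[0, ], list(A = "x"))
  expect_equal(nrow(empty), 0L)
})

test_that("seriousness follows the outcome-code rule", {
  outc <- tibble::tibble(primary_id = c("1", "2", "3"),
                         case_id = c("1", "2", "3"),
                         outcome_code = c("DE", "OT", "HO"))
  s <- case_seriousness(c("1", "2", "3", "4"), outc)
  expect_equal(s$serious, c(TRUE, FALSE, TRUE, FALSE))
})
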