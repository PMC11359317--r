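# Canned scenarios used by the test-suite and by examples. The
# "tiny-hand-checked" universe is small enough that every downstream number
# (cells, ROR, PRR, chi-squared, onset bins, CRS overlap) is documented with
# hand arithmetic in inst/extdata/tiny_hand_checked_notes.md.

tiny_demo <- function() {
  tibble::tribble(
    ~PRIMARYID, ~CASEID, ~FDA_DT,    ~EVENT_DT,  ~SEX, ~AGE, ~AGE_COD, ~OCCP_COD, ~REPORTER_COUNTRY,
    "101",  "1",  "20230101", "20230215", "F",  "10", "YR", "MD", "US",
    "102",  "1",  "20230301", "20230215", "F",  "10", "YR", "MD", "US",
    "201",  "2",  "20230110", "20230220", "M",  "30", "YR", "MD", "FR",
    "205",  "2",  "20230110", "20230220", "M",  "30", "YR", "MD", "FR",
    "301",  "3",  "20230115", "20230310", "F",  "70", "YR", "PH", "JP",
    "401",  "4",  "20230120", NA,         "M",  "45", "YR", "CN", "US",
    "501",  "5",  "20230125", "20230401", NA,   NA,   NA,   NA,   "DE",
    "601",  "6",  "20230201", "20230301", "F",  "55", "YR", "MD", "US",
    "701",  "7",  "20230205", NA,         "M",  "60", "YR", "MD", "GB",
    "801",  "8",  "20230210", NA,         "F",  "40", "YR", "MD", "US",
    "901",  "9",  "20230215", NA,         "M",  "35", "YR", "CN", "CA",
    "1001", "10", "20230220", NA,         "F",  "50", "YR", "MD", "US",
    "1101", "11", "20230225", NA,         "M",  "65", "YR", "PH", "US",
    "1201", "12", "20230301", NA,         "F",  "25", "YR", "MD", "US"
  )
}

tiny_drug <- function() {
  base <- tibble::tribble(
    ~CASEID, ~DRUG_SEQ, ~ROLE_COD, ~DRUGNAME, ~PROD_AI,
    "1",  "1", "PS", "ACMECEL", "acmecel",
    "2",  "1", "PS", "Acmecel", "ACMECEL",
    "3",  "1", "PS", "ACMECEL", NA,
    "4",  "1", "SS", "ACMECEL", "ACMECEL",   # SS only: not attributed
    "4",  "2", "PS", "OTHER DRUG 1", NA,
    "5",  "1", "PS", "aCmEcEl", NA,          # case noise
    "6",  "1", "PS", "BETACEL", "BETACEL",
    "7",  "1", "PS", "BETACEL", NA,
    "8",  "1", "PS", "OTHER DRUG 2", NA,
    "9",  "1", "PS", "OTHER DRUG 3", NA,
    "10", "1", "PS", "OTHER DRUG 1", NA,
    "11", "1", "PS", "OTHER DRUG 4", NA,
    "12", "1", "PS", "OTHER DRUG 2", NA
  )
  expand_versions(base)
}

tiny_reac <- function() {
  base <- tibble::tribble(
    ~CASEID, ~PT,
    "1",  "Cytokine release syndrome",
    "1",  "Pyrexia",
    "2",  "CYTOKINE RELEASE SYNDROME",   # case noise; maps to same PT
    "3",  "Cytokine storm",              # CRS group member
    "3",  "Intention tremor",            # Tremor group member
    "4",  "Pyrexia",
    "5",  "Hypotension",
    "6",  "Cytokine release syndrome",
    "7",  "Pyrexia",
    "8",  "Cytokine release syndrome",
    "9",  "Pyrexia",
    "10", "Hypotension",
    "10", "Cytokine release syndrome",
    "11", "Pyrexia",
    "11", "Tremor",
    "12", "Pyrexia"
  )
  expand_versions(base)
}

tiny_ther <- function() {
  base <- tibble::tribble(
    ~CASEID, ~DSG_DRUG_SEQ, ~START_DT,
    "1", "1", "20230201",   # event 20230215 -> 14 days
    "2", "1", "20230220",   # event 20230220 -> 0 days
    "3", "1", "20230301",   # event 20230310 -> 9 days
    "5", "1", "202303",     # month precision -> onset excluded (partial)
    "6", "1", "20230201"    # event 20230301 -> 28 days
  )
  expand_versions(base)
}

tiny_outc <- function() {
  base <- tibble::tribble(
    ~CASEID, ~OUTC_COD,
    "1",  "HO",
    "2",  "DE",
    "3",  "OT",
    "6",  "OT",
    "10", "DE"
  )
  expand_versions(base)
}

tiny_indi <- function() {
  base <- tibble::tribble(
    ~CASEID, ~INDI_DRUG_SEQ, ~INDI_PT,
    "1", "1", "B-cell lymphoma",
    "6", "1", "B-cell lymphoma"
  )
  expand_versions(base)
}

# attach child rows to every emitted version of their case
expand_versions <- function(tbl) {
  versions <- tiny_demo() |> dplyr::select("PRIMARYID", "CASEID")
  tbl |>
    dplyr::inner_join(versions, by = "CASEID",
                      relationship = "many-to-many") |>
    dplyr::relocate("PRIMARYID")
}

tiny_bundle <- function() {
  structure(
    list(demo = tiny_demo(), drug = tiny_drug(), reac = tiny_reac(),
         ther = tiny_ther(), outc = tiny_outc(), indi = tiny_indi()),
    class = "faers_bundle", quarter = "2023Q1"
  )
}

messy_dates_bundle <- function() {
  demo <- tibble::tribble(
    ~PRIMARYID, ~CASEID, ~FDA_DT,    ~EVENT_DT,
    "9101", "91", "20230401", "20230115",  # start 20230101 -> 14 d, retained
    "9201", "92", "20230401", NA,          # missing event date
    "9301", "93", "20230401", "202301",    # month precision -> partial
    "9401", "94", "20230401", "20230115"   # start 20230201 -> negative
  )
  drug <- tibble::tribble(
    ~PRIMARYID, ~CASEID, ~DRUG_SEQ, ~ROLE_COD, ~DRUGNAME, ~PROD_AI,
    "9101", "91", "1", "PS", "ACMECEL", NA,
    "9201", "92", "1", "PS", "ACMECEL", NA,
    "9301", "93", "1", "PS", "ACMECEL", NA,
    "9401", "94", "1", "PS", "ACMECEL", NA
  )
  reac <- tibble::tribble(
    ~PRIMARYID, ~CASEID, ~PT,
    "9101", "91", "Pyrexia",
    "9201", "92", "Pyrexia",
    "9301", "93", "Pyrexia",
    "9401", "94", "Pyrexia"
  )
  ther <- tibble::tribble(
    ~PRIMARYID, ~CASEID, ~DSG_DRUG_SEQ, ~START_DT,
    "9101", "91", "1", "20230101",
    "9201", "92", "1", "20230101",
    "9301", "93", "1", "20230101",
    "9401", "94", "1", "20230201"
  )
  structure(
    list(demo = demo, drug = drug, reac = reac, ther = ther,
         outc = empty_faers_table("outc"), indi = empty_faers_table("indi")),
    class = "faers_bundle", quarter = "2023Q2"
  )
}

#' Canned synthetic scenarios
#'
#' Four scenarios used throughout the documentation and tests:
#'
#' * `"tiny-hand-checked"`: a 12-case universe (14 emitted report versions,
#'   two of them superseded duplicates) whose every downstream number is
#'   documented with hand arithmetic in
#'   `inst/extdata/tiny_hand_checked_notes.md`. The returned object carries
#'   the expected values in `$expected`.
#' * `"messy-dates"`: four cases exercising every time-to-onset exclusion
#'   branch exactly once (retained, missing, partial precision, negative
#'   interval).
#' * `"null-universe"`: a 20,000-case draw with six products and no planted
#'   associations, for criteria calibration.
#' * `"planted-signals"`: a 5,000-case draw with two strongly planted
#'   (product, event) pairs for end-to-end recovery checks.
#'
#' @param name Scenario name.
#' @return For the two hand-built scenarios, a list with `bundle` (a
#'   `faers_bundle`) and `expected`; for the simulated ones, the
#'   [synth_faers()] result (bundle, universe, truth, config).
#' @export
make_fixture <- function(name = c("tiny-hand-checked", "null-universe",
                                  "planted-signals", "messy-dates")) {
  name <- rlang::arg_match(name)
  switch(
    name,
    "tiny-hand-checked" = list(
      bundle = tiny_bundle(),
      expected = list(
        kept_primary_ids = c("102", "205", "301", "401", "501", "601",
                             "701", "801", "901", "1001", "1101", "1201"),
        n_cases = 12L,
        product_cases = list(ACMECEL = c("1", "2", "3", "5"),
                             BETACEL = c("6", "7")),
        # (ACMECEL, Cytokine release syndrome): see the notes file
        acmecel_crs = list(a = 3L, b = 1L, c = 3L, d = 5L,
                           ror = 5, prr = 2, chi2 = 1.5),
        hypotension_crs_overlap = 0.5
      )
    ),
    "messy-dates" = list(
      bundle = messy_dates_bundle(),
      expected = list(statuses = c("retained", "missing", "partial",
                                   "negative"),
                      retained_days = 14L)
    ),
    "null-universe" = synth_faers(synth_config(
      n_cases = 20000,
      products = tibble(name = paste0("PRODUCT ", LETTERS[1:6]),
                        prevalence = rep(0.03, 6)),
      seed = 770001
    )),
    "planted-signals" = synth_faers(synth_config(
      n_cases = 5000,
      products = tibble(name = c("ACMECEL", "BETACEL"),
                        prevalence = c(0.08, 0.08)),
      planted = tibble(
        product = c("ACMECEL", "BETACEL"),
        event = c("Cytokine release syndrome", "Neurotoxicity"),
        multiplier = c(25, 25)),
      seed = 424242
    ))
  )
}
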