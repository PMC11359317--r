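# Independent scalar oracles: straight transcriptions of the printed
# formulas, evaluated cell-by-cell at double precision. They deliberately
# share no code with the package's vectorized implementations.

oracle_ror <- function(a, b, c, d, alpha = 0.05) {
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- qnorm(1 - alpha / 2)
  list(ror = or, ci_low = exp(log(or) - z * se), ci_high = exp(log(or) + z * se))
}

oracle_prr <- function(a, b, c, d) {
  (a / (a + b)) / (c / (c + d))
}

oracle_chi2 <- function(a, b, c, d, yates = FALSE) {
  n <- a + b + c + d
  dev <- abs(a * d - b * c)
  if (yates) dev <- max(0, dev - n / 2)
  n * dev^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# random strictly positive 2x2 tables
random_tables <- function(n, seed, max_cell = 500) {
  set.seed(seed)
  # doubles: the scalar oracles must not overflow integer arithmetic
  tibble::tibble(
    a = as.numeric(sample.int(max_cell, n, replace = TRUE)),
    b = as.numeric(sample.int(max_cell, n, replace = TRUE)),
    c = as.numeric(sample.int(max_cell, n, replace = TRUE)),
    d = as.numeric(sample.int(max_cell, n, replace = TRUE))
  )
}

test_dict <- function() {
  read_pt_dictionary(system.file("extdata", "synthetic_meddra_mini.tsv",
                                 package = "faerspv"))
}

test_groups <- function() {
  read_term_groups(system.file("extdata", "term_groups.yaml",
                               package = "faerspv"))
}

# grouped incidence + product attribution for the tiny fixture
tiny_universe <- function() {
  fx <- make_fixture("tiny-hand-checked")
  dd <- dedup_faers(normalize_faers(fx$bundle))
  pc <- filter_primary_suspect(dd$exposures,
                               list(ACMECEL = "acmecel", BETACEL = "betacel"))
  mapped <- normalize_pt(dd$reactions$pt_verbatim, test_dict(), quiet = TRUE)
  case_pts <- dplyr::bind_cols(dplyr::select(dd$reactions, "case_id"), mapped)
  list(
    fixture = fx, data = dd, product_cases = pc,
    universe = group_case_events(case_pts, test_groups()),
    universe_ids = dd$cases$case_id
  )
}
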