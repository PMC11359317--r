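# faerspv

Pharmacovigilance signal detection for FAERS spontaneous-report data, as a
tidyverse-native R package.

Spontaneous-report databases like the FDA Adverse Event Reporting System
(FAERS) have no exposure denominator, so adverse-event risks cannot be
estimated directly. Disproportionality analysis instead asks whether an
event is reported more often for a drug than the rest of the database would
predict. `faerspv` implements that workflow end-to-end for the quarterly
FAERS ASCII packets — built for comparing the toxicity spectra of the six
approved CAR T-cell products (CRS, ICANS, infections, cytopenias,
cardiorespiratory events), but generic over any drug list:

* **Ingestion** of the six `"$"`-delimited quarterly tables (DEMO, DRUG,
  REAC, THER, OUTC, INDI), with lossless typing, partial-date precision
  tracking, and FDA-style case deduplication (latest `FDA_DT`, ties to the
  higher `PRIMARYID`).
* **Primary-suspect attribution** of cases to products via exact normalized
  matching of `DRUGNAME`/`PROD_AI` synonyms (role `PS` only).
* **Term normalization** against a user-supplied PT dictionary
  (MedDRA is licensed and does not ship) plus composite term groups
  (e.g. all tremor variants as one event) with set semantics per case.
* **Disproportionality screening** per (product, event) pair on the 2×2
  table with cells `a, b, c, d`:

  `ROR = ad/bc` with `95% CI = exp(ln ROR ± z·√(1/a+1/b+1/c+1/d))`,
  `PRR = [a/(a+b)]/[c/(c+d)]`,
  `χ² = n(ad−bc)²/[(a+b)(c+d)(a+c)(b+d)]`,

  flagged as a signal when `n ≥ 3`, ROR CI lower limit `> 1`, `PRR > 2`
  and `χ² > 4` all hold, ranked by descending ROR.
* **Profiling**: cohort demographics, time-to-onset with explicit exclusion
  accounting, post-infusion onset windows (0–7, 8–30, 31–60, >60 days),
  CRS overlap rates, SOC distribution of positive signals, with ggplot2
  `autoplot()`/`plot_*()` helpers.
* **A synthetic FAERS emulator** with planted drug–event odds multipliers,
  duplicate case versions and messy dates, so the whole pipeline is
  testable and calibratable without downloading anything.

## Worked example

Generate a synthetic universe with two planted associations, run the full
pipeline, and inspect the screen:

```r
library(faerspv)
library(dplyr)

cfg <- synth_config(
  n_cases = 5000,
  products = tibble(name = c("ACMECEL", "BETACEL"),
                    prevalence = c(0.08, 0.08)),
  planted = tibble(product = c("ACMECEL", "BETACEL"),
                   event = c("Cytokine release syndrome", "Neurotoxicity"),
                   multiplier = c(25, 25)),
  seed = 424242)

res <- run_pipeline(
  file.path(tempdir(), "demo-run"),
  products = list(ACMECEL = "ACMECEL", BETACEL = "BETACEL"),
  dictionary = system.file("extdata", "synthetic_meddra_mini.tsv",
                           package = "faerspv"),
  groups = system.file("extdata", "term_groups.yaml", package = "faerspv"),
  synth = cfg)

glance(res$screen)
#> # A tibble: 1 × 5
#>   n_pairs n_signals n_products n_events n_universe
#>     <int>     <int>      <int>    <int>      <int>
#> 1      42         4          2       21       5000

res$screen |> tidy() |> filter(is_signal) |>
  select(product, event, n, ror, ci_low, ci_high, prr, chi2)
#> # A tibble: 4 × 8
#>   product event                         n   ror ci_low ci_high   prr   chi2
#>   <chr>   <chr>                     <int> <dbl>  <dbl>   <dbl> <dbl>  <dbl>
#> 1 ACMECEL Cytokine release syndrome   138 23.2   17.4    30.8  15.7  829.
#> 2 ACMECEL Tachycardia                  20  2.10   1.29    3.42  2.05   9.31
#> 3 BETACEL Neurotoxicity               119 29.5   21.4    40.9  21.0  838.
#> 4 BETACEL Fungal infection              8  2.41   1.12    5.20  2.38   5.39
```

Both planted pairs (odds multiplier 25) are recovered at the top of their
product's ranking with large RORs and overwhelming χ²; the two small
incidental hits illustrate why the joint rule is read as a screen, not a
verdict. `res$paths` lists the TSV/JSON outputs written (signal table,
demographics, onset bins, CRS overlap, SOC distribution, run manifest).

Single statistics are available directly and vectorized:

```r
ror(10, 90, 100, 9900)
#> # A tibble: 1 × 3
#>     ror ci_low ci_high
#>   <dbl>  <dbl>   <dbl>
#> 1    11   5.56    21.8
```

To analyze real FAERS data, point `run_pipeline()` at a directory of
quarterly packets (`faers_dir`, `start = "2017Q4"`, `end = "2024Q1"`),
supply your PT dictionary TSV, and use the shipped
`inst/extdata/car_t_products.yaml` synonym list (or your own).

## Scope notes

Signal detection on spontaneous reports indicates reporting associations,
not causation or incidence. Bayesian disproportionality (BCPNN/IC,
MGPS/EBGM), multiple-testing adjustment, the full MedDRA hierarchy and
legacy pre-2012 FAERS formats are out of scope. See the methods vignette
(`vignettes/faers-signal-detection.Rmd`) for the model, parameter and
design rationale.
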