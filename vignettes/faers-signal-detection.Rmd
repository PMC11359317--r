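---
title: "Disproportionality signal detection for FAERS spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection for FAERS spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faerspv)
library(dplyr)
```

## The problem

Spontaneous-report databases such as the FDA Adverse Event Reporting System
(FAERS) collect safety reports submitted by clinicians, consumers and
manufacturers. They have no denominator — nobody knows how many patients
took each drug — so adverse-event risks cannot be estimated directly.
Disproportionality analysis sidesteps this by asking whether an event is
reported *more often than expected* for a drug, taking the rest of the
database as the expectation. `faerspv` implements this workflow end-to-end
for the quarterly FAERS ASCII packets, with CAR T-cell immunotherapies as
the motivating use case: six approved products (four targeting CD19, two
targeting BCMA) whose toxicity profiles — cytokine release syndrome (CRS),
immune effector cell-associated neurotoxicity (ICANS), infections,
cytopenias, cardiorespiratory events — clinicians need to compare.

## The statistic

For one (drug, event) pair the deduplicated reports are cross-classified:

|              | target event | other events |
|--------------|--------------|--------------|
| target drug  | a            | b            |
| other drugs  | c            | d            |

The reporting odds ratio is

$$\mathrm{ROR} = \frac{a\,d}{b\,c},\qquad
95\%\ \mathrm{CI} = \exp\!\Big(\ln \mathrm{ROR} \pm z_{0.975}
\sqrt{\tfrac1a+\tfrac1b+\tfrac1c+\tfrac1d}\Big),$$

with $z_{0.975}$ the exact normal quantile (1.959964...), and the
proportional reporting ratio and Pearson statistic are

$$\mathrm{PRR} = \frac{a/(a+b)}{c/(c+d)},\qquad
\chi^2 = \frac{n\,(ad-bc)^2}{(a+b)(c+d)(a+c)(b+d)},\quad n = a+b+c+d.$$

A pair is flagged as a positive signal when **all four** criteria hold:
$a \ge 3$, the lower 95% confidence limit of the ROR exceeds 1,
$\mathrm{PRR} > 2$ and $\chi^2 > 4$. All comparisons except the count are
strict; the rule is monotone in each statistic. The combined rule is
deliberately conservative: on simulated null universes (no planted
association) well under 5% of pairs are flagged, because the four
conditions must hold jointly.

```{r stats}
ror(10, 90, 100, 9900)
prr(10, 90, 100, 9900)
chi_square(10, 90, 100, 9900)
evaluate_signal(n = 10, ci_low = 5.56, prr = 10, chi2 = 74.4)
```

## Ingestion model and its assumptions

FAERS distributes six `"$"`-delimited tables per quarter (DEMO, DRUG, REAC,
THER, OUTC, INDI). The package parses them losslessly — every column as
character, typing deferred to entity accessors — because real packets
contain malformed fields that must degrade gracefully, not crash.

Decisions a reader should know about, made once and applied throughout:

* **Deduplication.** FAERS re-publishes a case each time it is amended.
  Per case identifier we keep the version with the latest `FDA_DT`,
  breaking ties by the numerically larger `PRIMARYID`. Modern FAERS files
  have no ISR field (the legacy report key); `PRIMARYID` is its documented
  successor, so "larger report key" is interpreted as larger `PRIMARYID`.
* **Primary suspect only.** A case counts for a product only if a
  `ROLE_COD = "PS"` exposure matches one of the product's synonyms. Name
  matching is exact on normalized strings (upper-case, trimmed, internal
  whitespace collapsed) — deterministic and auditable; no fuzzy matching.
  A case matching several products is attributed to each: the alternative
  (picking one) would need an arbitrary priority rule and would make
  per-product cohorts depend on unrelated products.
* **Partial dates.** FAERS dates arrive as `YYYYMMDD`, `YYYYMM` or `YYYY`.
  They are retained with an explicit precision (`day`/`month`/`year`/
  `missing`) rather than discarded at parse time; each downstream analysis
  decides what it can use. Time-to-onset requires day precision at both
  ends and excludes — with a reason, not an error — pairs that are
  missing, partial, or negative (event before therapy start). Mid-period
  imputation was considered and rejected as a default: at the week-scale
  resolution of the onset windows (0–7 days) a mid-month guess is wrong by
  more than the window width.
* **Age.** `AGE` is normalized to years via `AGE_COD` (DEC×10, YR×1,
  MON÷12, WK÷52, DY÷365, HR÷8760); results outside 0–120 years become
  missing rather than propagating impossible values.
* **Seriousness.** A case is serious iff it carries at least one outcome
  code in {DE, LT, HO, DS, CA, RI}; `OT` alone is non-serious.

## Term normalization and composite events

Event names are MedDRA preferred terms (PTs), and MedDRA is revised twice a
year, so verbatim PTs must be corrected to a current version. MedDRA is
licensed and cannot ship with the package; the interface therefore consumes
a user-supplied TSV (`verbatim_pt`, `current_pt`, `soc`). A synthetic
mini-dictionary covering all fixture terms ships for testing — it is
labelled synthetic and is not a MedDRA extract.

Composite events pool clinically equivalent PTs (all tremor variants under
"Tremor"; cytokine release syndrome + cytokine storm under the CRS label;
hypotension + capillary leak syndrome + orthostatic hypotension; and so
on). Groups live in an editable YAML file, must be disjoint, and are
applied with *set semantics*: a case reporting two members of one group
counts once for that group, because the counting unit everywhere is the
deduplicated case, not the PT row. Infection PTs can additionally be
classed by pathogen type (bacterial/fungal/viral) through explicit,
user-editable PT lists standing in for the licensed MedDRA HLGT level.

```{r groups}
groups <- read_term_groups(system.file("extdata", "term_groups.yaml",
                                       package = "faerspv"))
apply_term_groups(c("Intention tremor", "Capillary leak syndrome",
                    "Pyrexia"), groups)
```

## Screening choices

* **Comparator.** The background (`c`, `d` cells) defaults to *all other
  reports in the ingested universe*, the usual whole-database screen. A
  `comparator = "within-class"` option restricts the background to the
  other screened products for sensitivity analysis; within-class RORs are
  not comparable to whole-database ones and the two should not be mixed in
  one table.
* **Zero cells.** With the default `correction = "none"` a zero cell is a
  hard error naming the cell; `correction = "haldane"` adds 0.5 to every
  cell first. Silent corrections would distort the ROR ranking, so the
  choice is always explicit. In `screen_signals()` a pair whose statistics
  are undefined is retained with a `status` note and `NA` statistics —
  never silently dropped.
* **Chi-squared.** The default is the classic uncorrected statistic, which
  is the form conventionally paired with the PRR > 2, χ² > 4 rule; Yates'
  continuity correction is available behind a flag (`yates = TRUE`) and can
  only lower the statistic, i.e. it is the stricter variant.
* **Ordering.** Within each product, rows are ranked by descending ROR with
  ties broken alphabetically by event label, so output order is
  deterministic.

## What the synthetic generator emulates — and what it does not

`synth_config()` / `synth_faers()` generate FAERS-dialect quarterly packets
with known ground truth. The generative model:

* Each of `n_cases` cases is exposed to at most one target product
  (configured prevalences) or to a background drug.
* Each event has a background per-report probability $r$, i.e. odds
  $o = r/(1-r)$. A planted (product, event) multiplier $m$ scales the
  *odds*: exposed cases report the event with probability
  $om/(1+om)$. Planting on the odds scale makes the true case-level ROR of
  the pair exactly $m$, so recovery tests have an analytically known
  target.
* Onset days are log-normal (default median 5 days, $\sigma_{\log} = 0.9$),
  echoing the early post-infusion peak typical of acute CAR T-cell
  toxicity, with a long right tail; event date = therapy start + onset,
  receipt date follows after a Poisson reporting delay.
* Duplicate case versions are re-emissions with a later `FDA_DT` and higher
  `PRIMARYID` and identical clinical content, so deduplication correctness
  is decidable from ground truth. The extra-version probability is
  $r_{dup}/(1-r_{dup})$, making superseded rows an expected `duplicate_rate`
  fraction of emitted DEMO rows.
* A configurable fraction of event dates is truncated to month precision or
  blanked, exercising the onset exclusion branches.
* All randomness flows from one integer seed through a single generator
  stream; the caller's RNG state is preserved. Identical config + seed
  gives byte-identical files.

Deliberately **not** emulated: free-text narratives, dosage fields,
realistic drug-name misspellings beyond case/whitespace noise, reporting
backlog dynamics, and event-event correlation beyond what shared exposure
induces. Passing tests on synthetic data therefore demonstrate the
*mechanics* (parsing, dedup, counting, formulas, criteria, determinism)
and estimator calibration under the stated model — not robustness to the
full messiness of real FAERS extracts, where name matching and duplicate
detection are the dominant practical difficulties.

## Problem sizes used by the test-suite

The suite checks, among ~60 properties: exact agreement of ROR/CI/PRR/χ²
with brute-force formula evaluation on 1,000 random positive tables
(≤ 1e-9 relative); 95% CI coverage within 95% ± 1.5% over 2,000 multinomial
tables of size 5,000 (expected smallest cell 250 — a large-cell regime
where the log-normal interval is well calibrated); recovery of a planted
odds-10 association (prevalence 0.05, background rate 0.01, n = 100,000
cases) in at least 95 of 100 seeds with median estimated ROR in [8, 12.5];
a null-universe false-positive fraction below 5% across 50 seeds; and
byte-identical pipeline reruns. These sizes were chosen so each check has
comfortable statistical resolution while the whole suite stays quick to
run.

## A worked example

```{r pipeline}
cfg <- synth_config(
  n_cases = 5000,
  products = tibble::tibble(name = c("ACMECEL", "BETACEL"),
                            prevalence = c(0.08, 0.08)),
  planted = tibble::tibble(
    product = c("ACMECEL", "BETACEL"),
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
res$screen |> tidy() |> filter(is_signal) |> select(product:d, ror, prr)
```

Both planted pairs surface at the top of their product's ranking with the
signal flag set. The output directory holds `signals.tsv` (2-decimal
display table plus a full-precision companion), `demographics.tsv`,
`onset_bins.tsv`, `overlap.tsv`, `soc_distribution.tsv` and a
`manifest.json` whose record counts telescope (emitted versions =
deduplicated cases + duplicates removed; onset candidates = retained + each
exclusion class).

## Known limitations

* Disproportionality measures reporting, not risk: no causal or incidence
  interpretation survives the missing denominator, under-reporting and
  notoriety effects of spontaneous data.
* No multiple-testing adjustment is applied — the four-part rule is the
  screen, as is conventional in this literature; Bayesian shrinkage methods
  (BCPNN/IC, MGPS/EBGM) are out of scope.
* The dictionary interface models only the PT→SOC mapping plus explicit
  group lists, not the full MedDRA LLT/HLT/HLGT hierarchy.
* Legacy (pre-2012, ISR-era) and XML-dialect FAERS files are not supported.
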