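# Hand calculations for the "tiny-hand-checked" fixture

The fixture (`make_fixture("tiny-hand-checked")`) emits 14 DEMO report
versions covering 12 distinct cases, two products (ACMECEL, BETACEL) and
four event labels after grouping. Every number below is derived by hand and
is asserted by the test-suite.

## Deduplication

| case | versions (PRIMARYID @ FDA_DT)           | kept | rule                      |
|------|-----------------------------------------|------|---------------------------|
| 1    | 101 @ 2023-01-01, 102 @ 2023-03-01      | 102  | latest FDA_DT             |
| 2    | 201 @ 2023-01-10, 205 @ 2023-01-10      | 205  | FDA_DT tie -> higher id   |
| 3-12 | single version each                     | 301, 401, 501, 601, 701, 801, 901, 1001, 1101, 1201 | unchanged |

Kept PRIMARYIDs: 102, 205, 301, 401, 501, 601, 701, 801, 901, 1001, 1101,
1201 (12 cases). Deduplicating again changes nothing (idempotent).

## Primary-suspect attribution

ACMECEL synonyms match cases 1, 2, 3, 5 via a PS-role DRUGNAME or PROD_AI
(case-insensitive, whitespace-normalized; case 5 has `"aCmEcEl"`). Case 4
carries ACMECEL only with role SS and is therefore NOT attributed (its PS
drug is OTHER DRUG 1). BETACEL: cases 6, 7.

## Event labels after grouping (set semantics)

CRS composite = {cytokine release syndrome, cytokine storm}:
cases 1, 2, 3, 6, 8, 10 (case 3 enters via "Cytokine storm").
Tremor composite: cases 3 ("Intention tremor"), 11 ("Tremor").
Pyrexia (no group): cases 1, 4, 7, 9, 11, 12. Hypotension: cases 5, 10.

## 2x2 table for (ACMECEL, Cytokine release syndrome)

Universe = 12 deduplicated cases; ACMECEL cases = {1,2,3,5}.

* a = ACMECEL and CRS = |{1,2,3}| = 3
* b = ACMECEL, other events only = |{5}| = 1
* c = CRS without ACMECEL = |{6,8,10}| = 3
* d = rest = 12 - 3 - 1 - 3 = 5

ROR = (3*5)/(1*3) = 5.
log-CI: se = sqrt(1/3 + 1/1 + 1/3 + 1/5) = 1.366260;
95% CI = exp(ln 5 -/+ 1.959964 * 1.366260) = (0.34356, 72.76671).
PRR = (3/4) / (3/8) = 2.
chi2 = 12 * (3*5 - 1*3)^2 / (4 * 8 * 6 * 6) = 12 * 144 / 1152 = 1.5.
Signal verdict: n = 3 passes, but CI lower limit 0.344 <= 1, PRR = 2 not
> 2, chi2 = 1.5 not > 4 -> not a signal.

## Time to onset (ACMECEL cohort, earliest PS start)

| case | START_DT  | EVENT_DT  | result              |
|------|-----------|-----------|---------------------|
| 1    | 2023-02-01| 2023-02-15| 14 days (retained)  |
| 2    | 2023-02-20| 2023-02-20| 0 days (retained)   |
| 3    | 2023-03-01| 2023-03-10| 9 days (retained)   |
| 5    | 2023-03 (month) | 2023-04-01 | excluded: partial |

Binning with edges 7/30/60 (upper-inclusive): day 0 -> "0-7";
days 9 and 14 -> "8-30". Fractions: 1/3 and 2/3.

## CRS overlap for Hypotension

Cases with Hypotension = {5, 10}; of these, case 10 also reports CRS.
Overlap rate = 1/2 = 0.5.
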