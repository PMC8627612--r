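# srconcord

Do AMSTAR-2 and ROBIS — the two standard instruments for appraising the
quality of conduct of systematic reviews — agree with each other when applied
to the same reviews? `srconcord` provides a tested, reusable pipeline for
answering that question. It is aimed at meta-researchers and evidence-synthesis
methodologists who hold paired item-level appraisals of a cohort of
systematic reviews and want to quantify how concordantly the two instruments
judge the same methodological constructs.

The package covers the full path from raw item responses to a reliability
report:

* **Instrument schemas.** AMSTAR-2 (16 items, 7 critical, `Y`/`PY`/`N`/`NA`
  responses) and ROBIS (21 items in 4 domains, `Y`/`PY`/`PN`/`N`/`NI`) as
  validated tibble schemas, with a data-first validator that reports every
  violation instead of failing.
* **AMSTAR-2 overall confidence rating.** High / Moderate / Low / Critically
  low from critical and non-critical flaw counts, with meta-analysis-
  conditional items excluded and design-stratified items (9, 11) flawed when
  any stratum is `N`.
* **Harmonization.** The canonical set of 11 matched comparisons (12 AMSTAR-2
  and 14 ROBIS items across 4 domains; 26/37 items = 70.3% coverage), each
  with its footnote rule: default binary collapse (ROBIS `Y`/`PY` vs
  `N`/`PN`/`NI`), composite rules for multi-item comparisons, meta-analysis
  gating, and a three-level ordered scale for the literature-search
  comparison.
* **Agreement.** Gwet's chance-corrected agreement coefficient with
  delete-one jackknife confidence intervals and qualitative bands.
* **Synthetic cohorts.** A latent-quality generator producing schema-valid
  paired assessments with controllable inter-instrument concordance, so the
  pipeline is testable end to end without access to raw appraisal data.

## The statistic

For two raters (here: the two harmonized instruments), `n` subjects and `q`
categories with agreement weights `w_kl` (identity weights unless stated),
Gwet's coefficient is

    pi_k = (1 / 2n) * sum_i [ 1(a_i = k) + 1(b_i = k) ]     average propensity
    pa   = (1 / n)  * sum_i w[a_i, b_i]                     observed agreement
    pe   = T_w / (q (q - 1)) * sum_k pi_k (1 - pi_k)        chance agreement
    AC   = (pa - pe) / (1 - pe)

with `T_w = sum_kl w_kl`. Identity weights give the unweighted first-order
coefficient AC1, whose chance term stays stable under extreme prevalence —
important here, because quality items in applied cohorts are answered `N`
far more often than `Y`. Quadratic weights
(`w_kl = 1 - (k - l)^2 / (q - 1)^2`) give the weighted generalization AC2,
used for the one comparison scored on the ordered scale `N < PY < Y`. The
standard error is the delete-one jackknife estimate and the 95% interval is
Wald-normal, upper bound truncated at 1. Coefficients are labelled poor
(≤ 0), slight (0, 0.20], fair (0.20, 0.40], moderate (0.40, 0.60],
substantial (0.60, 0.80] or almost perfect (0.80, 1].

## Worked example

```r
library(srconcord)

cohort <- simulate_cohort(n_reviews = 101, seed = 2026)
report <- run_reliability(cohort)
report
#> Inter-instrument reliability over 101 reviews (11 matched comparisons)
#>
#> Domain 1: Study eligibility criteria
#>   c1  eligibility criteria / PICO                   A1 vs R1.3  n=101  ALMOST_PERFECT; 0.87 (0.78, 0.95)
#>   c2  a priori protocol                             A2 vs R1.1  n=101  ALMOST_PERFECT; 0.87 (0.78, 0.95)
#>
#> Domain 2: Identification and selection of studies
#>   c3  comprehensive literature search               A4 vs R2.1+2.2+2.3+2.4  n=101  ALMOST_PERFECT; 0.85 (0.76, 0.94)
#>   c4  duplicate study selection                     A5 vs R2.5  n=101  ALMOST_PERFECT; 0.87 (0.79, 0.96)
#>
#> Domain 3: Data collection and study appraisal
#>   c5  duplicate data extraction                     A6 vs R3.1  n=101  ALMOST_PERFECT; 0.90 (0.83, 0.97)
#>   c6  adequate description of included studies      A8 vs R3.2  n=101  ALMOST_PERFECT; 0.87 (0.78, 0.96)
#>   c7  risk-of-bias assessment method                A9 vs R3.4  n=101  SUBSTANTIAL; 0.76 (0.63, 0.88)
#>
#> Domain 4: Synthesis and findings
#>   c8  appropriate statistical synthesis             A11 vs R4.3+4.4  n=83   ALMOST_PERFECT; 0.95 (0.90, 1.00)
#>   c9  risk of bias in synthesis and interpretation  A12+13 vs R4.6  n=101  ALMOST_PERFECT; 0.88 (0.80, 0.97)
#>   c10 heterogeneity addressed                       A14 vs R4.4  n=101  ALMOST_PERFECT; 0.92 (0.85, 0.99)
#>   c11 publication bias / robustness of findings     A15 vs R4.5  n=83   ALMOST_PERFECT; 0.92 (0.84, 0.99)
```

Each row is one matched comparison: `n` is the number of applicable reviews
(the two comparisons gated on a meta-analysis drop the 18 reviews without
one), and the right-hand column is the agreement band with the coefficient
and its 95% jackknife interval. `autoplot(report)` draws the corresponding
forest plot, and `format_report()`/`write_report()` export the table.

The coefficient itself is a first-class object with broom-style methods:

```r
pairs <- data.frame(a = c("POS", "POS", "POS", "NEG"),
                    b = c("POS", "POS", "NEG", "NEG"))
gwet_ac(pairs, categories = c("NEG", "POS"))
#> Gwet's agreement coefficient (AC1, unweighted)
#>   n = 4 pairs, q = 2 categories (NEG < POS)
#>   pa = 0.75, pe = 0.4688
#>   AC = 0.53 (95% CI -0.39 to 1)  [MODERATE]
```

Per-review AMSTAR-2 confidence ratings come from `amstar2_overall()`; under
the generator's default left-skewed quality distribution almost all reviews
rate critically low, as is typical of applied cohorts:

```r
amstar2_overall(cohort$assessments, cohort$metadata)[1:4, ]
#> # A tibble: 4 × 4
#>   review_id critical_flaws noncritical_flaws rating
#>   <chr>              <int>             <int> <ord>
#> 1 SR0001                 5                 6 CRITICALLY_LOW
#> 2 SR0002                 6                 8 CRITICALLY_LOW
#> 3 SR0003                 5                 7 CRITICALLY_LOW
#> 4 SR0004                 4                 7 CRITICALLY_LOW
```

Real data enter through `read_assessments()`/`read_metadata()` (long-format
CSV) or `read_assessments_json()`; see the function documentation for the
column contracts.

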