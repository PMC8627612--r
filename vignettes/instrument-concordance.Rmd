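---
title: "Measuring concordance between AMSTAR-2 and ROBIS appraisals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring concordance between AMSTAR-2 and ROBIS appraisals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srconcord)
```

## The problem

AMSTAR-2 and ROBIS both appraise the quality of conduct of systematic
reviews, but they were designed independently: AMSTAR-2 as a 16-item critical
appraisal checklist yielding a four-level overall confidence rating, ROBIS as
a 21-item, four-domain risk-of-bias instrument. Teams choosing between them —
or interpreting assessments made with different instruments — need to know
where the two instruments measure the same methodological construct and how
reliably their judgements coincide when they do.

`srconcord` operationalises that question as an inter-rater reliability
problem. The two instruments play the role of two raters; the "subjects" are
reviews; and the rating scale for each matched construct is obtained by
harmonizing the instruments' native response alphabets onto a common
categorical scale. Agreement on each construct is then quantified with
Gwet's chance-corrected coefficient, and the coefficients are summarised
with qualitative bands from poor to almost perfect.

## The comparison scheme

Eleven comparisons connect 12 AMSTAR-2 items to 14 ROBIS items under four
domain headings (eligibility criteria; identification and selection; data
collection and appraisal; synthesis and findings). Four AMSTAR-2 items
(3, 7, 10, 16) and seven ROBIS items (1.2, 1.4, 1.5, 3.3, 3.5, 4.1, 4.2)
address constructs unique to their instrument and stay unmatched; the
matched 26 of 37 items give the 70.3% construct overlap reported by
`coverage_stats()`. ROBIS item 4.4 (heterogeneity) takes part in two
comparisons. Ten comparisons are fully overlapping in construct; the
publication-bias/robustness comparison is only partially overlapping,
because robustness of findings is a broader notion than publication bias.

The default mapping is binary: ROBIS `Y`/`PY` counts as positive against
AMSTAR-2 `Y` (plus `PY` where the item admits it); ROBIS `N`/`PN`/`NI`
counts as negative against AMSTAR-2 `N`. Four comparisons need more than
that:

* **Literature search (AMSTAR-2 item 4 vs ROBIS 2.1–2.4).** The four ROBIS
  sub-items collapse to the ordered scale `N < PY < Y`: `Y` when all four
  are positive, `PY` when the core pair 2.3/2.4 is positive but not all
  four, `N` otherwise. This is the one comparison scored with quadratic
  weights, so near-misses between adjacent levels receive partial credit.
* **Risk-of-bias assessment (item 9 vs 3.4)** and **synthesis methods
  (item 11 vs 4.3+4.4).** For reviews including both randomised and
  non-randomised studies, AMSTAR-2 records one response per design stratum;
  the item is positive only when every stratum is positive (item 11 demands
  an unqualified `Y`). The item-11 comparison applies only to reviews with a
  meta-analysis.
* **Risk of bias in synthesis (items 12+13 vs 4.6).** With a meta-analysis,
  both items 12 and 13 must be `Y`; without one, item 12 is not assessed and
  item 13 alone carries the comparison.

Two genuinely open points in the scheme were settled as package defaults and
exposed as options. First, how ROBIS 4.3 and 4.4 combine in the item-11
comparison is not specified by the published footnotes; the package requires
*both* to be positive (`rule_e_mode = "ALL"`), by analogy with the
all-positive clause of the literature-search rule and with the conjunctive
stratum rule on the AMSTAR-2 side; `"ANY"` is available for sensitivity
analysis. Second, whether the heterogeneity comparison (item 14 vs 4.4)
should also be gated on a meta-analysis is unstated; it is implemented
ungated, since item 14 is assessed for every review.

Reviews that fail schema validation are dropped from all comparisons with a
warning — partial, silently imputed records would bias the propensity terms
of the chance correction.

## The AMSTAR-2 rating

A review's overall confidence is a deterministic function of its flaw
counts: `HIGH` with no critical flaw and at most one non-critical flaw,
`MODERATE` with no critical flaw but more than one non-critical flaw, `LOW`
with exactly one critical flaw, `CRITICALLY_LOW` with more than one. A flaw
is an `N` response; `NA` items (meta-analysis-conditional items of reviews
without one) are excluded from both counts, which makes exclusion exactly
equivalent to a no-flaw response — a property the test suite verifies by
brute force. `PY` is an affirmative partial judgement and is not a flaw by
default; because published guidance leaves a stricter reading open for the
critical items, `strict_py_flaw = TRUE` counts critical-item `PY` as a flaw.

## The agreement coefficient

For ratings `a_i, b_i` over `n` reviews and `q` categories with weights
`w`, the package computes

$$\pi_k = \frac{1}{2n}\sum_i \left[\mathbf 1(a_i = k) + \mathbf 1(b_i = k)\right],
\qquad p_a = \frac{1}{n}\sum_i w_{a_i b_i},$$
$$p_e = \frac{T_w}{q(q-1)} \sum_k \pi_k (1 - \pi_k),
\qquad AC = \frac{p_a - p_e}{1 - p_e},$$

with $T_w = \sum_{k,l} w_{kl}$. Identity weights give the unweighted AC1;
quadratic weights $w_{kl} = 1 - (k-l)^2/(q-1)^2$ give the weighted AC2. The
chance term is built from *average* category propensities rather than the
product of marginals, which keeps the coefficient stable when one category
dominates — precisely the regime of strongly left-skewed quality cohorts,
where most items are answered negatively on both instruments.

The category scale of each comparison is design-fixed (`NEG`/`POS`, or
`N < PY < Y`), not inferred from the data: a category unobserved in a given
sample still contributes a zero-propensity term. `run_reliability()`
therefore passes the scale explicitly to `gwet_ac()`.

### Confidence intervals

The interval method behind previously published coefficients of this kind
is generally not reported, so the package makes its own, fully documented
choice: the delete-one jackknife standard error

$$\widehat{se} = \sqrt{\frac{n-1}{n} \sum_i \left(AC_{(-i)} - \overline{AC_{(-\cdot)}}\right)^2}$$

with a Wald-normal interval $AC \pm z_{0.975}\,\widehat{se}$
($z_{0.975} = 1.959964$; the normal rather than a t quantile, following
large-sample practice for agreement coefficients). The upper bound is
truncated at 1; the lower bound is not, since slightly negative lower bounds
are meaningful for near-chance agreement. Consequences of this choice: the
intervals are deterministic and assumption-light, but interval endpoints
computed by other software (closed-form linearized variances, bootstrap
implementations) will differ in the trailing digits even on identical data.
The test suite checks the jackknife against a nonparametric bootstrap on a
small worked example (agreement within 25% on the standard error) and
verifies empirical coverage within [0.92, 0.98] at the study-scale sample
size of 101 pairs over 2,000 simulation replicates.

Degenerate inputs are reported, not guessed at: fewer than two applicable
pairs, or a chance term of exactly 1, yield a structured "not estimable"
row in the report rather than an infinite or missing coefficient. For
binary and three-level quadratic scales the chance term is in fact bounded
well below 1, so the guard exists for custom weight matrices.

### Reporting conventions

Coefficients and interval bounds are reported to two decimals with ties
rounded half away from zero (`round_half_up()`), matching the convention of
published agreement tables; the underlying tibble keeps full precision.
Bands use half-open intervals with poor at $\le 0$: a coefficient of
exactly 0.60 is moderate, 0.80 substantial.

## The synthetic-cohort generator

No public corpus of paired item-level AMSTAR-2/ROBIS assessments exists, so
the package ships a generator whose defaults encode the study conditions the
pipeline is meant for: 101 reviews; latent quality
$u \sim \mathrm{Beta}(1.2, 6)$, a strongly left-skewed distribution under
which high-confidence AMSTAR-2 ratings are rare (the calibration check
`calibrate_prevalence()` keeps the high-rating share at or below 5%, in line
with applied cohorts where only about 1% of reviews rate high); an 80%
meta-analysis rate; a 15/55/30 split of RCT-only, NRSI-only and mixed-design
reviews; and a 25% chance that a met construct is only partially met.

The generative model is a single latent factor per review. Items are grouped
into *constructs*: one per matched comparison group (the two comparisons
sharing ROBIS 4.4 fuse into one construct) and one per unmatched item. Each
construct is latently met with probability `u`, partially met with
probability `py_prob` within the met mass, and each instrument's items emit
the latent state deterministically (met gives `Y`; partial gives `PY` where
the alphabet allows, else `Y`; unmet gives `N` on AMSTAR-2 and `PN`/`N`/`NI`
with probabilities 0.3/0.5/0.2 on ROBIS — fixed, invented splits). With
probability `1 - concordance` an observation is instead redrawn uniformly
from the item's alphabet (`noise = "adjacent"` substitutes a one-step error
on the ordered scale, useful for exercising quadratic weights). The default
concordance of 0.9 reflects consensus-based appraisal workflows, which
produce mostly almost-perfect coefficients. A single RNG stream with a fixed
draw order (quality, meta-analysis indicators, design mixes, latent states,
ROBIS unmet emissions, noise) makes cohorts byte-reproducible given a seed.

What the generator does *not* emulate: correlated rater psychology beyond
the shared latent factor, item-specific difficulty, informative missingness,
or any coupling between design mix and quality. Passing tests on synthetic
cohorts therefore demonstrate the pipeline's correctness and the
coefficient's statistical behaviour — not properties of real appraisal data.

One property worth spelling out, because it is easy to assume otherwise:
at `concordance = 0`, AC1 does **not** converge to zero on every comparison.
Under independence the observed agreement converges to a product-marginal
quantity while AC1's chance term uses average propensities, so the limit is
zero only when the two sides' positive rates are similar and near one half.
That holds for the single-item default-rule comparisons (limit ≈ 0.01), but
composite rules skew the ROBIS-side marginal (for example, all four search
sub-items positive has probability $0.4^4$ under uniform redraw) and shift
the limit away from zero. The acceptance tests check the default-rule
comparisons against zero and *every* comparison against its closed-form
independence value — a stronger property than a blanket zero.

## Problem sizes used by the test suite

The suite favours exhaustive enumeration where alphabets are small: all 625
four-tuples of the literature-search rule, every response-by-metadata
combination of the conditional rules, all $2^8$ binary configurations of
four pairs against a brute-force oracle, and all 80 critical/non-critical
flaw-count combinations of the rating rule. Statistical properties use a
100,000-review cohort for the independence regime, 2,000 replicates of 101
pairs for interval coverage, and triplicate 300-review cohorts at four
concordance levels for monotonicity. These sizes keep every Monte-Carlo
check's sampling error an order of magnitude below its tolerance.

## Limitations

* The ROBIS phase structure (relevance assessment, domain-concern and
  overall risk-of-bias judgements) is narrative and has no published
  algorithm; the package deliberately does not model it. A mechanical
  domain-concern profile is available behind an explicit acknowledgement
  flag (`robis_concern_heuristic()`) and is excluded from the pipeline.
* Published coefficients bundled in `published_agreement()` are reference
  values for band classification; their underlying raw assessments are not
  public, so digit-level reproduction of those coefficients or their
  intervals is out of reach by construction.
* The comparison scheme is one defensible matching; alternative schemes
  (for example a 12-comparison matching that pairs AMSTAR-2 item 3 with
  ROBIS 1.4 and merges 3.1/3.5) exist and would yield different coverage
  statistics. The table is exportable as JSON so deviations are auditable,
  but only the canonical scheme ships.
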