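---
title: "A dual-purpose sampling design for annual claims populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A dual-purpose sampling design for annual claims populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelsample)
library(dplyr)
```

## The problem

National claims files (Medicare-style beneficiary summary files) describe a
dynamic population: each year beneficiaries die, switch in and out of managed
care, move between counties, and newly qualify. A study that buys an annual
sample of fixed size faces two conflicting needs:

* **cross-sectional validity** — each year's sample should be representative
  of that year's eligible population, so annual prevalences and means can be
  estimated;
* **longitudinal retention** — as many previously sampled members as possible
  should be kept, so multi-year cohorts have power.

Sampling each year independently destroys the panel; keeping only the
baseline cohort lets the sample age away from the population. `panelsample`
implements a design that achieves both: retain every still-eligible sampled
member, and *fill in* the attrition with a properly weighted draw from the
beneficiaries who could not have been sampled the year before. Because the
newly eligible frame is exactly the complement of the retained set within the
new year's eligible population, the union is a valid stratified sample of
every follow-up year.

## Eligibility

A beneficiary-year is eligible when the beneficiary (i) has an
ever-recorded diabetes diagnosis, (ii) was alive the whole calendar year,
(iii) had 12 months of fee-for-service enrollment that year, and (iv) lives
in a county of the closed study set. Only the aged (65+) population is
modelled. Beneficiaries who die mid-year are treated as ineligible in their
death year — the 12-month enrollment rule cannot be satisfied — which also
fixes the population denominators: partial-year decedents are excluded from
the year's eligible count. The alternative (counting decedents in
denominators) would change population totals by roughly the annual mortality
rate but none of the design identities.

## The baseline allocation

The baseline year's sample of `total_target` (default 900,000) is allocated
in two deterministic stages over (county × race) strata, where race is
dichotomized to white/minority at load time:

1. **County minimums, then proportional remainder.** Every county gets
   `min(500, N_c)` — small counties are completely enumerated. The remaining
   budget is spread over counties proportionally to their *unsampled*
   population `N_c − min(500, N_c)`, using largest-remainder (Hamilton)
   rounding so the county targets sum exactly to the total. The realized
   remainder sampling rate is an *outcome* of the population at hand, never a
   parameter.
2. **Race minimums, then smooth oversampling.** Within a county each race
   group gets `min(250, N_g)`; the rest of the county target is split by the
   cubic
   $$p_s(x) = 2\left(x - \tfrac12\right)^3 + \tfrac{x - 1/2}{2} + \tfrac12,$$
   applied to the minority share $x$ of the still-unsampled county
   population. The cubic fixes $0 \mapsto 0$, $\tfrac12 \mapsto \tfrac12$,
   $1 \mapsto 1$, is strictly increasing, satisfies $p_s(1-x) = 1-p_s(x)$,
   and has slope 2 at both endpoints: whichever group is locally rare is
   sampled at about twice its share, transitioning smoothly to equal
   sampling at parity. The minority count is rounded to the nearest integer
   and capped at the group population, with overflow reassigned to the other
   group, so the split always conserves the county target.

Members are then drawn by simple random sampling without replacement within
each stratum, and every member carries the Horvitz–Thompson weight
$w_h = N_h / n_h$. Two algebraic identities follow and are enforced by
tests: weights over a stratum sum exactly to $N_h$ (summing to the eligible
population total over all strata), and the weighted proportion of any
stratification variable — race — equals its population value exactly.

Ordering of the two stages is a genuinely open design point; we apply county
minimums first and race minimums within the county target, matching the
narrative order of the procedure, so a county's total is fixed before its
race split.

## Follow-up years

* **Retention.** A sampled member is kept for year $t+1$ iff eligible in
  $t+1$ *and* in the same county. Retained members keep their original
  weight and wave stratum (county, race, entry year); no reweighting is
  applied. The implicit assumption — sample attrition matches population
  attrition in expectation — is surfaced as a tested property: weighted
  annual totals track the eligible population count in every follow-up year.
* **Fill-in frame.** All beneficiaries eligible in $t+1$ who were ineligible
  in $t$, plus between-county movers (in their destination county's frame).
  A previously sampled member who exited and later re-qualifies re-enters
  the frame and may be resampled as a member of a new wave; the design never
  allows two rows for one beneficiary in the same year.
* **Fill-in allocation.** The baseline allocation procedure is re-run on the
  *full* year-$(t+1)$ eligible population; each stratum's fill-in is
  `min(frame, max(10, target − retained))`. The floor of 10 guarantees new
  members in every county every year; it applies per (county × race) stratum
  with a nonempty frame (the stricter reading), and empty frames are logged,
  not fatal. Shortfalls are subtracted per stratum, not per county.
* **Fill-in weights.** Frame size over fill-in size, per stratum — the
  Horvitz–Thompson weight of the frame draw. Weights over a fill-in wave
  stratum sum exactly to the frame size.

## Design-based estimation

Design strata are (county × race × entry wave). For a total
$\hat{Y} = \sum_i w_i y_i$ the variance estimator is the stratified
without-replacement form
$$\widehat{V}(\hat{Y}) = \sum_h N_h^2\left(1 - \frac{n_h}{N_h}\right)
  \frac{s_h^2}{n_h},$$
with $s_h^2$ the within-stratum sample variance; the finite-population
correction makes census strata contribute nothing. Means and proportions are
ratios $\hat{Y}/\hat{N}$ estimated by Taylor-series linearization: the total
variance applied to residuals $z_i = (y_i - \hat{\bar y})/\hat{N}$.
Comparisons against known population values use a Wald $z$-test with the
design SE and a normal reference — appropriate at these sample sizes, and
the difference from a score test is negligible at $n \approx 9\times10^5$.
The unbiasedness of the total variance is checked against brute-force
enumeration of all samples from tiny strata, and the test's type-I error and
CI coverage are checked over hundreds of replicate draws.

Numerical choices:

* **Singleton strata** ($n_h = 1 < N_h$) contribute zero variance, with a
  warning and a count in `glance()`; the fill-in floor of 10 makes them rare
  by design. Collapsing strata was deliberately left out.
* **Stratification variables** have design SE exactly 0 (race is constant
  within a stratum), so their one-sample p-value is degenerate: 1 where the
  identity holds exactly (baseline), 0 otherwise. The point difference is
  the meaningful quantity in follow-up years.
* **No multiplicity correction** is applied across comparisons; reports use
  the per-comparison $\alpha = 0.05$ convention.
* Largest-remainder ties are broken by larger population, then lexicographic
  county id, making every allocation fully deterministic.
* Per-stratum draw seeds are derived from (master seed, year, county, race)
  via a 31-bit string hash, so draws are reproducible and independent of the
  order in which strata are processed.

## The synthetic population

Real beneficiary summary files are restricted, so the package ships a seeded
simulator whose defaults emulate the statistical structure such a population
exhibits; they were fixed once, from the population the design is meant for,
and are not tuning knobs:

| parameter | default | emulates |
|---|---|---|
| counties | 600 | a multi-state county system (study regions of ~950 counties scale linearly) |
| total eligibles | 1.9M | a ~2M-person disease population |
| county sizes | log-normal, sdlog 1.1 | heavy-tailed county sizes; smallest counties fall under the 500 minimum and are fully enumerated |
| minority share | Beta(2, 8) per county | ~80% white overall with county heterogeneity |
| age | truncated normal (≥65), post-truncation mean 75.09, sd 7.5 | aged claims population (the underlying location is solved by `uniroot` so the *truncated* mean hits the target; ages are rounded to whole years) |
| sex | 42.9% male | the female-majority aged population |
| conditions | 21 independent Bernoulli flags at `default_condition_prevalences()` | chronic-condition mix from ~1% (endometrial cancer) to ~93% (hypertension) |
| mortality | 7% at age 75, log-odds +0.08/year of age | rising mortality with age |
| HMO switch / return | 7% / 30% | managed-care churn |
| moves | 2%/year, destination ∝ county size | between-county migration preserving the size distribution |
| entry | 7% new 65-year-old enrollees + 7% incident diagnoses | frame inflow |
| condition accrual | 2%/year/condition | upward prevalence drift in later years |

Jointly these give one-year eligibility retention of ~86% and same-county
sample retention of ~84%, with a slowly growing population. Exit reasons
(death / lost FFS / moved) are recorded on the evolved table for audit.

What the simulator does **not** emulate: spatial correlation between
neighbouring counties, cause-specific mortality, correlation between
conditions (including sex-specific cancers — flags are independent of sex),
or calibrated secular trends. Passing tests on this population therefore
demonstrate the *design identities and estimator calibration* — which are
algebraic or distribution-free — and the representativeness magnitudes under
realistic size structure; they do not certify behaviour under, say, strong
spatial clustering of race or condition comorbidity, which affect neither
the weight identities nor unbiasedness but would change design effects.

## Problem sizes used by the test-suite

The full-scale checks run the design at its intended size — 1.9M eligibles,
600 counties, 900,000 sampled — for the baseline-year representativeness
measures (exact race identity; replicate-draw deviations of mean age, %
female, and all 21 prevalences). Multi-year panel properties (weight
identities per wave, annual total tracking over 10 years, retention
monotonicity, cohort comparisons) run on scaled-down populations of
2,400–20,000 beneficiaries with proportionally scaled minimums, where
hundreds of replicate panels are cheap and the Monte-Carlo error of each
bound is explicit in the test.

## Known limitations

* Retained members are never reweighted; if sample attrition deviates
  systematically from population attrition (non-random within strata), the
  follow-up-year estimates drift. The annual-total tracking property is the
  canary.
* No post-stratification, raking, nonresponse adjustment, or
  replicate-weight (BRR/jackknife) variance construction.
* Design-based regression coefficients are out of scope; the estimation
  module covers totals, means, and proportions.
* The aged population only; disabled/ESRD entry pathways are not modelled.
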