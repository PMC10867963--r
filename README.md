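# panelsample

Representative longitudinal **and** cross-sectional samples from annual
claims populations.

Studies built on national claims files (Medicare-style beneficiary summary
files) usually buy a fixed-size annual sample. A pure baseline cohort decays
— deaths, managed-care switching, and moves remove ~16% of an aged
fee-for-service disease population per year — so after a few years it no
longer represents anyone; independent annual samples, conversely, contain
almost no multi-year follow-up. `panelsample` implements a stratified panel
design that serves both purposes at once, together with the design-based
estimators used to validate it and a seeded synthetic population simulator
so the whole pipeline runs without restricted data.

## The design

For the baseline year, the annual target *n* (default 900,000) is allocated
over (county × race) strata:

* every county receives min(500, N<sub>c</sub>) — small counties are fully
  enumerated — and the remainder is apportioned proportionally to the
  unsampled county populations with largest-remainder rounding;
* within a county, each race group (white / minority) receives
  min(250, N<sub>g</sub>), and the rest is split by the smooth oversampling
  cubic

  p<sub>s</sub>(x) = 2(x − ½)³ + (x − ½)/2 + ½,

  where *x* is the minority share of the still-unsampled county population:
  whichever group is locally rare is sampled at roughly twice its share,
  transitioning to equal sampling at parity (p<sub>s</sub>(1 − x) = 1 −
  p<sub>s</sub>(x));
* members are drawn by SRS without replacement within strata and carry
  Horvitz–Thompson weights N<sub>h</sub>/n<sub>h</sub>.

In each follow-up year, every sampled member still eligible (alive, 12
months fee-for-service, same county) is retained with original weight and
wave stratum. The attrition is replaced from the **newly eligible frame** —
beneficiaries who could not have been sampled the year before (new
enrollees, HMO returners, the newly diagnosed, in-movers) — with at least 10
per stratum and more where retention fell short of that year's re-computed
target, weighted by frame size over fill-in size. Estimation uses
Taylor-series linearization with finite-population correction over
(county × race × entry-wave) strata.

See `vignette("sampling-design")` for the full model, parameter meanings,
and numerical choices.

## Worked example

```r
library(panelsample)

pop <- synthetic_population(n_counties = 40, total_population = 120000,
                            years = 2006:2010, seed = 42)
panel <- run_panel(pop, total_target = 50000, county_min = 500,
                   race_min = 250, min_fill = 10, seed = 42)
retention_matrix(panel)
#> <retention_matrix> count (% of wave's initial size)
#>   follow_up_year `2006`         `2007`        `2008`        `2009`        `2010`
#> 1           2006 50000 (100.0%) <NA>          <NA>          <NA>          <NA>
#> 2           2007 41742 (83.5%)  8258 (100.0%) <NA>          <NA>          <NA>
#> 3           2008 34908 (69.8%)  6986 (84.6%)  8106 (100.0%) <NA>          <NA>
#> 4           2009 28829 (57.7%)  5968 (72.3%)  6932 (85.5%)  8271 (100.0%) <NA>
#> 5           2010 23705 (47.4%)  5061 (61.3%)  5894 (72.7%)  7016 (84.8%)  8324 (100.0%)
```

Each year's sample stays at the 50,000 target: the 2006 wave decays to 47.4%
by 2010 (retained members keep their weights for longitudinal analyses)
while the yearly fill-in waves restore cross-sectional representativeness.
Comparing the weighted 2010 sample — the *worst* year, four fill-ins deep —
against the 2010 population:

```r
cross_sectional_report(panel, pop, 2010)
#>   variable  population_value estimate      se difference p_value
#> 1 age_mean            75.2     75.1   0.0414   -0.0339     0.413
#> 2 pct_male             0.427    0.427 0.00347  -0.000560   0.872
#> 3 pct_white            0.758    0.757 0        -0.00107    0
```

Mean age differs by 0.03 years (not significant) and % male by 0.06 points;
% white is a stratification variable, so its design SE is exactly 0 and the
tiny follow-up-year difference carries a degenerate p-value (at baseline the
difference is zero to machine precision). The 21 chronic-condition
prevalences (`prevalence_report(panel, pop, 2010)`) deviate by at most 0.21
points at this 50k scale, and shrink further at the design's full 900k size.

Estimates are plain design objects:

```r
d <- sample_analysis_table(panel, pop, 2010)
tidy(compare_estimate(weighted_mean(d, age),
                      mean(eligible_population(pop, 2010)$age)))
```

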