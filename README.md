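# concordkit

Demographic identifiers in administrative records are often missing or
disagree between sources. When the same people appear in an electronic
health record (EHR) system and in census survey microdata, their
recorded race/ethnicity can be compared person by person — and the
choice of which source supplies the group label changes group-level
health statistics. `concordkit` implements that data-quality analysis
as a reusable, tested pipeline for linked person-level records:

* **Harmonization** of heterogeneous race/ethnicity codings to the 1997
  OMB standard categories (Hispanic, White, Black, AIAN, Asian, NHPI,
  Multiracial, plus `Unreported`), with Hispanic-of-any-race precedence
  and multi-race sets retained.
* **Census-observation resolution**: allocated (imputed) responses are
  dropped, same-source-same-year conflicting responses are removed
  wholesale, and the remaining observations are prioritized (decennial
  census over ACS, then most recent).
* **Concordance classification** of each linked person as concordant,
  partially concordant (a single race contained in the other source's
  multi-race selection), discordant, or nonreporting, with the
  Fig-1-style EHR × census cross-tabulation, discordance/missingness
  rates, and discordant-composition tables.
* **Outcome grouping**: ICD-9/ICD-10/SNOMED events collapsed to
  3-character ICD-10 groups (`E11.42` → `E11`), per-patient
  ever-indicators, top-k outcome selection.
* **Estimation**: group prevalences with continuity-corrected Wilson
  score intervals, prevalence *shifts* between labelings (the change in
  a group's estimated prevalence when group membership comes from the
  census labeling instead of the EHR labeling), with delta-method Wald
  intervals from person-clustered logistic fits, pattern
  disaggregation, and Bonferroni family-wise adjustment.
* **Cohort comparisons**: the 39 pairwise demographic contrasts across
  concordance groups (continuity-corrected two-proportion tests),
  practice-level regressions, and concentration reports.
* **Disclosure-style protection**: exact discrete Gaussian count noise
  with base-10 rounding (for fixture realism — not certified disclosure
  avoidance).
* **A synthetic linked-cohort generator** with full ground truth and
  closed-form expected rates, so the whole pipeline is testable without
  restricted microdata.

## The statistics at the core

For a group *g* under labeling *s* ∈ {EHR, census} and outcome *o*, the
prevalence is `p̂ = k/n` over the persons labeled *g* under *s*, with a
continuity-corrected Wilson score interval at the Bonferroni-adjusted
level α/m. The prevalence shift is

```
Δ = p̂(census) − p̂(EHR)   (reported in percentage points)
```

estimated by stacking the two group denominators with a source
indicator, fitting a logistic model `logit P(y=1) = β₀ + β₁·src`, and
transforming to the probability scale by the delta method; because many
persons sit in both denominators, the variance is clustered on persons
(sandwich estimator). Demographic contrasts use the classic two-sample
test for equality of proportions with continuity correction at
α = 0.05/39.

## Worked example

```r
library(concordkit)

dat <- generate_cohort(paper_like_config(n_patients = 20000), seed = 7)
run <- run_pipeline(dat)
run
#> concordkit pipeline run: 8 stages complete
#>   cohort: 19182 linked persons (of 20000 EHR patients)
#>   discordance 5.5% (strict 8.4%), missingness 19.5%
```

19,182 of 20,000 synthetic patients resolve to a census label (the rest
lost all observations to allocation filtering or conflict dropping).
8.4% of reporting patients are recorded discordantly (5.5% when partial
concordance counts as agreement) and 19.5% report race/ethnicity to the
census source but not in the EHR — close to this configuration's
closed-form expectations (7.8%, 5.0%, 19.3%; see `expected_rates()`).

```r
missingness_rate(run$records, by = "census") |>
  dplyr::filter(census_category %in% c("White", "Asian", "NHPI"))
#>   census_category     n n_nonreporting  rate
#> 1 Asian             637            247 0.388
#> 2 NHPI               33             11 0.333
#> 3 White           13310           2357 0.177
```

EHR missingness is far from uniform across census-recorded groups —
17.7% for White patients versus ~39% for Asian patients here — which is
exactly the structure that biases single-source prevalence estimates.

```r
dplyr::filter(run$shifts, group == "White", outcome_group == "E11")
#>   group n_ehr n_census p_ehr p_census delta_pp lower_pp upper_pp
#> 1 White 11881    13310 0.111    0.112    0.133   -0.436    0.702
```

Switching the White group's membership from EHR to census labels moves
estimated Type 2 diabetes (`E11`) prevalence by +0.13 pp here, with the
Bonferroni-adjusted delta-method interval spanning zero at this sample
size. `autoplot(run$shifts)` draws the dot-and-interval panel;
`plot_pattern_disaggregation(run$patterns)` decomposes focus groups
into their recording-pattern cohorts.

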