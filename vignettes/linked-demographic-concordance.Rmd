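---
title: "Measuring race/ethnicity concordance and its impact on prevalence estimates in linked records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring race/ethnicity concordance and its impact on prevalence estimates in linked records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(concordkit)
```

## The problem

Electronic health records routinely lack race/ethnicity for a large
share of patients, and where both an EHR system and census survey
microdata record it for the same person, the two labels disagree for a
non-trivial fraction. Both phenomena are invisible to an analyst
holding only one source, yet both change group-level statistics: a
group's estimated disease prevalence depends on *which source supplies
the group labels*. `concordkit` operationalizes this audit for any pair
of linked person-level sources that can be harmonized to the 1997 OMB
categories. Linkage itself is assumed given (shared anonymized person
keys); probabilistic record linkage, geocoding, and imputation methods
such as BISG are out of scope.

## Harmonization model

Every source coding is mapped to one of seven reported categories —
Hispanic (of any race), and non-Hispanic White, Black, AIAN, Asian,
NHPI, Multiracial — or to `Unreported`. Three rules do all the work:

1. **Ethnicity precedence.** A Hispanic ethnicity response dominates
   any race entry, on either source.
2. **Multi-race.** Two or more distinct mapped races yield
   `Multiracial`, retaining the race set. Census-side multi-race labels
   always carry ≥ 2 component races; an EHR string coded directly as
   "multiracial" yields `Multiracial` with an *empty* race set, since
   its components are unobserved. Classification only ever consults the
   census-side race set, so this asymmetry does not affect results.
3. **Collapse of non-response.** "Unknown", "declined", and blank are a
   single `Unreported` state; so are codes like "other" that have no
   home in the 1997 taxonomy. Matching is case-insensitive after
   trimming, because decentralized practices vary in casing.

The EHR mapping is an externalized two-column table
(`read_ehr_mapping()`), shipped with a documented default covering
common EHR dialect strings; this keeps the engine auditable and
reusable across EHR dialects.

## Census-observation resolution

A person may respond to several censuses and surveys. Resolution
applies, in order: *(1)* removal of allocated (survey-imputed)
responses; *(2)* removal of every observation in a (source, year) cell
whose harmonized labels disagree — multiple non-matching responses in
one source-year suggest linkage error, so the whole cell is distrusted;
*(3)* priority. Two priority rules are plausible where the sources'
stated rules interact: we default to *decennial-over-ACS regardless of
recency* (`priority = "decennial"`), reading the source-priority rule
as unconditional, and expose global recency as a configuration switch
(`priority = "recency"`). Conflicts are judged on harmonized labels
(category + race set), not raw codes, because the OMB category is the
analysis unit. Allocation filtering runs before conflict detection, so
an allocated response can never create or mask a conflict.

`pairwise_census_labels()` applies the same machinery within two
disjoint source/year windows, enabling within-census discordance
analyses (ACS vs a decennial year, or two decennial years).

## Concordance classification

With a reported census label required (the linked cohort is defined by
valid census race/ethnicity), each person is:

* `nonreporting` if the EHR label is `Unreported`;
* `concordant` if categories match (two Multiracial labels are
  concordant regardless of race-set identity);
* `partial` if the census label is Multiracial and the EHR single race
  is one of its components (only this direction — a Hispanic census
  label vs an EHR single race is always discordant because ethnicity
  carries no race set; the mirrored EHR-Multiracial rule is available
  via `mirror_partial = TRUE` but deviates from the convention of the
  analyses this package follows);
* `discordant` otherwise.

Rates follow directly: discordance is computed among reporting persons,
with `partial` counted as agreement or folded into discordance
according to `allow_partial`; missingness is `nonreporting` over the
cohort, overall or within census-category columns. The cross-tab
normalizes rows to 100% and columns to 100% over reported EHR rows,
with the `Unreported` row expressed against the full column — matching
the presentation conventions of published agreement matrices.

## Outcomes

Clinical events are collapsed to 3-character ICD-10 stems (letter + two
digits); ICD-9 and SNOMED codes go through a crosswalk first. The
shipped crosswalk is a small fixture covering common primary-care
codes — the national GEM/SNOMED maps are external reference data, and
the package's computation is truncation after mapping. Unmapped codes
are dropped with a count rather than failing the run, since real EHR
extracts contain junk. Ever-indicators span the person's whole record
window (no date filtering), and top-k selection breaks count ties
lexicographically, optionally excluding stems such as `Z` codes
(encounter reasons, not diagnoses).

## Estimation

**Wilson intervals.** Group prevalences use the continuity-corrected
Wilson score interval, clipped to [0, 1] with exact boundary behaviour
(lower bound 0 at k = 0, upper bound 1 at k = n). Families of intervals
are adjusted by Bonferroni: `alpha_family / n_comparisons`, with 350
used for the group × outcome shift family and 39 for the demographic
contrast table, mirroring the published analysis design.

**Shifts.** The shift for group *g* and outcome *o* is the
percentage-point difference between the census-labeled and EHR-labeled
prevalence. The interval comes from a logistic fit on the stacked
denominators with a source indicator, transformed to the probability
difference by the delta method. Two numerical choices matter:

* *Point estimate.* In this saturated model the fitted group
  probabilities are exactly the (weighted) sample proportions, so the
  point estimate is computed directly from them rather than from IRLS
  coefficients — the identity `Δ = p̂_census − p̂_EHR` then holds to
  machine precision.
* *Overlap.* Most persons sit in both denominators, so observations are
  not independent; the variance is clustered on persons
  (`sandwich::vcovCL`). Ignoring the overlap would overstate the
  variance; the clustered interval is validated against a person-level
  bootstrap in the test suite.

The model is unweighted by default — no weighting scheme is recoverable
from the published description, and at weight 1 the estimand is exactly
the difference of group proportions — but a per-person weight column is
accepted for generality.

**Pattern disaggregation.** Each focus aggregate (a group under one
labeling) is partitioned by the counterpart label into
recording-pattern cohorts; constituent counts sum exactly to the
aggregate and the aggregate prevalence is their count-weighted mean.
The set of patterns is generated mechanically from the data, not
hard-coded: the number of distinct patterns is a property of the cohort.

## Cohort comparisons

The demographic contrast table crosses 13 characteristic levels (3 age
bands at a configurable reference date, defaulting to the end of the
emulated record window, 2021-12-31; 2 sexes; 4 SVI bands with the
half-open convention `[0,25]`, `(25,50]`, `(50,75]`, `(75,100]`; 4 RUCA
bands) with 3 group pairs at α = 0.05/39. Denominators are full group
totals: persons missing address information or with other/missing sex
occupy no band, so SVI/RUCA shares need not total 100% — this is the
convention under which the published contrasts reproduce exactly from
the printed counts. Partially concordant persons are grouped with the
discordant for this table.

Practice-level analysis fits simple OLS regressions on per-practice
summaries. The published description names three models but discusses
five relationships; the model set is configurable with a five-model
default (discordance and missingness on practice size, discordance on
missingness, and both rates on the non-White patient share). A constant
regressor degrades only its own model, with a note. Concentration
reports rank practices by pattern-member count; the "large practice"
screen threshold is 1,000 patients (exclusive).

## Disclosure mechanism

`sample_discrete_gaussian()` is an exact sampler for
P(X = x) ∝ exp(−x²/2σ²) on the integers, by rejection from a two-sided
geometric (discrete Laplace) base — no floating-point normal rounding
is involved. `protect_counts()` adds a draw to each count, clamps at
zero, then rounds to the nearest multiple of the base
(clamp-then-round, because released tables contain no negative counts).
The defaults σ = 4 and base 10 reflect that published counts in this
domain are multiples of 10; the true production noise scale is
unpublished. This module provides fixture realism and privacy
demonstrations only — it performs no formal privacy accounting and is
not certified disclosure avoidance. For the same reason, comparisons
with published values elsewhere in the package always go through the
published counts themselves, never through this module.

## The synthetic generator

`generate_cohort()` samples a linked cohort with full ground truth:

* a latent identity per person from `category_probs`, with the
  Multiracial mass split over configured race sets;
* practice-level recording defects in deterministic blocks (so exposure
  fractions are exact): practices lacking a Hispanic intake option
  record latent-Hispanic patients under a fallback race, and practices
  without multi-race selection record latent-Multiracial patients under
  one uniformly chosen component race;
* per-category EHR masking to `Unreported`;
* a per-person, time-invariant *fluidity* relabeling at census
  reporting, through a confusion kernel whose default mass moves
  preferentially Hispanic↔White, single race↔Multiracial-containing-it,
  and AIAN/NHPI→White. A single time-invariant kernel is a deliberate
  simplification: fluidity and error cannot be separated observationally
  anyway, and one kernel exercises every pipeline branch;
* 1–3 census observations per person with allocation flags and injected
  same-source-year conflicts. Conflicts are injected only against
  reported originals so that conflict-dropping removes whole cells and
  cohort exclusion stays independent of the person's labels — this
  keeps the closed-form expectations exact;
* outcome indicators from per-category logistic models (optional age
  slope, default 0), and covariates from simple parametric stand-ins
  (uniform SVI with a missing share, metropolitan-heavy RUCA) that are
  documented, not fit to any source.

`expected_rates()` composes these rules analytically — enumerating the
joint distribution of (latent label, defect exposure, EHR label, census
label) as probability atoms — and returns exact expected discordance,
missingness (overall and by census category), and group prevalences
under both labelings. `paper_like_config()` fixes parameters, once and
by closed form rather than simulation, so these expectations land on
the magnitudes reported by the linked EHR–census study this package
emulates: strict discordance ≈ 7.8% (≈ 5.0% with partial concordance),
overall missingness ≈ 19.3%, census-standpoint missingness 17.7% /
35.2% / 38.1% for White / Asian / NHPI, and census-labeled NHPI Type 2
diabetes prevalence ≈ 16.7% (target 17.0%). The latent NHPI diabetes
probability is 21.5%, so concordantly recorded NHPI persons show the
highest prevalence, which inflow from larger, lower-prevalence groups
then dilutes — the masking structure the analysis is designed to expose.

**What passing tests do and do not show.** The generator reproduces the
*statistical structure* the pipeline assumes: group-dependent
missingness, defect-concentrated discordance, multi-observation census
histories, group-dependent outcomes. It does not emulate real
geography, household response behaviour, temporal drift in
self-identification, care-seeking differences, or linkage error beyond
the injected conflicts — so recovery on synthetic data validates the
pipeline's correctness, not the realism of any substantive conclusion
about real cohorts.

## Validation design and problem sizes

The test suite checks each statistical primitive against an independent
oracle built by a different route: Wilson intervals against a numerical
inversion of the defining score inequality (1,000 random (k, n) pairs,
agreement to 1e-8 or better); the two-proportion test against a
closed-form cell-wise chi-squared computation (1,000 pairs, 1e-10);
classification against brute-force set membership over every
(single race × 2- or 3-race set) pair; the cross-tab against hand
tallies; OLS slopes against the moment-ratio formula; the discrete
Gaussian sampler against its directly normalized pmf (total variation
< 0.01 at σ = 2 over 10⁶ draws, variance within 5% at σ ∈ {1, 2, 5});
and delta-method shift intervals against a person-level cluster
bootstrap (agreement on zero-coverage in ≥ 95% of 100 scenarios).

Parameter recovery runs the full pipeline on 20 seeded cohorts of
100,000 persons and compares observed rates with `expected_rates()`.
Because this produces ~300 individual comparisons, a conjunction of
per-comparison 3-standard-error checks would reject a correct pipeline
about half the time by chance alone; the criterion is therefore
enforced through the sampling distribution of the standardized
deviations — every |z| < 5, at least 98% within 3 (99.7% expected), and
each quantity's 20-seed mean within 3 standard errors of the mean,
which is 4.5× more sensitive to genuine bias than any single-seed
check. Interval calibration uses 200 replicates at n = 5,000. These
sizes are the package's validation design choices; all suites run on a
single CPU.

## Known limitations

* The EHR mapping fixture covers common dialect strings, not any
  specific vendor's full code system; production use should supply a
  site-specific mapping table.
* The crosswalk fixture is deliberately small; unmapped codes are
  counted and dropped, not resolved.
* Partial concordance is directional (census-Multiracial only) by
  default; the mirrored rule changes rates and is clearly flagged.
* The disclosure module is illustrative, with no privacy-budget
  accounting.
* Closed-form expectations require a zero age slope in the outcome
  models; a nonzero slope is supported by the generator but not by
  `expected_rates()`.
* Discordance cannot be decomposed into fluidity versus recording error
  from linked labels alone — the generator models them separately, but
  the pipeline, like any observational analysis, sees only their sum.
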