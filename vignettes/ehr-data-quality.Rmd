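---
title: "Curating multi-site EHR extracts: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating multi-site EHR extracts: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehrcurate)
library(dplyr)
```

## The problem

Pooled electronic health records from dozens of health systems are an
attractive substrate for inpatient drug-effectiveness studies — they carry
vitals and laboratory values that claims data never see — but they inherit
every idiosyncrasy of their contributing sites: variables a source data
model cannot express, missingness that waxes and wanes over calendar time,
drug exposures documented as duplicated single-day rows at one site and as
multi-day intervals (sometimes reversed) at another, patients whose entire
prior medical history lives in another health system, and death dates that
disagree with discharge dates by a day or by a month.

`ehrcurate` implements that curation layer as a set of composable,
tibble-in / tibble-out functions over a small OMOP-like dialect
(`person`, `visit_occurrence`, `drug_exposure`, `measurement`,
`condition_occurrence`, `death`, `concept`, `concept_ancestor`, `site`),
plus a synthetic multi-site generator that plants each of those pathologies
with known ground truth so every stage can be validated end to end without
access to protected data.

Three conventions run through the whole package:

* **day resolution** — all dates are calendar days; timestamps are
  truncated on load, because visit ends and death dates are not reliably
  time-stamped at source;
* **closed intervals** — a one-day exposure has `start == end` and counts
  one exposure day;
* **flag, never silently drop** — invalid rows (reversed intervals, missing
  demographics, broken references) survive loading and are itemized by
  `validate_bundle()`; each analysis stage applies its own documented drop
  rule, mirroring stage-specific cleaning practice.

## Hospital episodes and the cohort

Raw visit tables fragment a single care experience into overlapping
inpatient and emergency rows. `build_macrovisits()` merges, per person, all
inpatient/ED intervals that overlap or sit within `merge_gap_days` empty
days of each other (default 0: overlap or abutting only). The true merge
heuristic used by the source enclave is not public, so this conservative
rule is the documented stand-in and the gap is a parameter. The operation
is idempotent and conserves the union of covered days — both properties are
tested against a brute-force day-enumeration oracle.

`select_cohort()` then applies the study rules: non-missing age and sex;
age at index ≥ 18 (computed as index year − birth year, since the dialect
has no birth day); index date on or after 2020-01-01 (earlier positive
tests are implausible); a first qualifying macrovisit; and stay length
≥ 2 days. Because no published index-to-admission window exists, we
operationalize "hospitalized with COVID-19" as a macrovisit starting within
±14 days of the index date (configurable, `admit_window_days`). Every rule
outcome is a `flag_*` column, so `attrition()` can report a sequential,
monotone attrition table.

## Site fitness screening

`completeness_matrix()` computes, per site and variable, the percentage of
cohort patients with at least one value during their stay;
`temporal_missingness()` the complementary fraction by calendar month of
admission. Screening combines four rules (`apply_exclusion_rules()`):

* mean missingness across the key vitals (SpO2, respiration rate, body
  temperature, heart rate, BMI) above **0.70**;
* mean missing proportion more than **2 population SDs** above the global
  mean;
* *temporal variance* more than 2 population SDs above the global mean
  temporal variance;
* a recorded per-site date shift beyond **7 days** (calendar time is a
  proxy for viral variant and standard-of-care, so shifted sites are
  unusable for time-sensitive questions);
* optionally, falling outside the retained completeness cluster.

"Temporal variance" has no published formula; we define it as the variance
across pandemic months of the site's monthly missing fraction, averaged
over variables. Likewise the two-SD screens are pooled over variables and
applied in **one pass** using moments computed before any exclusion —
iterative re-screening is defensible but was not described, so it is not
done. These are documented choices, not derived ones.

`cluster_sites()` clusters completeness vectors with Euclidean distance and
average linkage (again unstated in the source analysis, hence
configurable), cutting at `k = 2` and retaining the cluster with higher
mean completeness. When every site is identical the population SD is zero
and the strict inequalities fire for nobody — the degenerate case is a
no-op, not an error.

## Drug eras

The OMOP-derived era table merges exposures separated by up to 30 days — a
persistence window built for chronic outpatient dispensing that is
inappropriate for short-term inpatient acute care. `build_drug_eras()`
therefore rebuilds eras from raw rows with gap 0 by default (30 remains one
argument away):

1. drop rows with end before start (logged — these are data errors);
2. treat absent end dates as single-day exposures;
3. deduplicate identical (person, start, end) rows;
4. sort; 5. merge overlap-or-gap ≤ `gap_days`.

The characteristic same-start pair of one bounded one-day row and one
unbounded row needs no special case: rule 2 makes them identical and rule 3
collapses them. Era day-coverage equals the union of the retained rows' day
sets — tested against an enumeration oracle on thousands of randomly
corrupted row sets.

Downstream audits: `concept_distribution()` (how much of an ingredient's
volume is coded at ingredient level, i.e. without dose or route),
`duration_distribution()` with an optional filter dropping patients whose
era ends on discharge or death date, and `claim_inferred_breakdown()`,
which tallies the provenance labels behind single-day eras by site —
single-day courses of a drug with a fixed 5- or 10-day regimen are almost
always billing-inferred artifacts, and heavily concentrated at particular
sites.

## EHR continuity

`months_prior_history()` measures history depth as whole months between the
earliest recorded visit of any kind (no older than the extract's lookback
floor, default 2018-01-01) and the macrovisit start, using a 30.4375-day
month (365.25 / 12; the source defines no month length) and capping at 24
months because the floor makes deeper history unmeasurable. Patients with a
prior visit but less than one month of depth get months = 0 in the
`under_24` group — the group is defined by *having* prior history, the cap
group by `months >= 24`, and the three groups partition the cohort. The
"earliest visit" is strictly before the episode start: same-day records are
part of the episode, not history.

`baseline_covariates()` turns user-supplied concept sets into presence
indicators before admission (medications within a configurable lookback),
plus two visit-level outcomes: ventilation/ECMO within the first 2 days of
the stay, and in-hospital mortality. `smd()` implements the standardized
mean difference — binary
$(p_a-p_b)/\sqrt{(p_a(1-p_a)+p_b(1-p_b))/2}$, continuous
$(m_a-m_b)/\sqrt{(s_a^2+s_b^2)/2}$ — with |SMD| < 0.1 labelled negligible.
It depends only on summary moments, is antisymmetric, and returns exactly 0
for identical groups even when the pooled spread is 0. `history_table()`
renders the stratified baseline table with Kruskal-Wallis / chi-square
p-values from the standard `stats` routines and `"<k"` small-cell
suppression (default 20).

## Outcomes

EHR-only mortality is in-hospital mortality. `classify_mortality()` encodes
the day-resolution reconciliation rule: offsets of −1, 0, +1 day between
death date and visit end are in-hospital deaths (time-of-day rounding);
offsets ≤ −2 are rare data errors, excluded; offsets ≥ +2 are unsystematic
external reports, treated as *not* in-hospital. A death record followed by
any later visit is a billing-style artifact and is likewise classified as a
data error; the asymmetry between the two tails (late ≫ early) is reported
by `death_delta_distribution()` as evidence the tails have different
mechanisms. The 28-day clock for `within_28d` is anchored at the macrovisit
start — the published outcome names no anchor, and admission is the only
date every patient has; the tolerance and horizon are both parameters.

`classify_acute_events()` separates genuine acute events from
carried-forward history by the events-per-day rule: a code on *every* stay
day is history re-recorded daily, not a new event; a first occurrence
before treatment start excludes the patient; anything else on or after
treatment start is an acute post-treatment event. Duplicate codes within a
day are ignored (day-level semantics). `disposition_audit()` quantifies why
composite outcomes like death-or-hospice are rarely feasible: it ranks the
reported discharge dispositions and flags sites that report none.

## What the generator emulates — and what it does not

`simulate_ehr_bundle()` is first-class, tested code, and its defaults *are*
the study conditions the package is built around:

* measurement capture probabilities per variable default to the observed
  non-missing fractions of a hospitalized COVID-19 population (body
  temperature 0.876, creatinine 0.428, PaO2 0.011, ...), scaled across
  sites by a deterministic gradient, with optional per-month multipliers
  for planting temporal missingness spikes; values are log-normal/normal
  around the published medians and IQRs;
* history mixture 30% none / 36% 1-23 months / 34% capped, with comorbidity,
  prior-medication, ventilation and mortality prevalences per history group
  taken from the published stratified table (e.g. hypertension
  0.45 / 0.59 / 0.74);
* drug courses peak at 5 days with a secondary 10-day peak; documentation
  corruption follows the two observed paradigms (`daily_duplicated`,
  `multiday_interval`, or `mixed` per site) with duplicates, open ends and
  reversed pairs; 55% of treated patients are claim-truncated to a
  single-day "Inferred from claim" record, with a 73% target share at one
  designated site;
* death-date offsets concentrate at 0 with a heavier positive tail, plus
  post-discharge death records and occasional after-death billing visits.

Because equal-sized sites cannot always host a 73% share of all truncated
courses, the designated site receives `min(share × total, its treated
count)` and the remainder spreads over the other sites; the ground truth
records the *realized* fraction and share, which is what recovery tests
compare against (the total truncated count, and hence the overall planted
fraction, is preserved).

Comorbidity and prior-medication codes are planted with dates before
admission even for patients with no prior *visits* — history groups are
defined by visits only, which is exactly how real extracts can show
documented comorbidities for patients the continuity metric calls
history-free.

The generator does **not** emulate clinically coherent disease
trajectories, realistic vocabularies beyond a toy concept table, free text,
or within-day timing. Passing parameter-recovery tests therefore
demonstrates that the pipeline measures what was planted under the stated
missingness/corruption mechanisms — not that any particular real-world
extract satisfies those mechanisms.

## Numerical choices and problem sizes

All interval merging works on integer day numbers with a single
running-maximum pass per person (two intervals merge iff
`next_start ≤ running_end + gap + 1`), so results are exact and independent
of input row order; ties are resolved by sorting on (start, end). Month
arithmetic uses `floor(days / 30.4375)`. Population (denominator-n) SDs are
used in the site screens; a zero SD excludes no one. The SMD returns 0 when
both numerator and denominator vanish.

The validation suites run the oracles at 1000 random dirty drug-row sets
and 500 random visit sets, and the parameter-recovery checks at 2000
patients per site (3-site and 20-site designs) under fixed seeds; a full
pipeline on 450 synthetic patients runs in about a second, and the whole
test suite in well under a minute.

## Known limitations

* The macrovisit merge rule and the index-to-admission window are
  documented simplifications of unpublished heuristics; both are parameters.
* Remaining patient-level missingness is profiled, not repaired: multiple
  imputation, inverse-probability weighting and competing-risk survival
  modelling are deliberately out of scope — the pipeline emits the cleaned
  columns those analyses would consume.
* Concept sets are user-supplied configuration; no vocabulary download or
  mapping is performed, and phenotype construction (the index events) is an
  input, not a module.
* Exclusion screening is one-pass; sites near a threshold can flip with the
  cohort, and the 2-SD rules will, by construction, flag ~2.5% tails even
  in homogeneous populations.
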