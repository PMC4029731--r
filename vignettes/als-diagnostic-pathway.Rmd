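---
title: "Methods: claims-based ALS diagnostic-pathway analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: claims-based ALS diagnostic-pathway analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alsclaims)
```

## The problem and the data model

Amyotrophic lateral sclerosis is typically diagnosed a year or more after
its first symptoms. In administrative claims the disease leaves a coded
trail — gait abnormality, muscle weakness, dysphagia, speech disturbance —
that precedes the first claim carrying the ALS diagnosis code (ICD-9-CM
335.20). This package reconstructs that trail in claims shaped like the CMS
Medicare research extracts of the 2005–2009 era, whose defining constraint
is that **services are dated only by calendar quarter**. Every duration in
the package is therefore an integer number of quarters, converted to years
by a factor of 0.25 only at reporting time. Age is the difference between
the quarter's calendar year and the birth year; quarter granularity cannot
resolve mid-year birthdays, and the one-year uncertainty this introduces is
immaterial against a 65-year eligibility threshold.

A dataset is two tables: patient metadata (birth year, enrollment start,
optional death quarter, physician-office-sample flag) and claim lines
(patient, quarter, care setting, code kind, code). Diagnosis codes are
ICD-9-CM; procedure claims carry opaque procedure-group identifiers rather
than real CPT/HCPCS codes, because procedure coding systems are licensed and
the analysis needs only group membership ("a sensory nerve conduction test
happened"), not the billing detail.

## The symptom rule book

The catalog encodes each diagnosis of interest with a likelihood tier
(`high` or `moderate`), an onset category (`bulbar` or `limb`), and one or
more code patterns. A pattern ending in `X` (e.g. `438.1X`, `359.X`) is a
code family: it matches any completion of its prefix, which covers both
fourth- and fifth-digit expansions. Patterns printed without a wildcard
(e.g. `728.2`, `719.4`) are exact, even where ICD-9-CM defines fifth digits
beneath them — the rule book is taken at face value. Undotted claim codes
(`7872`) are normalized by inserting the dot after the third character
(fourth for E-codes), the common form in claims extracts.

The first-symptom rule: scanning quarters in ascending order from
enrollment through the diagnosis quarter *inclusive* (so a zero-quarter
delay is representable), a quarter triggers when it contains

* at least one high-likelihood code, **or**
* codes for **two distinct** moderate-likelihood diagnoses of interest.

"Two distinct" means two different diagnosis-of-interest labels, not two
claims of the same code: repeat billing of one moderate code is weak
evidence and does not trigger. The two moderate diagnoses may fall in any
care settings. Neither rule takes precedence; the onset category is derived
from the union of all definitions matched in the triggering quarter, which
is what makes a concurrent `both` onset (limb and bulbar in one quarter)
expressible. Only the bulbar/limb rule-book definitions participate in
onset detection; the broader reporting groups (nerve, respiratory, other)
are descriptive.

Two layout ambiguities in the source table were resolved as follows: throat
pain (784.1) is listed among the bulbar high-likelihood rows without its own
tier cell and is encoded high/bulbar; and late-effect dysphagia (438.82)
shares the "Dysphagia" label, so it contributes both to onset detection and
to the dysphagia reporting group.

## Cohorts and the attrition funnel

The ALS cohort requires, in order: a first 335.20 claim inside the
diagnosis window (default Q1 2007–Q4 2009); at least two 335.20 claim
*lines* inside that window (the published rule counts claims in the window;
`count_claims_in_window = FALSE` counts all claims, and whether the two
claims must fall in distinct quarters is not specified — we count lines);
age ≥ 65 at the index quarter; ≥ 8 whole quarters between enrollment start
and the index quarter ("two years or more", at the only resolution
available); and membership in the physician-office sample. The diagnosis
quarter is fixed as the quarter of the first 335.20 claim before any
criterion is evaluated, so each criterion is a pure per-patient predicate
and the surviving set is independent of application order; only the
attrition counts depend on it. The time-to-diagnosis subcohort further
requires the index event in Q1 2008–Q4 2009, guaranteeing at least three
years of lookback. The comparison cohort excludes the whole 335.* family,
not just 335.20: a patient with any motor-neuron-disease claim would
contaminate the reference rates.

Windows are stored as calendar quarter labels (`"2007Q1"`) and converted
using the dataset's epoch, so the same criteria apply to real-era data
(epoch 2005) and to synthetic data with longer pre-periods (epoch 2000).

## Prevalence rate ratios

For each symptom/diagnosis group, the ALS percentage counts patients with at
least one matching claim in the 8 quarters ending the quarter *before*
diagnosis; the comparison percentage uses the fixed calendar window Q1
2008–Q4 2009 (comparison patients have no index event to anchor on). The
ratio is computed on **unrounded** percentages and rounded half-up to one
decimal only for display: several published rows (speech disturbance
24/2 printed as 15) are irreconcilable with rounded inputs, which shows the
original computation also divided unrounded values; consequently the
package's regression tests assert only the rows whose printed ratio is
consistent with its printed inputs. A zero comparison percentage yields an
infinite ratio flagged `undefined` rather than an error; 0/0 yields a
flagged 0. Reported rows satisfy prevalence ≥ 10% *or* ratio ≥ 5
(inclusive thresholds, ordered by descending ratio, stable for ties), and
the filter is idempotent.

Medians of quarter-valued durations use midpoint interpolation for even
counts, so values off the quarter grid (2.88 years) are legitimate outputs;
display rounding is half-up to two decimals. Whole-percent displays also
round half-up — base R's round-half-even would disagree on exact halves.

## Diagnostic usage tables

Symptom lag rows anchor on the first occurrence of the *specific* code
group, independent of the onset rule (a lone moderate code defines its own
symptom's lag even though it cannot trigger onset), binned 0–3 / 4–7 / 8–11
/ 12+ quarters. Test utilization counts each patient once per test group in
the same 8-quarter window, and reports the median time to diagnosis among
patients *with* the test; the median is suppressed as "not determined" when
fewer than `min_n` patients contribute. The suppression threshold is
configurable with default 11, chosen so that subgroup cells around 10–12% of
a ~45-patient subgroup — the pattern seen in the published
electromyography rows — are representable as suppressed; the original
suppression rule is not stated. Whether the published test-table medians
anchor on first symptom or elsewhere is also not stated; the package
anchors on the onset call, consistent with the symptom tables.

## The synthetic generator

The generator emulates the *structure* the analysis assumes, with known
ground truth: quarterly claim bundles across inpatient/outpatient/office
settings; an index 335.20 event (two claim lines) in the diagnosis window;
an onset quarter at `diagnosis − lead` carrying one high-likelihood code of
the planted category (a limb + bulbar pair for `both`); planted
pre-diagnosis symptom-group claims; background symptom rates in comparison
patients; and per-onset-type diagnostic-test claims.

Key parameter choices:

* **Onset mix** defaults to 74/17/8 limb/bulbar/both (renormalized), the
  reported composition of the source cohort.
* **Lead times** are geometric — memoryless, one parameter, a deliberately
  conservative single-parameter choice since only medians are reported for
  the source cohort — parameterized by their target median: 10 quarters
  (limb), 5 (bulbar), 1 (both), i.e. 2.5, 1.25 and 0.25 years. Tests assert
  recovery of what was planted, not of any external value.
* **Background rates** are 8-quarter period prevalences taken from the
  general-Medicare column of the published tables, converted to per-quarter
  Bernoulli rates via `r = 1 − (1 − p)^{1/8}` so the planted period
  prevalence over any 8-quarter window equals the target.
* **Simulation epoch** is Q1 2000 with the diagnosis window kept at
  Q1 2007–Q4 2009: the seven extra pre-period years make truncation of
  geometric lead times at enrollment rare, so planted medians are cleanly
  recoverable. (Real extracts begin in 2005; the synthetic pre-period is
  deliberately longer.)
* **Planting scope**: by default, ALS patients receive pre-diagnosis
  symptom claims only for groups whose codes *cannot* fire the onset rule
  (decided by pattern-overlap against the rule book). Injecting
  onset-capable codes at their population rates would silently re-date
  roughly a fifth of planted onsets, making planted parameters
  unrecoverable and every downstream test uninterpretable. Setting
  `als_background_groups = "all"` turns that false-trigger pressure on
  deliberately — the onset calls may then only move earlier, a property the
  test suite checks — and `"none"` disables planting.

The generator does **not** emulate: billing idiosyncrasies (revenue centers,
adjudication), mortality and censoring, enrollment churn, correlated
comorbidity structure, code miscoding/specificity error, or seasonal claim
intensity. Passing recovery tests therefore demonstrates that the pipeline
measures what the rules define on data of this shape — not that the rule
book is clinically valid on real claims, which required expert review in
the original design.

A fixed seed makes output byte-identical; all randomness flows from
`simulation_config(seed = ...)`.

## Problem sizes and determinism

The test suite exercises the oracle-equivalence property on ~1,100 random
claim histories against a naive per-quarter re-classification oracle, and
full-pipeline parameter recovery at n_als = 300 / n_background = 3,000 —
the package's standard demonstration scale, which keeps per-category
subgroups large enough for 3-standard-error recovery bounds while a full
simulate-and-analyze cycle stays under half a minute. At this scale the
per-category median time to diagnosis sits on a 0.25-year grid and its
sampling distribution at ~30-patient subgroups spans neighboring grid
points; recovery tests therefore compare pipeline output to the *planted
ground truth* of the same patients (exact under default planting) rather
than to the theoretical distribution median.

Everything downstream of the generator is deterministic: fixed inputs and
configuration produce byte-identical report bundles.

## Known limitations

* ICD-9-CM only; no ICD-10 mapping.
* Quarter granularity caps timing resolution at ±1 quarter everywhere and
  makes age exact only to the year.
* Exact patterns printed without wildcards do not match their ICD-9-CM
  fifth-digit children; this is faithful to the printed rule book, not to
  the coding hierarchy.
* The comparison cohort is unmatched (no age/sex standardization), as in
  the original design; prevalence ratios are descriptive, with no
  interval estimates or hypothesis tests.
* Reported onset-mix percentages use patients with a classified onset as
  the primary denominator; the all-patients denominator is also reported,
  since the source's percentages (summing to 99%) do not disambiguate.
```{r}
sessionInfo()
```
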