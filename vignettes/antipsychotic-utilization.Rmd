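---
title: "Antipsychotic drug-utilization analysis with ATC/DDD standardization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Antipsychotic drug-utilization analysis with ATC/DDD standardization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxddd)
```

## The measurement model

Psychiatric inpatient units prescribe antipsychotics across many chemicals,
routes and formulations, so raw milligram doses are not comparable between
drugs. `rxddd` standardizes prescriptions in the way drug-utilization
research does:

* **ATC coding.** Every drug is identified by its WHO Anatomical Therapeutic
  Chemical code. Antipsychotics are the `N05A` group *minus* the `N05AN`
  chemical subgroup: the ATC files lithium under `N05A`, but lithium is not
  an antipsychotic, so it is carved out at the subgroup level.
* **DDD.** Each drug *presentation* — the `(ATC, route, form)` triple — has a
  defined daily dose in mg/day, the WHO's assumed maintenance dose. Route
  and form are part of the registry key because the same chemical carries
  different DDDs by presentation (oral risperidone 5 mg/day, the long-acting
  injectable 2.7 mg/day). The shipped registry covers the 18 antipsychotic
  presentations of the reference inpatient cohort; it is fixture-defined
  rather than pinned to a particular WHO index year, and users can supply
  their own delimited-text registry to extend or update it.
* **PDD.** The prescribed daily dose is what clinicians actually ordered.
  Daily schedules contribute `dose × times_per_day` mg/day; depot
  (long-acting injectable) orders are spread uniformly over their injection
  interval in calendar days, `dose / interval_days`, deliberately ignoring
  pharmacokinetics — 25 mg of fluphenazine every 28 days is 0.89 mg/day.
* **PDD/DDD.** Dose intensity is the cohort mean PDD divided by the DDD. A
  ratio strictly greater than 1.5 is classified as *excessive dosing*; the
  threshold is strict (a drug at exactly 1.50 is not flagged) and is applied
  to the unrounded ratio.

### Per-patient PDD

A patient's PDD for one presentation is computed from a day-by-day ledger:
each calendar day's doses of that presentation are summed (overlapping
orders of the same drug add), and the average is taken **over exposed days
only** — days with a nonzero dose — not over the whole admission. Averaging
over the full stay would deflate the PDD below any dose that was actually
prescribed, which contradicts its reading as a dose-intensity measure; this
choice is a package decision, since "average daily dose prescribed" admits
both readings. Date ranges are inclusive at both ends (a one-day order is
one exposed day), and dose titration is represented as consecutive orders
rather than an intra-order taper syntax.

### Confidence intervals and display

Per-drug 95% CIs on the mean PDD are t-based (`mean ± t(0.975, n−1)·sd/√n`).
The CI method is a documented choice: with n = 1 or zero variance the
interval collapses to a point, which is consistent with any mean±margin
method. All internal computation is unrounded; display rounding is half
away from zero (doses and ratios at 2 dp, percentages at 1 dp). Half-away
matters: 290/400 = 0.725 must display as 0.73, where banker's rounding
would give 0.72.

## Polypharmacy detection

Antipsychotic polypharmacy (APP) is the concurrent use of two or more
antipsychotic *chemicals* by one patient. Two design points matter:

* **Agents, not formulations.** Concurrency is counted at the level-7 ATC
  chemical, so oral plus depot risperidone is one agent. This follows the
  APP literature's convention.
* **Overlap granularity.** One calendar day of shared activity makes two
  agents concurrent by default. `min_overlap_days` raises the number of
  consecutive shared days required, which treats short cross-taper switches
  as sequential rather than concurrent; the default of 1 day is the
  strictest reading.

The implementation merges each chemical's prescription ranges into interval
unions and runs an event sweep; a brute-force day-enumeration oracle checks
it on randomized instances in the test suite. A depot injection is active
from injection through its interval, consistent with the dosing ledger.

Regimens are `none`, `monotherapy` or `polypharmacy` (ever ≥ 2 concurrent).
`antipsychotic_only` separately records whether antipsychotics were the only
psychotropics prescribed, covering the alternative reading of "polytherapy"
as any psychotropic combination. Where a source reports both an APP
prevalence from its regimen table and a different narrative percentage, the
package follows the table definition.

## Diagnoses, age bands and off-label screening

ICD-10 codes map to the F-chapter decade blocks used in the report tables
(F00–F09 organic, F10–F19 substance use, F20–F29 schizophrenia and other
psychoses, F30–F39 mood, F40–F49 anxiety-related, F60–F69 personality);
remaining F blocks and non-F chapters pool into `other`. Age bands are
half-open with the boundary ascending — [18,35), [35,50), [50,65), [65,∞) —
a convention that must be fixed explicitly because printed band headers
commonly overlap at the boundaries (35 appearing in two columns).

Off-label screening is driven by an editable policy table rather than
hard-coded rules, because operational off-label criteria differ by
jurisdiction and study. The shipped default is a conservative surrogate:
psychotic-spectrum diagnoses (F20–F29) license every antipsychotic,
quetiapine is additionally allowed in mood disorders, and anything else is
off-label. Growing the policy's allowed sets can only shrink the off-label
share (tested as a monotonicity property). The flags carry a rationale:
`psychotic_diagnosis`, `approved_nonpsychotic` or `no_eligible_diagnosis`.

## Cohort tables

`analyze_cohort()` assembles three tables. Table 1 (demographics ×
diagnosis) reports, per category, within-category age-band and sex
distributions with Pearson chi-square P values computed without continuity
correction — the default tests each category against the rest of the cohort
(2×k tables), with a `test_scope = "global"` variant testing the full
category-by-band table, since either reading is defensible. Small expected
counts produce a warning, not a fallback test. Table 2 (diagnosis × regimen)
partitions patients into single-diagnosis strata, named comorbidity pairs
and catch-alls, so stratum sizes always sum to the cohort size. Table 3 is
the per-drug utilization table described above; its prescription count is
patient-presentation exposures by default (a cohort of 217 patients with 365
"prescriptions" averages ~1.7 drugs per patient, which is exposure counting),
with raw order counting available via `count_mode = "order"`.

## The synthetic cohort generator

`generate_cohort()` exists so every pipeline stage can be exercised without
patient-level data, which for this kind of inpatient prescription register
is never published. Its defaults emulate a two-unit brief psychiatric
inpatient cohort of 353 adults:

* diagnosis category weights from the single-diagnosis mix of such a cohort
  (psychoses ≈ 0.42, mood ≈ 0.28, anxiety ≈ 0.10, personality ≈ 0.09,
  substance use ≈ 0.07), a comorbidity probability of 0.312, and age/sex
  mixes of 27.3/35.5/27.3/9.9% across bands and 48.7% female;
* per-category antipsychotic use probabilities (1.0 for psychoses, 0.74 for
  mood, 0.57 for personality, 0.50 for substance use, 0.21 for
  anxiety-related), combined for comorbid patients as the maximum across
  their categories; a polypharmacy probability of 0.369 among users; and a
  0.714 probability of a concomitant non-antipsychotic psychotropic;
* per-drug prescription frequencies and target mean PDD/DDD multipliers
  taken from the shipped utilization table, with daily doses drawn
  lognormally (`sigma = 0.4`) around `ratio × DDD` — doses are positive and
  right-skewed, which is why means exceed medians for most drugs in real
  utilization tables; stays are 7–30 days and depot orders use a 28-day
  interval.

Because the per-category use rule takes the maximum over a comorbid
patient's categories, the default emergent cohort-wide use share is higher
than the 61.5% such a cohort reports overall (whose comorbid catch-all
stratum contained no users); passing `use_prob = 0.615` reproduces the
headline share directly and is what the recovery checks use. Generation is
deterministic given the seed, and the generator emits exactly the file
formats the readers consume, making it the integration-test driver.

What passing tests on synthetic cohorts do **not** show: real prescription
data contain titrations, mid-stay switches, PRN orders, documentation
errors and diagnosis revisions that the generator does not emulate. The
generator validates the arithmetic and the classification logic, not the
package's robustness to messy registers.

`fixture_table3_cohort()` complements the stochastic generator with a
hand-built deterministic mini-cohort whose exposures land exactly on several
reference utilization rows (eleven clozapine patients with mean 345.45
mg/day and ratio 1.15; one ziprasidone patient at exactly ratio 1.50; three
fluphenazine depot patients at 0.89 mg/day).

## Problem sizes and numerical choices

The test suite runs the randomized concurrency cross-check on 500 small
instances, dose-mean recovery on an 800-patient cohort, and binomial
parameter recovery on 5000-patient cohorts at three probability settings,
checking observed counts against 99% binomial bands; these sizes give tight
checks while keeping the whole suite around a minute on one CPU. Degenerate
inputs are defined rather than left to error: empty prescription lists
yield flagged no-exposure results, an empty cohort yields a zero-total
table, zero-user drugs are omitted from APP shares, and a zero denominator
yields an undefined-percent sentinel (`NA`).

## Known limitations

* No dose-equivalence conversion between chemicals (e.g. chlorpromazine
  equivalents); PDD/DDD is the only cross-drug scale.
* Depot conversion is calendar-day uniform; no pharmacokinetic modelling or
  loading-dose regimens.
* The off-label policy is a surrogate, not a regulatory label database.
* DDD units are mg/day only.
* The registry ships one route per presentation as observed in the reference
  cohort; users needing other presentations must extend the registry file.
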