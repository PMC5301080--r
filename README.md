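# rxddd

Drug-utilization analytics for psychiatric inpatient cohorts, built on
ATC/DDD standardization.

Pharmacoepidemiology studies of antipsychotic prescribing need raw
prescription registers turned into comparable, cohort-level measures.
`rxddd` implements that pipeline for tabular inputs (patients, ICD-10
diagnoses, prescriptions):

* **ATC/DDD standardization** — a validating parser for WHO Anatomical
  Therapeutic Chemical codes and a drug registry keyed by presentation
  `(ATC, route, form)`, since oral and long-acting forms of one chemical
  carry different defined daily doses (DDD). Antipsychotics are `N05A`
  excluding the lithium subgroup `N05AN`.
* **Prescribed daily dose (PDD)** — a day-ledger average of what was
  actually ordered, per patient and presentation, over exposed days. Depot
  injections spread uniformly over their interval: 25 mg every 28 days is
  0.89 mg/day.
* **Dose intensity** — per-drug mean PDD with t-based 95% CI and the
  PDD/DDD ratio; a ratio strictly above 1.5 flags *excessive dosing*.
* **Antipsychotic polypharmacy (APP)** — temporal-overlap detection of ≥ 2
  concurrent antipsychotic chemicals (formulations of one chemical count
  once), with a configurable cross-taper tolerance, plus per-drug APP
  shares.
* **Off-label screening** — antipsychotic orders checked against an
  editable policy table mapping ATC prefixes to licensed diagnosis
  categories.
* **Cohort reports** — demographics × diagnosis (with Pearson chi-square),
  diagnosis × regimen, and per-drug utilization tables, as CSV/JSON.
* **Synthetic cohorts** — a seeded generator emulating a brief inpatient
  unit (diagnosis mix, per-category antipsychotic use, mono/polytherapy
  split, lognormal doses centered on multiples of DDD), so the whole
  pipeline is testable without patient data.

## Worked example

```r
library(rxddd)

fx <- fixture_table3_cohort() # deterministic mini-cohort
rep <- analyze_cohort(fx$patients, fx$diagnoses, fx$prescriptions)
print(rep)
```

```
Cohort report: 21 patients, 21 antipsychotic users (100.0%), 21 prescriptions
Regimens: 21 monotherapy, 0 polypharmacy

Drug utilization (PDD in mg/day, displayed at 2 dp):
  n                     drug     atc ddd_mg median_pdd mean_pdd            ci ratio excessive
  2              Amisulpride N05AL05  400.0     800.00   800.00       800-800  2.00      TRUE
 11                Clozapine N05AH02  300.0     350.00   345.45 271.17-419.74  1.15     FALSE
  3             Fluphenazine N05AB02    1.0       0.89     0.89     0.89-0.89  0.89     FALSE
  1 Long-acting paliperidone N05AX13    2.5       3.57     3.57     3.57-3.57  1.43     FALSE
  1  Long-acting risperidone N05AX08    2.7       7.14     7.14     7.14-7.14  2.64      TRUE
  1              Ziprasidone N05AE04   80.0     120.00   120.00       120-120  1.50     FALSE
  2   Zuclopenthixol acufase N05AF05   30.0      25.00    25.00         25-25  0.83     FALSE
```

Reading the rows: eleven clozapine patients average 345.45 mg/day against a
DDD of 300 mg/day, a dose intensity of 1.15 — above the maintenance
assumption but not excessive. The two amisulpride patients at 800 mg/day
are at twice the DDD and flagged. Ziprasidone at exactly 1.50 is *not*
flagged: the excessive threshold is strict. Single-patient drugs collapse
to point confidence intervals.

For a stochastic cohort at realistic scale:

```r
co <- generate_cohort(cohort_spec(n_patients = 353, seed = 42, use_prob = 0.615))
rep <- analyze_cohort(co$patients, co$diagnoses, co$prescriptions)
rep$headline
rep$table2          # diagnosis strata vs mono/polytherapy
rep$app_shares      # share of each drug's users in polypharmacy
write_report(rep, "out/")
```

Command-line wrappers live in `inst/cli/`:

```sh
Rscript inst/cli/simulate.R --seed 42 --out cohort/
Rscript inst/cli/analyze.R --patients cohort/patients.csv \
  --diagnoses cohort/diagnoses.csv --prescriptions cohort/prescriptions.csv \
  --out report/
```

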