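# rxfill

Linking EHR prescribing data to pharmacy dispensing records, and analyzing
what the link reveals about primary medication nonadherence.

## The problem

Electronic health records say which medications were *prescribed*; they
usually do not say whether the prescription was ever *filled*. Dispensing
feeds (e.g. from e-prescribing networks) close that gap, but they speak a
different ontology: prescribing records carry RxNorm concept identifiers
(RxCUIs), dispensing records carry National Drug Codes (NDCs), and one RxCUI
maps to many NDCs. Studies that treat a prescription as medication receipt
misclassify every patient who never picked the drug up — and those patients
differ systematically from the ones who did.

`rxfill` implements the full analysis pipeline for this setting, aimed at
pharmacoepidemiologists working with EHR + dispensing extracts:

1. **Vocabulary** — an RxCUI→NDC crosswalk with 11-digit (5-4-2) NDC
   normalization and ingredient-token drug-name validation.
2. **Linkage** — greedy earliest-first, strictly one-to-one matching of each
   prescription to the nearest compatible fill on or after the prescribing
   date, then a day-cutoff label (default 30 days; a same-day fill is day 0).
3. **Cohort** — new-user (incident-user) design: earliest in-window
   outpatient prescription per patient, a 12-month washout over both
   prescriptions and fills, an under-18 age restriction, and a
   data-completeness filter requiring a later encounter.
4. **Covariates** — 22 contextual variables per member, including PHQ-9
   severity (0-4 nonminimal, 5-9 mild, 10-14 moderate, 15-19 moderately
   severe, 20-27 severe; "Not taken" when none within the 2 weeks before
   the index date).
5. **Balance** — standardized mean differences between fillers and
   non-fillers: `|p1 − p2| / sqrt((p1(1−p1) + p2(1−p2))/2)` for binary
   covariates, `|m1 − m2| / sqrt((s1² + s2²)/2)` for continuous ones, and the
   Mahalanobis-type `sqrt(Tᵀ S⁻¹ T)` form for multicategory ones; SMD > 0.10
   flags imbalance.
6. **Propensity & outcomes** — a lasso (L1-penalized logistic) propensity
   model for fill status with a stratified 9:1 train/test split and 5-fold
   cross-validated penalty, held-out AUROC, ATE inverse-probability weights
   `1/e(x)` and `1/(1−e(x))`, Kaplan-Meier curves, and marginal / IPW-weighted
   Cox hazard ratios (Efron ties; robust sandwich variance under weighting)
   for time to a follow-up visit with the prescribing provider, censored at
   90 days.

Because real prescribing/dispensing extracts are protected health data, the
package ships a **synthetic data generator** (`generate_population()`) that
emulates the study structure with known ground truth — a covariate-driven
fill process, a fill-delay distribution massed at day 0, decoy and missed
dispensings, and a proportional-hazards follow-up process — so every stage
is testable end to end.

## Worked example

```r
library(rxfill)

report <- run_pipeline(pipeline_config(
  sim = sim_config(n_patients = 1254, seed = 2021),
  propensity = propensity_options(seed = 2021)
))
print(report)
#> rxfill pipeline report
#>   cohort: 1084 patients; 775 (71.5%) filled within 30 days
#>   among matched fills: 80.5% same-day, 91.0% within 7 days
#>   covariates flagged imbalanced (SMD > 0.10): 13 of 22
#>   propensity test AUROC: 0.841
#>   Marginal HR 1.521 (95% CI 1.259-1.838), 609 events / 1084 subjects
#>   IPW-weighted HR 1.621 (95% CI 1.230-2.138), 609 events / 1084 subjects
```

Reading the output: of 1254 simulated patients, 1084 survive the washout and
completeness filters; 71.5% of the cohort filled within the 30-day cutoff,
and among matched fills 80.5% were dispensed on the prescribing day. The
lasso model separates fillers from non-fillers well (held-out AUROC 0.841)
because the generator's default fill model is covariate-driven, so the
balance table flags many covariates as imbalanced. Fillers return to their
prescriber sooner (marginal HR 1.52); the generator's true hazard ratio is
1.5, and with no simulated confounding of the follow-up process the weighted
and unweighted estimates agree within sampling error.

The attrition log and full balance table are in the report:

```r
attrition_log(report$cohort)
#>   stage                    n_before n_after
#> 1 index candidates             1254    1254
#> 2 washout                      1254    1184
#> 3 age < 18                     1184    1184
#> 4 capture-window encounter     1184    1084
report$balance          # 22-row SMD table
plot_km(report$km_followup)   # follow-up curves by fill status
```

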