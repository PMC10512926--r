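# renangia

Renal angina index scoring and severe-AKI screening evaluation for
pediatric intensive-care cohorts.

## The problem

Serum creatinine rises late in acute kidney injury (AKI), so by the time a
PICU patient meets KDIGO criteria the window for prevention has often
closed. The **renal angina index (RAI)** is a day-of-admission screen that
combines AKI *risk* (why the child is in the ICU) with early *injury*
signals (a small creatinine rise, fluid accumulation) to identify children
at risk of **severe AKI (sAKI; KDIGO stage ≥ 2) on day 3** — and, because
of its high negative predictive value, to rule it out cheaply in
low-resource units. This package is for clinical researchers validating
the RAI (or a locally re-weighted variant) in their own cohort: it
implements the score, the outcome adjudication, and the complete
diagnostic-precision toolkit, plus a synthetic cohort generator so every
step is testable without patient data.

## The score

For each admission, on day 0:

- **Risk** = the highest applicable stratum: ICU admission → 1, solid-organ
  / stem-cell transplant → 3, mechanical ventilation *and* vasopressor
  support within 8 h → 5.
- **Injury** = max of two tiers:
  - creatinine ratio ΔSCr = SCr(enrollment)/SCr(baseline): 1 → 1,
    (1, 1.5) → 2, [1.5, 2) → 4, ≥ 2 → 8;
  - percent fluid overload %FO = (fluid in − fluid out)/weight × 100:
    <5% → 1, [5,10)% → 2, [10,15)% → 4, ≥15% → 8 (creatinine tier alone
    when fluids were not charted).
- **RAI = Risk × Injury**, positive at **RAI ≥ 8**.

When no baseline creatinine is on record it is imputed from height by
assuming a normal clearance of 120 mL/min/1.73 m²:
BSCr = k·height/120 with the Schwartz constant k = 36.5 µmol/L·cm⁻¹.

The **modified RAI (mRAI)** replaces the risk maximum with the **sum** of
locally derived risk-factor weights and uses the creatinine tier only:
mRAI = (Σ applicable weights) × creatinine score. The engine is
weight-agnostic — supply any named weight set via `score_config()`.

Screens are evaluated against day-3 sAKI with sensitivity, specificity,
PPV and NPV, each with an *untruncated* Wald 95% CI (p ± 1.96·√(p(1−p)/n);
bounds may exceed 100% at small n, as such tables are printed), cutoff
scans with Youden's J = sens + spec − 1, empirical ROC curves with the
tie-corrected Mann–Whitney AUC, and the DeLong test for paired AUCs.

## Worked example

```r
library(renangia)

# a septic, ventilated infant on pressors, no baseline creatinine on file
rec <- list(age_years = 0.8, sex = "male", height_cm = 70, weight_kg = 8,
            diagnosis_category = "sepsis", mechanical_ventilation_8h = TRUE,
            vasopressor_support_8h = TRUE, d0_scr_umol_l = 38,
            fluid_in_l_8h = 0.9, fluid_out_l_8h = 0.4)
compute_rai(rec)
#> Renal angina index
#>   creatinine ratio: 1.785 (baseline imputed from height)
#>   fluid overload:    6.2%
#>   risk 5 x injury 4 = 20  ->  POSITIVE
```

The imputed baseline is 36.5·70/120 = 21.3 µmol/L, so 38 µmol/L on
admission is a 1.79× rise (injury 4); full organ support gives risk 5;
20 ≥ 8 flags renal angina.

A whole cohort, end to end (here the bundled fixed-margin synthetic
cohort, which reproduces the contingency structure of a 122-admission
validation cohort):

```r
coh    <- generate_cohort(cohort_config(fixed_margins = TRUE), seed = 1)
scored <- score_cohort(coh)
adj    <- adjudicate_cohort(coh)
summary(adj)
#> Adjudicated cohort: 122 admissions
#>   KDIGO stages:  0:94  1:10  2:12  3:6
#>   any AKI:    28 (23.0%)
#>   severe AKI: 18 — prevalence 14.8 (8.5–21.0)%

screening_metrics(confusion_matrix(scored$rai_positive, adj$saki))
#> Screening metrics (95% wald CI, percent):
#>   sensitivity  55.6 (32.6–78.5)  [n=18]
#>   specificity  85.6 (78.8–92.3)  [n=104]
#>   ppv          40.0 (20.8–59.2)  [n=25]
#>   npv          91.8 (86.3–97.2)  [n=97]
```

A positive screen catches 10 of 18 sAKI cases (sensitivity 55.6%), but a
negative screen is reassuring: 89 of 97 screen-negative children stay free
of sAKI (NPV 91.8%). `run_pipeline(pipeline_config(...))` does all of the
above plus subgroup tables, cutoff scans, ROC points and a DeLong
comparison, writing CSVs and a JSON run summary; the same pipeline is
scriptable via `inst/cli/renangia.R
(score|adjudicate|evaluate|simulate|run)`.

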