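---
title: "Methods: renal angina scoring, severe-AKI adjudication, and screening evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: renal angina scoring, severe-AKI adjudication, and screening evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(renangia)
```

This vignette documents the models and conventions the package implements,
the free design choices that had to be made where the published definitions
leave room, and what the synthetic-data machinery does and does not
establish about real cohorts.

## The index

The renal angina index treats early AKI prediction like chest-pain triage:
a patient "fulfils renal angina" when *risk of* AKI and *early signs of*
AKI coincide. Formally, on day 0 of PICU admission,

$$\mathrm{RAI} = R \times I, \qquad R \in \{1, 3, 5\},\; I \in \{1, 2, 4, 8\},$$

with positivity at $\mathrm{RAI} \ge 8$. $R$ is the highest applicable
risk stratum (ICU admission 1; transplant history 3; mechanical
ventilation *plus* vasopressor support within 8 h of admission 5) and $I$
the worse of two injury signals:

* the creatinine ratio $\Delta\mathrm{SCr} =
  \mathrm{SCr}_{d0}/\mathrm{BSCr}$, tiered
  $1 \to 1$, $(1, 1.5) \to 2$, $[1.5, 2) \to 4$, $\ge 2 \to 8$;
* percent fluid overload
  $\%\mathrm{FO} = 100\,(\text{in} - \text{out})/\text{weight}$ over the
  first 8 h, tiered $<5 \to 1$, $[5,10) \to 2$, $[10,15) \to 4$,
  $\ge 15 \to 8$.

**Tier boundary convention.** Creatinine tiers are closed on the left and
open on the right, matching the strata in which validation cohorts are
reported ("1.5x–1.99", "≥2x"): a ratio of exactly 1.5 scores 4, exactly
2.0 scores 8. A ratio of exactly 1 ("no change") scores 1, and any rise,
however small, enters the 2-tier — the day-0-above-baseline criterion
evaluated by the diagnostics module is exactly `delta_scr > 1`.

**Units.** Creatinine is µmol/L throughout (a `scr_mgdl_to_umol()`
conversion is provided at the I/O boundary only); fluids are litres and
weight kilograms, which puts %FO on the clinical 0–25 % scale.

**Missing fluid charting** is a supported state, not an error: the injury
score degrades to the creatinine tier alone and the result carries an
`fo_available = FALSE` flag so reports can count degraded scores.
Incomplete intake/output documentation affects the majority of records in
the kind of unit this package targets, so silently treating missing fluid
as zero overload would bias the index downward invisibly.

**Baseline imputation.** When no baseline creatinine was measured in the
90 days before admission, it is imputed by inverting the Schwartz
creatinine-clearance estimate at an assumed normal clearance:
$\mathrm{BSCr} = k \cdot \mathrm{height} / \mathrm{eCrCl}_0$ with
$k = 36.5$ µmol/L·cm⁻¹ (the mg/dL constant 0.413 × 88.4) and
$\mathrm{eCrCl}_0 = 120$ mL/min/1.73 m². Both constants are exposed in
`score_config()` because the clearance assumption, not the arithmetic, is
the scientific content. The imputation is linear in height and
inverse-linear in the assumed clearance, which the test suite asserts
analytically.

## The modified index

A locally re-weighted variant replaces the risk maximum by a **sum** of
condition weights and drops the fluid signal:
$\mathrm{mRAI} = \left(\sum_{c \in \text{applicable}} w_c\right) \times
I_{\Delta\mathrm{SCr}}$. The engine is deliberately weight-agnostic: the
risk-condition registry (`risk_conditions()`) maps condition names to
predicates on the cohort table, and any named positive weight vector is
accepted. The bundled `mrai_local` preset carries *placeholder* weights
for the locally relevant factors (sepsis, severe malaria, infancy, organ
support) — a unit validating its own derivation should substitute its own
weights. We chose not to reverse-engineer a specific published weight set
from its achievable-score list: such lists are empirical (they contain
only score values observed in that cohort) and do not uniquely determine
the weights, so any reconstruction would be false precision. Instead,
`enumerate_achievable_scores()` brute-forces the exact achievable set for
*any* configuration over all risk-factor subsets (with ICU admission
mandatory), and the property tests pin the scoring engine to that oracle.

Whether a patient with both creatinine and fluid signals should take the
max or the sum of tiers is convention, not mathematics; the max is the
published RAI semantics and is what `injury_score()` implements (and the
tests assert the combined score *is* the max of the single-signal scores).

## Severe-AKI adjudication

The day-3 outcome is KDIGO-based: stage 1 at ratio $[1.5, 2)$ or an
absolute rise ≥ 26.5 µmol/L within 48 h; stage 2 at ratio $[2, 3)$ or
oliguria; stage 3 at ratio ≥ 3 or renal replacement therapy. Severe AKI is
stage ≥ 2.

Two readings required a decision:

* **"200 % of baseline".** A creatinine "increase of 200 % from baseline"
  can be read as *reaching* 2× baseline or as *rising by* 200 % (i.e.
  3×). We adopt 2×: it is the KDIGO stage-2 wording ("2.0–2.9 times
  baseline"), and the 3× reading would leave stage 2 empty of
  creatinine-only cases. Equivalently, a ≥ 50 % fall in estimated
  clearance is the same criterion, since height-based eCrCl is
  proportional to 1/SCr at fixed height; the test suite asserts the two
  formulations coincide on random inputs.
* **Oliguria duration.** The cohort definition this package targets uses
  ≤ 0.5 mL/kg/h sustained ≥ 8 h as a severe criterion, shorter than the
  guideline's ≥ 12 h for stage 2. The 8-h rule is the default
  (`uo_rule = "cohort"`); the guideline thresholds (including stage-1 and
  stage-3 oliguria bands) are available with `uo_rule = "kdigo"`.

Records without urine-output documentation are staged on creatinine alone;
the 48-h absolute-rise criterion is skipped when no 48-h-spaced pair
exists (a day-0/day-3 pair is not one). When several criteria yield the
same stage the reported `basis` follows the fixed order creatinine ratio >
urine output > absolute rise > RRT — reporting only; the stage is the max.

## Screening evaluation

`screening_metrics()` computes sensitivity, specificity, PPV and NPV with
**untruncated Wald** intervals $p \pm 1.96\sqrt{p(1-p)/n}$. Untruncated is
deliberate: at $n = 18$ a sensitivity of 88.9 % has an upper bound of
103.4 %, and clinical validation tables print exactly that. Back-
calculation from such printed bounds is in fact how the CI method used by
the tables this package validates against was identified. Wilson
intervals, which respect $[0, 1]$, are available via
`ci_method = "wilson"` but are not the default because the package's
output is meant to be diffable against the published style. Percentages
round half-up to 1 decimal place, Youden's index and AUCs to 2 — half-up,
not banker's rounding, again to match clinical table conventions
(`round_half_up()`).

`cutoff_scan()` evaluates `score >= cutoff` (higher score = more
diseased, the ROC direction used throughout) and reports Youden's
$J = \text{sens} + \text{spec} - 1$ per cutoff; the optimum takes the
*smallest* cutoff on ties, favouring sensitivity, which is the correct
bias for a rule-out screen.

`roc_emp()` builds the empirical ROC over all distinct score values and
computes the AUC by the tie-corrected Mann–Whitney statistic from
mid-ranks — identical to the $O(n^2)$ concordance count
$\Pr(X > Y) + \tfrac12 \Pr(X = Y)$, which the tests verify on random tied
instances up to $n = 50$ and against the independent `pROC`
implementation.

`delong_test()` implements the DeLong comparison of two paired AUCs from
placement values, with the degenerate case (identical scores, zero
variance) defined as an exact tie ($z = 0$, $p = 1$). It is cross-checked
against `pROC::roc.test` and against a stratified paired bootstrap.

## The synthetic cohort generator

`generate_cohort()` synthesizes admissions **score-first**: severe-AKI
status, renal-angina positivity, and a (creatinine-tier, risk-stratum)
pair consistent with that positivity are sampled, and creatinine values
are then constructed backward (day-0 = baseline × a ratio drawn strictly
inside the sampled tier; day-3 realizes the sampled KDIGO stage). The
point of this inversion is exactness: re-scoring and re-adjudicating a
generated cohort must recover the sampled labels with zero mismatches
(`round_trip_check()`), making the generator a self-validating fixture for
the whole pipeline. Charted fluids are kept inside the lowest overload
tier so fluid data never flips a sampled label, and charted urine output
is non-oliguric except in dialysed patients.

Default parameters are the margins of a 122-admission PICU validation
cohort: prevalence 18/122, positivity 10/18 given severe AKI and 15/104
otherwise, 29.5 % infants, CNS-dominant diagnoses, conditional mortality
7/18 and 13/104, 61.5 % missing fluid charting. In **fixed-margin mode**
the generator abandons sampling of the discrete structure and constructs
the exact 8-cell table (severe AKI × positivity × creatinine tier) whose
margins reproduce that cohort's 2×2 tables — RAI (10/15/8/89), elevated
day-0 creatinine (16/2/66/38), mortality (7/13/11/91) — together with 10
non-severe stage-1 patients, one dialysed child, ventilation/vasopressor
counts, and 13 of 18 severe-AKI children aged ≤ 5 years. Published strata
for that cohort are not perfectly mutually consistent (the ΔSCr strata
imply one more elevated-creatinine patient than the elevated-D0 row, and
three different under-5 severe-AKI counts are implied in different
places); the fixed-margin construction privileges the 2×2 tables, which
are the quantities the evaluation pipeline is validated against, and lets
the stratum counts float within them.

Free distributional choices, made once: heights and weights come from
coarse pediatric growth approximations (infants 50 + 25·age cm, older
children 75 + 6·(age−1) cm; weight 2·(age+4) kg) — adequate for baseline
imputation, not growth standards; PICU length of stay is
3 + NegBin(size 2.2, µ 3.4) days (median ≈ 6, floor at the 72-h inclusion
criterion) and ventilation days 1 + NegBin(size 1.5, µ 3) among
ventilated children. A single root seed spawns fixed per-variable
substreams, so the same seed yields an identical cohort and editing one
block of the generator does not reshuffle the others.

**What passing tests do and do not show.** The generator emulates the
*contingency structure* of a real cohort, not renal physiology: no
sepsis-to-AKI causal pathway, no fluid-therapy dynamics, no measurement
error in creatinine, and diagnosis is sampled independently of positivity
within severe-AKI strata (the joint distribution is not published). Green
tests therefore establish that the scoring, adjudication and evaluation
machinery is mathematically correct and reproduces published tables from
their underlying counts — they say nothing about how the index performs
in any new population. Cohort-level AUCs for real data (reported as 0.77
for the RAI in the cohort whose margins we use) are *not* reproduced,
because patient-level scores were never published; the package instead
validates its AUC/DeLong machinery by oracle equivalence and bootstrap
agreement, and its reconstructed-cohort AUCs (≈ 0.79–0.80) are reported
for orientation only.

## Problem sizes and numerical tolerances

The test and acceptance workloads were sized for desk-scale re-runs: the
fixed-margin cohort is n = 122 by definition; oracle AUC checks use 60
random instances with n ≤ 50; the DeLong-vs-bootstrap comparison uses one
n = 200 cohort with 10,000 stratified resamples; round-trip sweeps cover
100 seeds; stochastic convergence is checked at n = 10,000 with a
3-binomial-SE band. Exact quantities (counts, metrics from counts, tier
assignments) are asserted exactly; only the bootstrap comparison carries a
stochastic tolerance (10 % relative on z).

## Known limitations

* The bundled modified-index weights are placeholders, not a validated
  local derivation.
* Day-0 urine output does not enter the injury score (creatinine and
  fluid overload only), and the adjudicator sees only the day-3
  urine-output summary, not an hourly record.
* No CKD screening or neonatal creatinine adjustments: the eligibility
  window is 1 month–16 years by design.
* Logistic-regression odds ratios for sAKI predictors are out of scope;
  published unadjusted ORs for this design are not reconcilable with
  their own 2×2 counts, and the regression specification is not
  recoverable.
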