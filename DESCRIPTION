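Package: renangia
Title: Renal Angina Index Scoring and Severe-AKI Screening Evaluation for PICU Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Computes the renal angina index (RAI) and a locally modified
    variant (mRAI) for pediatric intensive-care admissions, adjudicates
    day-3 severe acute kidney injury (KDIGO stage >= 2) from serum
    creatinine, urine output and dialysis use, and evaluates any score
    against that outcome with screening metrics (sensitivity, specificity,
    PPV, NPV with untruncated Wald intervals), cutoff scans with Youden's
    index, empirical ROC curves with Mann-Whitney AUC, and the DeLong
    paired-AUC test. Includes a seedable synthetic PICU-cohort generator
    with an exact fixed-margin mode reproducing the contingency structure
    of a 122-admission validation cohort, plus a CSV pipeline and
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
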