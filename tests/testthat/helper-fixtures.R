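# small builders used across test files

one_patient <- function(...) {
  rec <- list(
    patient_id = "P1", age_years = 4, sex = "female", height_cm = 100,
    weight_kg = 16, diagnosis_category = "CNS", icu_admission = TRUE,
    transplant_history = FALSE, mechanical_ventilation_8h = FALSE,
    vasopressor_support_8h = FALSE, baseline_scr_umol_l = 30,
    d0_scr_umol_l = 30, d3_scr_umol_l = 30,
    fluid_in_l_8h = NA_real_, fluid_out_l_8h = NA_real_,
    d3_urine_output_ml_kg_h = NA_real_, d3_urine_output_duration_h = NA_real_,
    died_in_picu = FALSE, picu_los_days = 5, ventilation_days = 0,
    received_rrt = FALSE
  )
  mod <- list(...)
  rec[names(mod)] <- mod
  as.data.frame(rec, stringsAsFactors = FALSE)
}

# O(n^2) concordance oracle for the AUC: fraction of (diseased,
# non-diseased) pairs ranked correctly, ties counted one half
auc_oracle <- function(scores, outcomes) {
  x <- scores[outcomes]; y <- scores[!outcomes]
  mean(outer(x, y, ">") + 0.5 * outer(x, y, "=="))
}

# stratified paired bootstrap of an AUC difference; returns the z statistic
# observed_diff / sd(bootstrap diffs)
bootstrap_delong_z <- function(scores_a, scores_b, outcomes, reps = 10000, seed = 42) {
  set.seed(seed)
  pos <- which(outcomes); neg <- which(!outcomes)
  obs <- roc_emp(scores_a, outcomes)$auc - roc_emp(scores_b, outcomes)$auc
  auc_fast <- function(s, o) {
    r <- rank(s, ties.method = "average")
    np <- sum(o)
    (sum(r[o]) - np * (np + 1) / 2) / (np * sum(!o))
  }
  diffs <- vapply(seq_len(reps), function(i) {
    idx <- c(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
    o <- outcomes[idx]
    auc_fast(scores_a[idx], o) - auc_fast(scores_b[idx], o)
  }, numeric(1))
  obs / stats::sd(diffs)
}
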