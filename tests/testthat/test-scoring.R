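test_that("baseline imputation follows the assumed-clearance formula", {
  cfg <- score_config()
  expect_equal(impute_baseline_scr(120, cfg), 36.5)  # height equals eCrCl: k
  expect_equal(impute_baseline_scr(110, cfg), 36.5 * 110 / 120)
  expect_error(impute_baseline_scr(0), "height_cm")
  expect_error(impute_baseline_scr(-5), "height_cm")

  # linear in height, inverse-linear in the assumed clearance
  h <- c(60, 90, 150)
  expect_equal(impute_baseline_scr(2 * h, cfg), 2 * impute_baseline_scr(h, cfg))
  cfg240 <- score_config(assumed_ecrcl = 240)
  expect_equal(impute_baseline_scr(h, cfg240), impute_baseline_scr(h, cfg) / 2)
})

test_that("creatinine ratio and percent fluid overload follow their definitions", {
  expect_equal(delta_scr(48.0, 28.7), 48.0 / 28.7)
  expect_equal(delta_scr(37.5, 37.5), 1.0)
  expect_equal(delta_scr(70.2, 35.1), 2.0)
  expect_error(delta_scr(0, 30), "enrollment_scr")
  expect_error(delta_scr(30, -1), "baseline_scr")

  expect_equal(percent_fluid_overload(1.0, 0.6, 10), 4.0)
  expect_equal(percent_fluid_overload(0.8, 0.8, 12), 0.0)
  expect_equal(percent_fluid_overload(2.0, 0.0, 8), 25.0)
  expect_equal(percent_fluid_overload(0.2, 0.9, 10), -7.0)  # net diuresis
  # missing fluid charting yields NA, never zero
  expect_true(is.na(percent_fluid_overload(NA, 0.5, 10)))
  expect_true(is.na(percent_fluid_overload(1, NA, 10)))
  expect_error(percent_fluid_overload(1, 0.5, 0), "weight_kg")
})

test_that("risk score: highest stratum originally, sum of weights when modified", {
  base <- one_patient()
  expect_equal(risk_score(base), 1)  # ICU admission alone
  expect_equal(risk_score(one_patient(transplant_history = TRUE)), 3)
  vent_vaso <- one_patient(mechanical_ventilation_8h = TRUE,
                           vasopressor_support_8h = TRUE)
  expect_equal(risk_score(vent_vaso), 5)
  # ventilation without pressors does not reach the top stratum
  expect_equal(risk_score(one_patient(mechanical_ventilation_8h = TRUE)), 1)
  # transplant + full support: max, not sum
  both <- one_patient(transplant_history = TRUE, mechanical_ventilation_8h = TRUE,
                      vasopressor_support_8h = TRUE)
  expect_equal(risk_score(both), 5)

  mcfg <- score_config("mrai_local")
  expect_equal(risk_score(base, mcfg), 1)
  septic_infant <- one_patient(diagnosis_category = "sepsis", age_years = 0.5)
  expect_equal(risk_score(septic_infant, mcfg), 1 + 4 + 2)
  expect_error(risk_score(base, structure(list(risk_weights = numeric(0)),
                                          class = "score_config")),
               "risk_weights")
})

test_that("injury score maps tiers correctly and is the max of the two signals", {
  cfg <- score_config()
  expect_equal(injury_score(1.0, NA, cfg), 1L)    # no change
  expect_equal(injury_score(1.2, NA, cfg), 2L)
  expect_equal(injury_score(1.5, NA, cfg), 4L)    # boundary closed on the left
  expect_equal(injury_score(1.7, NA, cfg), 4L)
  expect_equal(injury_score(1.999, NA, cfg), 4L)  # open on the right
  expect_equal(injury_score(2.0, NA, cfg), 8L)
  expect_equal(injury_score(1.2, 16, cfg), 8L)    # fluid tier dominates
  expect_equal(injury_score(1.2, 7, cfg), 2L)     # creatinine tier dominates
  expect_equal(injury_score(1.0, 12, cfg), 4L)
  expect_error(injury_score(0, NA, cfg), "delta_scr")

  # property: the combined score IS the max of the single-signal scores,
  # and is monotone in the creatinine ratio
  set.seed(7)
  for (i in 1:200) {
    d <- runif(1, 0.5, 3.5); fo <- runif(1, -2, 25)
    expect_identical(injury_score(d, fo, cfg),
                     max(injury_score(d, NA, cfg),
                         tier_lookup(fo, cfg$injury_fo_tiers)))
  }
  d <- sort(runif(100, 0.5, 3.5))
  expect_true(all(diff(injury_score(d, NA, cfg)) >= 0))
})

test_that("the index multiplies risk by injury and flags positivity at the cutoff", {
  # risk 1, injury 8 (ratio doubled): positive at the default cutoff
  r <- compute_rai(one_patient(d0_scr_umol_l = 60))
  expect_equal(r$rai, 8)
  expect_true(r$positive)
  # risk 1, injury 4: below the cutoff
  r <- compute_rai(one_patient(d0_scr_umol_l = 51))
  expect_equal(r$rai, 4)
  expect_false(r$positive)
  # maximum product 40
  r <- compute_rai(one_patient(d0_scr_umol_l = 66, mechanical_ventilation_8h = TRUE,
                               vasopressor_support_8h = TRUE))
  expect_equal(r$rai, 40)
  expect_true(r$positive)

  # baseline imputed from height when not recorded, and flagged
  rec <- one_patient(baseline_scr_umol_l = NA_real_, height_cm = 120,
                     d0_scr_umol_l = 36.5)
  r <- compute_rai(rec)
  expect_true(r$imputed_baseline)
  expect_equal(r$delta_scr, 1.0)
  # neither baseline nor height: error names both fields
  expect_error(compute_rai(one_patient(baseline_scr_umol_l = NA_real_,
                                       height_cm = NA_real_)),
               "baseline_scr_umol_l and height_cm")
  expect_error(compute_rai(one_patient(d0_scr_umol_l = NA_real_)), "d0_scr_umol_l")
})

test_that("modified index: risk sum times the creatinine tier, fluid ignored", {
  mcfg <- score_config("mrai_local")
  rec <- one_patient(diagnosis_category = "sepsis", age_years = 0.5,
                     d0_scr_umol_l = 60, fluid_in_l_8h = 3, fluid_out_l_8h = 0.1)
  r <- compute_mrai(rec, mcfg)
  expect_equal(r$risk_score, 7)       # 1 + sepsis 4 + infant 2
  expect_equal(r$injury_score, 8L)    # ratio 2.0; %FO 18% must NOT enter
  expect_equal(r$rai, 56)
  # same record under the original index picks up the fluid tier
  expect_equal(compute_rai(rec)$injury_score, 8L)
  expect_error(compute_mrai(rec, score_config("rai_original")), "mrai_mode")
})

test_that("score_cohort is consistent with the per-record path and carries flags", {
  coh <- generate_cohort(cohort_config(n_patients = 40), seed = 11)
  s <- score_cohort(coh)
  expect_s3_class(s, "rai_scored")
  expect_equal(s$rai, s$risk_score * s$injury_score)
  expect_equal(s$rai_positive, s$rai >= 8)
  for (i in c(1, 7, 23)) {
    r <- compute_rai(coh[i, ])
    expect_equal(r$rai, s$rai[i])
    expect_equal(r$positive, s$rai_positive[i])
  }
  # undocumented fluid degrades to creatinine-only scoring, flagged not fatal
  expect_true(any(!s$fo_available))
  expect_false(any(is.na(s$injury_score)))
})

test_that("achievable-score enumeration matches a brute-force subset oracle", {
  cfg <- score_config()
  # independent oracle: direct product set over attainable risk maxima
  oracle <- sort(unique(as.vector(outer(c(1, 3, 5), c(1, 2, 4, 8)))))
  expect_equal(enumerate_achievable_scores(cfg), oracle)
  # every positive original score at the default cutoff
  expect_equal(oracle[oracle >= 8], c(8, 10, 12, 20, 24, 40))

  expect_equal(enumerate_achievable_scores(
    score_config(risk_weights = c(icu_admission = 1),
                 injury_dscr_tiers = data.frame(lower = -Inf, score = 1),
                 injury_fo_tiers = data.frame(lower = -Inf, score = 1))), 1)

  # sum mode: exhaustive subset enumeration oracle
  mcfg <- score_config("mrai_local", risk_weights = c(icu_admission = 1, sepsis = 1,
                                                      ventilation = 2))
  sums <- unique(c(1, 1 + 1, 1 + 2, 1 + 1 + 2))
  inj <- c(1, 2, 4, 8)
  expect_equal(enumerate_achievable_scores(mcfg),
               sort(unique(as.vector(outer(sums, inj)))))

  # cohort scores always land in the achievable set (scoring never invents values)
  coh <- generate_cohort(cohort_config(n_patients = 300), seed = 3)
  expect_true(all(score_cohort(coh)$rai %in% enumerate_achievable_scores(cfg)))
})

test_that("score configs validate and round-trip through YAML presets", {
  expect_error(score_config(risk_weights = c(icu_admission = -1)), "positive")
  expect_error(score_config(risk_weights = c(not_a_condition = 2)), "unknown risk")
  expect_error(score_config(injury_dscr_tiers = data.frame(lower = c(1, 0.5),
                                                           score = c(2, 4))),
               "increasing")

  for (preset in c("rai_original", "mrai_local")) {
    path <- system.file("extdata", paste0(preset, ".yaml"), package = "renangia")
    cfg <- read_score_config(path)
    ref <- score_config(preset)
    expect_equal(cfg$risk_weights[sort(names(cfg$risk_weights))],
                 ref$risk_weights[sort(names(ref$risk_weights))])
    expect_equal(cfg$mrai_mode, ref$mrai_mode)
    expect_equal(cfg$injury_dscr_tiers$score, ref$injury_dscr_tiers$score)
  }
})
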