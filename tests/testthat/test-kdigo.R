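test_that("staging follows the creatinine, urine-output and dialysis criteria", {
  a <- kdigo_stage(30, 66)          # ratio 2.2
  expect_equal(a$stage, 2L)
  expect_true(a$severe)
  expect_equal(a$basis, "creatinine_ratio")

  a <- kdigo_stage(30, 48)          # ratio 1.6: stage-1 entry
  expect_equal(a$stage, 1L)
  expect_false(a$severe)

  expect_equal(kdigo_stage(30, 44)$stage, 0L)        # ratio < 1.5
  expect_equal(kdigo_stage(30, 45)$stage, 1L)        # exactly 1.5
  expect_equal(kdigo_stage(30, 90)$stage, 3L)        # ratio 3.0
  expect_equal(kdigo_stage(30, 60)$stage, 2L)        # exactly 2.0

  # oliguria >= 8 h is severe under the cohort rule even with flat creatinine
  a <- kdigo_stage(30, 30, uo_ml_kg_h = 0.3, uo_duration_h = 10)
  expect_true(a$severe)
  expect_equal(a$basis, "urine_output")
  # ... but not under the guideline rule, which needs 12 h for stage 2
  expect_false(kdigo_stage(30, 30, uo_ml_kg_h = 0.3, uo_duration_h = 10,
                           uo_rule = "kdigo")$severe)
  expect_true(kdigo_stage(30, 30, uo_ml_kg_h = 0.3, uo_duration_h = 13,
                          uo_rule = "kdigo")$severe)

  # 48-h absolute rise reaches stage 1 only, and is skipped when unavailable
  expect_equal(kdigo_stage(30, 40, scr_rise_48h_umol = 27)$stage, 1L)
  expect_equal(kdigo_stage(30, 40, scr_rise_48h_umol = NA)$stage, 0L)
  # dialysis is stage 3 regardless of creatinine
  a <- kdigo_stage(30, 30, received_rrt = TRUE)
  expect_equal(a$stage, 3L)
  expect_equal(a$basis, "rrt")
  # the creatinine criterion is reported when it ties for the top stage
  expect_equal(kdigo_stage(30, 95, received_rrt = TRUE)$basis, "creatinine_ratio")

  expect_error(kdigo_stage(0, 30), "baseline_scr")
  expect_error(kdigo_stage(30, -1), "current_scr")
})

test_that("staging invariants: severity definition, monotonicity, clearance equivalence", {
  set.seed(21)
  ratios <- runif(300, 0.5, 4)
  base <- runif(300, 15, 80)
  st <- kdigo_stage(base, base * ratios)
  expect_identical(st$severe, st$stage >= 2L)

  # monotone in the ratio for fixed other inputs
  ord <- order(ratios)
  expect_true(all(diff(st$stage[ord]) >= -1e-9 | diff(ratios[ord]) == 0))
  expect_true(all(diff(kdigo_stage(50, 50 * sort(ratios))$stage) >= 0))

  # the eCrCl-halving reading of severe AKI coincides with ratio >= 2 when
  # clearance is inversely proportional to creatinine at fixed height
  height <- runif(300, 55, 165)
  k <- 36.5
  ecrcl_base <- k * height / base
  ecrcl_d3 <- k * height / (base * ratios)
  halved <- ecrcl_d3 <= 0.5 * ecrcl_base
  expect_identical(halved, ratios >= 2)
})

test_that("cohort adjudication reports prevalence and requires day-3 creatinine", {
  coh <- generate_cohort(cohort_config(fixed_margins = TRUE), seed = 5)
  adj <- adjudicate_cohort(coh)
  expect_equal(sum(adj$saki), 18)
  expect_equal(sum(adj$aki_stage >= 1), 28)
  pr <- attr(adj, "prevalence")
  expect_equal(round_half_up(100 * pr$estimate, 1), 14.8)
  expect_equal(round_half_up(100 * mean(adj$aki_stage >= 1), 1), 23.0)
  expect_true(pr$ci_low < pr$estimate && pr$estimate < pr$ci_high)
  expect_identical(adj$saki, adj$aki_stage >= 2L)

  none <- coh
  none$d3_scr_umol_l <- NA_real_
  expect_error(adjudicate_cohort(none), "d3_scr_umol_l")
  some <- coh
  some$d3_scr_umol_l[c(3, 9)] <- NA_real_
  expect_error(adjudicate_cohort(some), "row")
  expect_error(adjudicate_cohort(coh[0, ]), "no rows")

  # all-quiescent cohort: zero prevalence
  quiet <- coh
  quiet$d3_scr_umol_l <- quiet$baseline_scr_umol_l
  quiet$d3_scr_umol_l[is.na(quiet$d3_scr_umol_l)] <-
    36.5 * quiet$height_cm[is.na(quiet$d3_scr_umol_l)] / 120
  quiet$received_rrt <- FALSE
  quiet$d3_urine_output_ml_kg_h <- NA_real_
  expect_equal(attr(adjudicate_cohort(quiet), "prevalence")$estimate, 0)
})
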