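test_that("confusion matrices cross-tabulate predictions against the outcome", {
  cm <- confusion_matrix(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(unlist(cm[c("tp", "fp", "fn", "tn")]), c(tp = 1, fp = 1, fn = 1, tn = 1))
  perfect <- confusion_matrix(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE))
  expect_equal(perfect$fp + perfect$fn, 0)
  expect_error(confusion_matrix(logical(0), logical(0)), "non-empty")
  expect_error(confusion_matrix(c(TRUE), c(TRUE, FALSE)), "lengths")
  expect_error(confusion_counts(2, -1, 0, 3), "non-negative")
})

test_that("screening metrics use the untruncated Wald interval", {
  m <- screening_metrics(confusion_counts(tp = 10, fp = 15, fn = 8, tn = 89))
  est <- round_half_up(100 * m$estimate, 1)
  expect_equal(est, c(55.6, 85.6, 40.0, 91.8))

  # small-n sensitivity: upper bound exceeds 100% (untruncated by design)
  m2 <- screening_metrics(confusion_counts(tp = 16, fp = 66, fn = 2, tn = 38))
  expect_equal(round_half_up(100 * m2$estimate[1], 1), 88.9)
  expect_equal(round_half_up(100 * m2$ci_low[1], 1), 74.4)
  expect_equal(round_half_up(100 * m2$ci_high[1], 1), 103.4)
  expect_gt(m2$ci_high[1], 1)
  # interval width is symmetric: 2 * 1.96 * SE
  se <- sqrt(m2$estimate * (1 - m2$estimate) / m2$n)
  expect_equal(m2$ci_high - m2$ci_low, 2 * 1.96 * se, tolerance = 1e-3)

  # Wilson alternative stays inside [0, 1]
  w <- screening_metrics(confusion_counts(tp = 16, fp = 66, fn = 2, tn = 38),
                         ci_method = "wilson")
  expect_lte(max(w$ci_high), 1)
  expect_gte(min(w$ci_low), 0)

  # perfect classifier: all four metrics 100%
  p <- screening_metrics(confusion_counts(tp = 5, fp = 0, fn = 0, tn = 7))
  expect_equal(p$estimate, rep(1, 4))
  # zero denominator: that metric undefined, others still present
  z <- screening_metrics(confusion_counts(tp = 0, fp = 0, fn = 3, tn = 9))
  expect_true(is.na(z$estimate[z$metric == "ppv"]))
  expect_equal(z$estimate[z$metric == "npv"], 0.75)
})

test_that("cutoff scan computes Youden's index and breaks ties toward sensitivity", {
  rs <- mrai_reference_scores()
  cuts <- c(4, 6, 8, 10, 12, 14, 20, 28, 40)
  sc <- cutoff_scan(rs$score, rs$saki, cuts)
  expect_equal(round_half_up(sc$youden[sc$cutoff == 10], 2), 0.42)
  expect_equal(round_half_up(sc$youden[sc$cutoff == 8], 2), 0.53)
  expect_equal(attr(sc, "best_cutoff"), 8)
  # J column consistent with its own sens/spec columns
  expect_equal(sc$youden, sc$sensitivity + sc$specificity - 1)
  # perfect classifier: J = 1 at the separating cutoff
  ps <- cutoff_scan(c(1, 1, 5, 5), c(FALSE, FALSE, TRUE, TRUE), c(1, 3, 5))
  expect_equal(max(ps$youden), 1)
  # tie broken toward the smallest cutoff
  tie <- cutoff_scan(c(1, 1, 5, 5), c(FALSE, FALSE, TRUE, TRUE), c(2, 3, 4))
  expect_equal(attr(tie, "best_cutoff"), 2)
  expect_error(cutoff_scan(1:3, c(TRUE, FALSE, TRUE), numeric(0)), "non-empty")
})

test_that("metrics are invariant under permutation of patient order", {
  set.seed(9)
  n <- 60
  scores <- sample(c(1, 2, 4, 8, 20, 40), n, replace = TRUE)
  out <- runif(n) < 0.3
  out[1] <- TRUE; out[2] <- FALSE
  perm <- sample.int(n)
  expect_equal(roc_emp(scores[perm], out[perm])$auc, roc_emp(scores, out)$auc)
  m1 <- screening_metrics(confusion_matrix(scores >= 8, out))
  m2 <- screening_metrics(confusion_matrix(scores[perm] >= 8, out[perm]))
  expect_equal(m1$estimate, m2$estimate)
  d1 <- delong_test(scores, scores + runif(n), out)
  d2 <- delong_test(scores[perm], (scores + runif(n))[perm], out[perm])
  expect_equal(d1$auc_a, d2$auc_a)
})

test_that("subgroup filtering preserves order and flags empty selections", {
  coh <- generate_cohort(cohort_config(fixed_margins = TRUE), seed = 1)
  adj <- adjudicate_cohort(coh)
  under5 <- subgroup_filter(adj, function(d) d$age_years <= 5)
  expect_equal(sum(under5$saki), 13)   # 13 of the 18 severe-AKI children
  expect_equal(attr(under5, "n_selected"), nrow(under5))
  expect_identical(under5$patient_id,
                   adj$patient_id[adj$age_years <= 5])

  all_rows <- subgroup_filter(coh, function(d) rep(TRUE, nrow(d)))
  expect_equal(nrow(all_rows), nrow(coh))
  expect_warning(none <- subgroup_filter(coh, function(d) rep(FALSE, nrow(d))),
                 "no records")
  expect_equal(nrow(none), 0)
  expect_error(subgroup_filter(coh, function(d) 1:3), "logical")
})
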