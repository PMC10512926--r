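#' Confusion matrix of a binary screen against severe AKI
#'
#' @param predicted logical vector (screen positive).
#' @param outcome logical vector (severe AKI), same length; `TRUE` is the
#'   diseased class.
#' @return object of class `"confusion"` with counts `tp`, `fp`, `fn`,
#'   `tn`.
#' @examples
#' confusion_matrix(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, FALSE))
#' @export
confusion_matrix <- function(predicted, outcome) {
  if (length(predicted) == 0 || length(outcome) == 0)
    stop_invalid("predicted/outcome", "must be non-empty")
  if (length(predicted) != length(outcome))
    stop_invalid("predicted/outcome", "lengths differ")
  predicted <- as.logical(predicted); outcome <- as.logical(outcome)
  if (any(is.na(predicted)) || any(is.na(outcome)))
    stop_invalid("predicted/outcome", "contain missing values")
  structure(list(
    tp = sum(predicted & outcome), fp = sum(predicted & !outcome),
    fn = sum(!predicted & outcome), tn = sum(!predicted & !outcome)
  ), class = "confusion")
}

#' Build a confusion object from raw counts
#'
#' @param tp,fp,fn,tn non-negative integer counts.
#' @return a `"confusion"` object.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop_invalid("counts", "must be non-negative integers")
  structure(as.list(counts), class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(screen = c("positive", "negative"),
                              outcome = c("sAKI", "no sAKI")))
  print(m)
  invisible(x)
}

binom_ci <- function(p, n, method = c("wald", "wilson"), conf = 0.95) {
  method <- match.arg(method)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  if (method == "wald") {
    # deliberately untruncated: bounds may leave [0, 1]
    half <- z * sqrt(p * (1 - p) / n)
    c(p - half, p + half)
  } else {
    d <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / d
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / d
    c(centre - half, centre + half)
  }
}

#' Screening metrics with confidence intervals
#'
#' Sensitivity, specificity, PPV and NPV from a confusion matrix, each with
#' a 95% binomial interval. The default is the untruncated Wald form
#' `p +/- 1.96 sqrt(p(1-p)/n)` — bounds may exceed \[0, 100\]% at small n,
#' as clinical tables often print them; Wilson intervals are available via
#' `ci_method`. A metric whose denominator is zero is returned as `NA`
#' (undefined); the others are still computed.
#'
#' @param cm a `"confusion"` object.
#' @param ci_method `"wald"` (default) or `"wilson"`.
#' @param conf confidence level.
#' @return object of class `"screen_metrics"`: a data.frame with one row
#'   per metric (`estimate`, `ci_low`, `ci_high` as proportions, `n` the
#'   denominator).
#' @examples
#' screening_metrics(confusion_counts(tp = 10, fp = 15, fn = 8, tn = 89))
#' @export
screening_metrics <- function(cm, ci_method = c("wald", "wilson"), conf = 0.95) {
  ci_method <- match.arg(ci_method)
  stopifnot(inherits(cm, "confusion"))
  num <- c(sensitivity = cm$tp, specificity = cm$tn, ppv = cm$tp, npv = cm$tn)
  den <- c(sensitivity = cm$tp + cm$fn, specificity = cm$fp + cm$tn,
           ppv = cm$tp + cm$fp, npv = cm$fn + cm$tn)
  est <- ifelse(den > 0, num / den, NA_real_)
  ci <- t(vapply(seq_along(est), function(i) {
    if (is.na(est[i])) c(NA_real_, NA_real_) else binom_ci(est[i], den[i], ci_method, conf)
  }, numeric(2)))
  out <- data.frame(metric = names(num), estimate = unname(est),
                    ci_low = ci[, 1], ci_high = ci[, 2], n = unname(den),
                    row.names = NULL)
  structure(out, conf = conf, ci_method = ci_method, confusion = cm,
            class = c("screen_metrics", "data.frame"))
}

#' @export
print.screen_metrics <- function(x, ...) {
  cat(sprintf("Screening metrics (%.0f%% %s CI, percent):\n",
              100 * attr(x, "conf"), attr(x, "ci_method")))
  for (i in seq_len(nrow(x))) {
    if (is.na(x$estimate[i])) {
      cat(sprintf("  %-12s undefined (denominator 0)\n", x$metric[i]))
    } else {
      cat(sprintf("  %-12s %s  [n=%d]\n", x$metric[i],
                  fmt_pct_ci(100 * x$estimate[i], 100 * x$ci_low[i],
                             100 * x$ci_high[i]), x$n[i]))
    }
  }
  invisible(x)
}

#' Scan cutoffs of an integer or continuous score
#'
#' For each cutoff, patients with `score >= cutoff` are screen-positive;
#' the screening metrics and Youden's index `J = sensitivity +
#' specificity - 1` are tabulated. The optimal cutoff maximises J, ties
#' broken toward the smallest cutoff (favouring sensitivity in a screening
#' context).
#'
#' @param scores numeric score per patient.
#' @param outcomes logical severe-AKI indicator, same length.
#' @param cutoffs cutpoints to evaluate (non-empty).
#' @param ci_method passed to [screening_metrics()].
#' @return object of class `"cutoff_scan"`: data.frame with one row per
#'   cutoff (`cutoff`, `tp`, `fp`, `fn`, `tn`, `sensitivity`,
#'   `specificity`, `ppv`, `npv` with CI columns, `youden`), attribute
#'   `best_cutoff`.
#' @examples
#' rs <- mrai_reference_scores()
#' cutoff_scan(rs$score, rs$saki, c(4, 6, 8, 10, 12, 14, 20, 28, 40))
#' @export
cutoff_scan <- function(scores, outcomes, cutoffs, ci_method = "wald") {
  if (length(cutoffs) == 0) stop_invalid("cutoffs", "must be non-empty")
  if (length(scores) != length(outcomes))
    stop_invalid("scores/outcomes", "lengths differ")
  cutoffs <- sort(unique(cutoffs))
  rows <- lapply(cutoffs, function(k) {
    cm <- confusion_matrix(scores >= k, outcomes)
    m <- screening_metrics(cm, ci_method = ci_method)
    data.frame(cutoff = k, tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn,
               sensitivity = m$estimate[1], sens_lo = m$ci_low[1], sens_hi = m$ci_high[1],
               specificity = m$estimate[2], spec_lo = m$ci_low[2], spec_hi = m$ci_high[2],
               ppv = m$estimate[3], ppv_lo = m$ci_low[3], ppv_hi = m$ci_high[3],
               npv = m$estimate[4], npv_lo = m$ci_low[4], npv_hi = m$ci_high[4],
               youden = m$estimate[1] + m$estimate[2] - 1)
  })
  tab <- do.call(rbind, rows)
  best <- tab$cutoff[which.max(tab$youden)]  # which.max takes the first (smallest) on ties
  structure(tab, best_cutoff = best, class = c("cutoff_scan", "data.frame"))
}

#' @export
print.cutoff_scan <- function(x, ...) {
  cat("Cutoff scan (score >= cutoff is screen-positive):\n")
  cat(sprintf("  %-8s %-18s %-18s %-18s %-18s %s\n",
              "cutoff", "sens", "spec", "PPV", "NPV", "Youden"))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  >= %-5g %-18s %-18s %-18s %-18s %.2f\n", x$cutoff[i],
                fmt_pct_ci(100 * x$sensitivity[i], 100 * x$sens_lo[i], 100 * x$sens_hi[i]),
                fmt_pct_ci(100 * x$specificity[i], 100 * x$spec_lo[i], 100 * x$spec_hi[i]),
                fmt_pct_ci(100 * x$ppv[i], 100 * x$ppv_lo[i], 100 * x$ppv_hi[i]),
                fmt_pct_ci(100 * x$npv[i], 100 * x$npv_lo[i], 100 * x$npv_hi[i]),
                round_half_up(x$youden[i], 2)))
  }
  cat("optimal cutoff (max Youden, ties -> smallest): >=", attr(x, "best_cutoff"), "\n")
  invisible(x)
}

#' Empirical ROC curve and Mann-Whitney AUC
#'
#' Operating points over every distinct score value (threshold rule:
#' `score >= threshold` is positive; higher scores mean more diseased).
#' The AUC is the Mann-Whitney statistic with ties counted one half,
#' computed from mid-ranks.
#'
#' @param scores numeric score per patient.
#' @param outcomes logical severe-AKI indicator.
#' @return object of class `"emp_roc"`: `thresholds`, `sensitivity`,
#'   `specificity` vectors (including the degenerate all-positive and
#'   all-negative ends), `auc`, `n_pos`, `n_neg`.
#' @examples
#' r <- roc_emp(c(1, 2, 3), c(FALSE, FALSE, TRUE))
#' r$auc  # 1: perfect separation
#' @export
roc_emp <- function(scores, outcomes) {
  if (length(scores) != length(outcomes))
    stop_invalid("scores/outcomes", "lengths differ")
  outcomes <- as.logical(outcomes)
  if (any(is.na(scores)) || any(is.na(outcomes)))
    stop_invalid("scores/outcomes", "contain missing values")
  n_pos <- sum(outcomes); n_neg <- sum(!outcomes)
  if (n_pos == 0) stop_invalid("outcomes", "contain no positive (diseased) cases")
  if (n_neg == 0) stop_invalid("outcomes", "contain no negative (non-diseased) cases")

  thr <- sort(unique(scores))
  sens <- vapply(thr, function(k) sum(scores >= k & outcomes) / n_pos, numeric(1))
  spec <- vapply(thr, function(k) sum(scores < k & !outcomes) / n_neg, numeric(1))
  # close the curve: a threshold above every score (nothing positive)
  thr <- c(thr, Inf); sens <- c(sens, 0); spec <- c(spec, 1)

  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[outcomes]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "emp_roc")
}

#' @export
print.emp_roc <- function(x, ...) {
  cat(sprintf("Empirical ROC: %d diseased vs %d non-diseased, AUC = %.2f\n",
              x$n_pos, x$n_neg, round_half_up(x$auc, 2)))
  invisible(x)
}

#' @export
plot.emp_roc <- function(x, ...) {
  ord <- order(1 - x$specificity, x$sensitivity)
  plot(1 - x$specificity[ord], x$sensitivity[ord], type = "s",
       xlab = "1 - specificity", ylab = "sensitivity",
       xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  graphics::legend("bottomright", bty = "n",
                   legend = sprintf("AUC = %.2f", round_half_up(x$auc, 2)))
  invisible(x)
}

# placement values: per-case mean of psi(X, Y) (1 win, 0.5 tie, 0 loss)
delong_placements <- function(scores, outcomes) {
  x <- scores[outcomes]; y <- scores[!outcomes]
  m <- length(x); n <- length(y)
  rall <- rank(c(x, y), ties.method = "average")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  v10 <- (rall[seq_len(m)] - rx) / n            # per diseased case
  v01 <- 1 - (rall[m + seq_len(n)] - ry) / m    # per non-diseased case
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong test for two paired AUCs
#'
#' Compares the AUCs of two scores measured on the same patients against
#' the same severe-AKI outcome, using the DeLong covariance of the
#' Mann-Whitney estimators computed from placement values. Returns the
#' z statistic `(AUC_a - AUC_b) / SE(diff)`, a two-sided normal p-value
#' and a 95% CI on the difference. Identical score vectors are an exact
#' tie: z = 0, p = 1.
#'
#' @param scores_a,scores_b numeric scores, paired by patient.
#' @param outcomes logical severe-AKI indicator.
#' @param conf confidence level for the difference CI.
#' @return object of class `"auc_comparison"`.
#' @examples
#' coh <- score_cohort(generate_cohort(cohort_config(fixed_margins = TRUE), seed = 1))
#' adj <- adjudicate_cohort(coh)
#' delong_test(coh$rai, coh$delta_scr, adj$saki)
#' @export
delong_test <- function(scores_a, scores_b, outcomes, conf = 0.95) {
  if (length(scores_a) != length(outcomes) || length(scores_b) != length(outcomes))
    stop_invalid("scores_a/scores_b/outcomes", "must be paired (equal lengths)")
  outcomes <- as.logical(outcomes)
  if (sum(outcomes) == 0 || sum(!outcomes) == 0)
    stop_invalid("outcomes", "need both classes present")

  pa <- delong_placements(scores_a, outcomes)
  pb <- delong_placements(scores_b, outcomes)
  m <- sum(outcomes); n <- sum(!outcomes)

  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
              (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  diff <- pa$auc - pb$auc
  se <- sqrt(max(var_diff, 0))
  if (se == 0) {
    z <- 0; p <- 1
  } else {
    z <- diff / se
    p <- 2 * stats::pnorm(-abs(z))
  }
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  structure(list(auc_a = pa$auc, auc_b = pb$auc, diff = diff, se = se,
                 z = z, p_two_sided = p,
                 ci_diff = c(diff - zq * se, diff + zq * se), conf = conf),
            class = "auc_comparison")
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat("Paired AUC comparison (DeLong):\n")
  cat(sprintf("  AUC a = %.3f, AUC b = %.3f, difference = %.3f (SE %.3f)\n",
              x$auc_a, x$auc_b, x$diff, x$se))
  cat(sprintf("  z = %.3f, two-sided p = %.3f, %.0f%% CI (%.3f, %.3f)\n",
              x$z, x$p_two_sided, 100 * x$conf, x$ci_diff[1], x$ci_diff[2]))
  invisible(x)
}

#' Filter a cohort by a patient-level predicate
#'
#' @param data cohort data.frame.
#' @param predicate function of the data.frame returning a logical vector
#'   (e.g. `function(d) d$age_years <= 5`).
#' @return the matching rows, order preserved, with attribute `n_selected`;
#'   an empty result triggers a warning but is allowed.
#' @examples
#' coh <- generate_cohort(cohort_config(fixed_margins = TRUE), seed = 1)
#' under5 <- subgroup_filter(coh, function(d) d$age_years <= 5)
#' nrow(under5)
#' @export
subgroup_filter <- function(data, predicate) {
  keep <- predicate(data)
  if (!is.logical(keep) || length(keep) != nrow(data))
    stop_invalid("predicate", "must return one logical per row")
  keep[is.na(keep)] <- FALSE
  out <- data[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("subgroup_filter: predicate selected no records")
  attr(out, "n_selected") <- nrow(out)
  out
}
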