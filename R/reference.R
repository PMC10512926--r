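#' Contingency counts of the 122-admission validation cohort
#'
#' The published margins of the PICU cohort this package models: 122
#' admissions, 18 with day-3 severe AKI. Cross-tabulations are given as
#' `(tp, fp, fn, tn)` against severe AKI. The modified-RAI cutoff table is
#' stored as true-positive / true-negative counts per cutoff, from which
#' every printed sensitivity, specificity, PPV, NPV and Youden value of the
#' cutoff scan is reconstructible.
#'
#' @return a list:
#' \describe{
#'   \item{n, n_saki, n_aki}{cohort size, severe-AKI count, any-AKI count.}
#'   \item{n_rai_pos, n_deaths}{RAI-positive and in-PICU death counts.}
#'   \item{rai}{confusion counts for RAI >= 8.}
#'   \item{d0_gt_bscr}{confusion counts for day-0 creatinine above
#'     baseline.}
#'   \item{mortality}{confusion counts for death by severe-AKI status.}
#'   \item{mrai_cutoffs}{data.frame `cutoff`, `tp`, `tn` (of 18 / 104).}
#'   \item{achievable_mrai}{the score values the local modified index
#'     produced.}
#' }
#' @export
reference_counts <- function() {
  list(
    n = 122L, n_saki = 18L, n_aki = 28L, n_rai_pos = 25L, n_deaths = 20L,
    rai = confusion_counts(tp = 10, fp = 15, fn = 8, tn = 89),
    d0_gt_bscr = confusion_counts(tp = 16, fp = 66, fn = 2, tn = 38),
    mortality = confusion_counts(tp = 7, fp = 13, fn = 11, tn = 91),
    mrai_cutoffs = data.frame(
      cutoff = c(4, 6, 8, 10, 12, 14, 20, 28, 40),
      tp = c(16L, 13L, 13L, 11L, 11L, 9L, 8L, 7L, 5L),
      tn = c(62L, 79L, 84L, 84L, 86L, 87L, 90L, 94L, 97L)
    ),
    achievable_mrai = c(1, 2, 3, 4, 6, 7, 8, 10, 12, 13, 14, 17, 20, 24,
                        26, 28, 34, 40, 56, 68, 80, 104, 136, 160)
  )
}

#' Patient-level modified-RAI scores consistent with the published cutoff
#' table
#'
#' Expands the per-cutoff true-positive/true-negative counts of
#' [reference_counts()] into one score per patient, placing each patient's
#' score on an achievable modified-RAI value inside the cutoff interval the
#' counts assign it to. Any such expansion reproduces the published cutoff
#' scan exactly; individual patient scores were not published, so this is a
#' synthetic reconstruction for validating the scan and ROC machinery.
#'
#' @return data.frame with columns `score` (numeric) and `saki` (logical),
#'   122 rows.
#' @export
mrai_reference_scores <- function() {
  rc <- reference_counts()
  tab <- rc$mrai_cutoffs
  n_pos <- rc$n_saki; n_neg <- rc$n - rc$n_saki
  # patients per half-open cutoff interval [c_k, c_{k+1})
  edges <- c(-Inf, tab$cutoff, Inf)
  pos_at <- c(n_pos, tab$tp)           # count with score >= each edge
  neg_fp <- c(n_neg, n_neg - tab$tn)   # false positives >= each edge
  pos_in <- -diff(c(pos_at, 0))
  neg_in <- -diff(c(neg_fp, 0))
  # a representative achievable score inside each interval
  rep_score <- vapply(seq_along(pos_in), function(i) {
    lo <- edges[i]; hi <- edges[i + 1]
    cand <- rc$achievable_mrai[rc$achievable_mrai >= max(lo, 1) & rc$achievable_mrai < hi]
    cand[1]
  }, numeric(1))
  data.frame(
    score = c(rep(rep_score, pos_in), rep(rep_score, neg_in)),
    saki = rep(c(TRUE, FALSE), c(n_pos, n_neg))
  )
}
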