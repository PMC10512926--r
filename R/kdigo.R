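#' KDIGO stage for one assessment
#'
#' Stages acute kidney injury from the creatinine ratio to baseline, the
#' 48-h absolute creatinine rise, urine output, and dialysis use:
#' \itemize{
#'   \item stage 1: ratio in \[1.5, 2.0) or a rise >= 26.5 \eqn{\mu}mol/L
#'     (0.3 mg/dL) within 48 h;
#'   \item stage 2: ratio in \[2.0, 3.0), or oliguria under the configured
#'     urine-output rule;
#'   \item stage 3: ratio >= 3.0, or renal replacement therapy.
#' }
#' Severe AKI is stage >= 2. The default urine-output rule is the cohort
#' definition — <= 0.5 mL/kg/h sustained for >= 8 h counts as stage 2;
#' `uo_rule = "kdigo"` selects the guideline thresholds instead
#' (stage 1: <0.5 for 6–12 h; stage 2: <0.5 for >= 12 h; stage 3: <0.3 for
#' >= 24 h). Urine-output and 48-h-rise criteria are simply skipped when
#' their inputs are unavailable (`NA`), as in cohorts with incomplete
#' charting.
#'
#' @param baseline_scr,current_scr creatinine in \eqn{\mu}mol/L.
#' @param scr_rise_48h_umol absolute rise over a 48-h window, `NA` when no
#'   48-h-spaced pair exists.
#' @param uo_ml_kg_h,uo_duration_h urine output and the duration it was
#'   sustained; `NA` when undocumented.
#' @param received_rrt logical.
#' @param uo_rule `"cohort"` (default) or `"kdigo"`.
#' @return object of class `"aki_assessment"`: `stage` (0–3), `severe`,
#'   `basis` (which criterion set the stage), `ratio`.
#' @examples
#' kdigo_stage(30, 66)                 # ratio 2.2 -> stage 2, severe
#' kdigo_stage(30, 30, uo_ml_kg_h = 0.3, uo_duration_h = 10)  # oliguric sAKI
#' @export
kdigo_stage <- function(baseline_scr, current_scr,
                        scr_rise_48h_umol = NA_real_,
                        uo_ml_kg_h = NA_real_, uo_duration_h = NA_real_,
                        received_rrt = FALSE,
                        uo_rule = c("cohort", "kdigo")) {
  uo_rule <- match.arg(uo_rule)
  check_positive(baseline_scr, "baseline_scr")
  check_positive(current_scr, "current_scr")
  ratio <- current_scr / baseline_scr

  cr_stage <- ifelse(ratio >= 3, 3L, ifelse(ratio >= 2, 2L, ifelse(ratio >= 1.5, 1L, 0L)))
  rise_stage <- ifelse(!is.na(scr_rise_48h_umol) & scr_rise_48h_umol >= 26.5, 1L, 0L)

  uo_stage <- uo_stage_for(uo_ml_kg_h, uo_duration_h, uo_rule)
  rrt_stage <- ifelse(isTRUE_vec(received_rrt), 3L, 0L)

  stage <- pmax(cr_stage, rise_stage, uo_stage, rrt_stage)
  # reporting tie-break: creatinine ratio > urine output > absolute rise > rrt
  basis <- rep(NA_character_, length(stage))
  basis[stage == rrt_stage & stage > 0] <- "rrt"
  basis[stage == rise_stage & stage > 0] <- "absolute_rise"
  basis[stage == uo_stage & stage > 0] <- "urine_output"
  basis[stage == cr_stage & stage > 0] <- "creatinine_ratio"
  basis[stage == 0] <- "none"

  structure(list(stage = stage, severe = stage >= 2L, basis = basis, ratio = ratio),
            class = "aki_assessment")
}

uo_stage_for <- function(uo, dur, uo_rule) {
  n <- max(length(uo), length(dur))
  uo <- rep_len(uo, n); dur <- rep_len(dur, n)
  out <- rep(0L, n)
  ok <- !is.na(uo) & !is.na(dur)
  if (uo_rule == "cohort") {
    out[ok & uo <= 0.5 & dur >= 8] <- 2L
  } else {
    out[ok & uo < 0.5 & dur >= 6] <- 1L
    out[ok & uo < 0.5 & dur >= 12] <- 2L
    out[ok & uo < 0.3 & dur >= 24] <- 3L
  }
  out
}

#' @export
print.aki_assessment <- function(x, ...) {
  n <- length(x$stage)
  if (n == 1) {
    cat(sprintf("KDIGO stage %d (%s)%s; creatinine ratio %.2f\n", x$stage,
                x$basis, if (x$severe) " — severe AKI" else "", x$ratio))
  } else {
    cat("KDIGO assessments:\n")
    print(table(stage = x$stage))
    cat(sprintf("severe AKI: %d / %d\n", sum(x$severe), n))
  }
  invisible(x)
}

#' Adjudicate severe AKI across a cohort
#'
#' Applies [kdigo_stage()] to every admission using the day-3 creatinine
#' against the (recorded or height-imputed) baseline, the documented day-3
#' urine output, and dialysis use, and reports the severe-AKI prevalence
#' with a 95% Wald interval.
#'
#' @param data cohort data.frame; rows lacking `d3_scr_umol_l` are an error
#'   (the cohort design requires a 72-h stay).
#' @param config a [score_config()] (for baseline imputation).
#' @param uo_rule passed to [kdigo_stage()].
#' @return `data` with `aki_stage`, `saki`, `aki_basis`, `ratio_d3`
#'   appended; class `"aki_cohort"` with a `prevalence` attribute
#'   (list: estimate, ci_low, ci_high, n).
#' @examples
#' coh <- generate_cohort(cohort_config(fixed_margins = TRUE), seed = 1)
#' adj <- adjudicate_cohort(coh)
#' attr(adj, "prevalence")$estimate * 100  # percent
#' @export
adjudicate_cohort <- function(data, config = score_config(),
                              uo_rule = c("cohort", "kdigo")) {
  uo_rule <- match.arg(uo_rule)
  data <- as.data.frame(data)
  if (nrow(data) == 0) stop_invalid("data", "has no rows")
  if (is.null(data$d3_scr_umol_l) || all(is.na(data$d3_scr_umol_l)))
    stop_invalid("d3_scr_umol_l", "column is required for adjudication")
  if (any(is.na(data$d3_scr_umol_l)))
    stop_invalid("d3_scr_umol_l",
                 paste("is missing for row(s)",
                       paste(which(is.na(data$d3_scr_umol_l)), collapse = ", ")))
  base <- resolve_baseline(data, config)
  ass <- kdigo_stage(
    baseline_scr = base$bscr,
    current_scr = data$d3_scr_umol_l,
    scr_rise_48h_umol = data$scr_rise_48h_umol %||% NA_real_,
    uo_ml_kg_h = data$d3_urine_output_ml_kg_h %||% NA_real_,
    uo_duration_h = data$d3_urine_output_duration_h %||% NA_real_,
    received_rrt = data$received_rrt %||% FALSE,
    uo_rule = uo_rule
  )
  out <- data
  out$aki_stage <- ass$stage
  out$saki <- ass$severe
  out$aki_basis <- ass$basis
  out$ratio_d3 <- ass$ratio
  p <- mean(ass$severe)
  se <- sqrt(p * (1 - p) / nrow(out))
  structure(out,
            prevalence = list(estimate = p, ci_low = p - 1.96 * se,
                              ci_high = p + 1.96 * se, n = nrow(out)),
            class = c("aki_cohort", "data.frame"))
}

#' @export
summary.aki_cohort <- function(object, ...) {
  pr <- attr(object, "prevalence")
  cat(sprintf("Adjudicated cohort: %d admissions\n", pr$n))
  cat("  KDIGO stages: ",
      paste(sprintf("%d:%d", 0:3, tabulate(object$aki_stage + 1L, 4L)), collapse = "  "), "\n")
  cat(sprintf("  any AKI:    %d (%.1f%%)\n", sum(object$aki_stage >= 1),
              round_half_up(100 * mean(object$aki_stage >= 1), 1)))
  cat(sprintf("  severe AKI: %d — prevalence %s%%\n", sum(object$saki),
              fmt_pct_ci(100 * pr$estimate, 100 * pr$ci_low, 100 * pr$ci_high)))
  invisible(object)
}
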