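#' Impute baseline serum creatinine from height
#'
#' When no baseline creatinine is on record, it is back-calculated from the
#' Schwartz estimate by assuming a normal creatinine clearance:
#' `BSCr = k * height / eCrCl` with the assumed clearance (default
#' 120 mL/min/1.73m2).
#'
#' @param height_cm height in cm.
#' @param config a [score_config()] (supplies `schwartz_k_umol` and
#'   `assumed_ecrcl`).
#' @return baseline creatinine in \eqn{\mu}mol/L.
#' @examples
#' impute_baseline_scr(120)  # = k when height equals the assumed clearance
#' @export
impute_baseline_scr <- function(height_cm, config = score_config()) {
  check_positive(height_cm, "height_cm")
  config$schwartz_k_umol * height_cm / config$assumed_ecrcl
}

#' Creatinine ratio at enrollment
#'
#' The enrollment (day-0) serum creatinine divided by the baseline value,
#' both in the same units. A ratio of 1 means no change.
#'
#' @param enrollment_scr,baseline_scr positive creatinine values.
#' @return the ratio (unitless).
#' @export
delta_scr <- function(enrollment_scr, baseline_scr) {
  check_positive(enrollment_scr, "enrollment_scr")
  check_positive(baseline_scr, "baseline_scr")
  enrollment_scr / baseline_scr
}

#' Percent fluid overload over the first 8 h
#'
#' `%FO = (fluid in - fluid out) / admission weight * 100`, fluids in
#' litres, weight in kg. Negative values (net diuresis) are allowed. If
#' either fluid field is missing the result is `NA` — fluid overload is
#' unavailable, not zero.
#'
#' @param fluid_in_l,fluid_out_l fluid volumes in litres (may be `NA`).
#' @param weight_kg admission weight in kg.
#' @return percent fluid overload, or `NA` when undocumented.
#' @export
percent_fluid_overload <- function(fluid_in_l, fluid_out_l, weight_kg) {
  check_positive(weight_kg, "weight_kg")
  n <- max(length(fluid_in_l), length(fluid_out_l))
  fluid_in_l <- rep_len(fluid_in_l, n)
  fluid_out_l <- rep_len(fluid_out_l, n)
  ok <- !is.na(fluid_in_l) & !is.na(fluid_out_l)
  if (any((fluid_in_l < 0 | fluid_out_l < 0), na.rm = TRUE))
    stop_invalid("fluid volumes", "must be non-negative")
  out <- rep(NA_real_, n)
  out[ok] <- (fluid_in_l[ok] - fluid_out_l[ok]) / rep_len(weight_kg, n)[ok] * 100
  out
}

# map values through an ordered tier table; `strict` rows require val > lower
tier_lookup <- function(values, tiers) {
  strict <- tiers$strict %||% rep(FALSE, nrow(tiers))
  out <- rep(NA_integer_, length(values))
  for (i in seq_len(nrow(tiers))) {
    hit <- if (strict[i]) values > tiers$lower[i] else values >= tiers$lower[i]
    out[!is.na(hit) & hit] <- as.integer(tiers$score[i])
  }
  out
}

#' Risk component of the renal angina index
#'
#' Under the original index the risk score is the single highest applicable
#' stratum; under the modified index (`mrai_mode`) it is the sum of all
#' applicable condition weights.
#'
#' @param data cohort data.frame (one row per admission) with the columns
#'   the configured risk conditions consult (see [risk_conditions()]).
#' @param config a [score_config()].
#' @return integer-valued risk score per row.
#' @export
risk_score <- function(data, config = score_config()) {
  data <- as.data.frame(data)
  if (length(config$risk_weights) == 0)
    stop("configuration error: risk_weights is empty", call. = FALSE)
  preds <- risk_conditions()
  w <- config$risk_weights
  applies <- vapply(names(w), function(nm) preds[[nm]](data), logical(nrow(data)))
  applies <- matrix(applies, nrow = nrow(data))
  if (config$mrai_mode) {
    as.vector(applies %*% w)
  } else {
    apply(applies, 1L, function(a) if (any(a)) max(w[a]) else 0)
  }
}

#' Injury component of the renal angina index
#'
#' The creatinine ratio and (when documented) the percent fluid overload are
#' each mapped through their tier tables; the injury score is the higher of
#' the two. With fluid data missing — common where intake/output charting is
#' incomplete — the creatinine tier alone is used.
#'
#' @param delta creatinine ratio(s), from [delta_scr()].
#' @param percent_fo percent fluid overload, `NA` when unavailable.
#' @param config a [score_config()].
#' @return integer injury score per element.
#' @export
injury_score <- function(delta, percent_fo = NA_real_, config = score_config()) {
  check_positive(delta, "delta_scr")
  n <- length(delta)
  percent_fo <- rep_len(percent_fo, n)
  dtier <- tier_lookup(delta, config$injury_dscr_tiers)
  ftier <- rep(NA_integer_, n)
  has_fo <- !is.na(percent_fo)
  if (any(has_fo)) ftier[has_fo] <- tier_lookup(percent_fo[has_fo], config$injury_fo_tiers)
  pmax(dtier, ftier, na.rm = TRUE)
}

resolve_baseline <- function(data, config) {
  n <- nrow(data)
  bscr <- if (is.null(data$baseline_scr_umol_l)) rep(NA_real_, n) else data$baseline_scr_umol_l
  height <- if (is.null(data$height_cm)) rep(NA_real_, n) else data$height_cm
  imputed <- is.na(bscr)
  if (any(imputed & is.na(height)))
    stop_invalid("baseline_scr_umol_l and height_cm",
                 paste("are both missing for row(s)",
                       paste(which(imputed & is.na(height)), collapse = ", ")))
  if (any(imputed)) bscr[imputed] <- impute_baseline_scr(height[imputed], config)
  list(bscr = bscr, imputed = imputed)
}

#' Score a cohort with the renal angina index
#'
#' Computes, per admission: the creatinine ratio (imputing the baseline from
#' height where it is not on record), percent fluid overload where
#' documented, the risk and injury components, their product, and the
#' positivity flag at the configured cutoff.
#'
#' @param data cohort data.frame in the standard dialect (see
#'   [read_cohort_csv()]).
#' @param config a [score_config()]; use preset `"mrai_local"` (or any
#'   config with `mrai_mode = TRUE`) for the modified index.
#' @return `data` with columns `delta_scr`, `percent_fo`, `fo_available`,
#'   `risk_score`, `injury_score`, `rai`, `rai_positive`,
#'   `imputed_baseline` appended; class `"rai_scored"` with the config as
#'   attribute.
#' @examples
#' coh <- generate_cohort(cohort_config(fixed_margins = TRUE), seed = 1)
#' scored <- score_cohort(coh)
#' table(scored$rai_positive)
#' @export
score_cohort <- function(data, config = score_config()) {
  data <- as.data.frame(data)
  if (nrow(data) == 0) stop_invalid("data", "has no rows")
  if (is.null(data$d0_scr_umol_l) || any(is.na(data$d0_scr_umol_l)))
    stop_invalid("d0_scr_umol_l", "is required for every row")
  check_positive(data$d0_scr_umol_l, "d0_scr_umol_l")
  if (is.null(data$weight_kg)) stop_invalid("weight_kg", "column is required")

  base <- resolve_baseline(data, config)
  delta <- delta_scr(data$d0_scr_umol_l, base$bscr)

  fin <- data$fluid_in_l_8h %||% rep(NA_real_, nrow(data))
  fout <- data$fluid_out_l_8h %||% rep(NA_real_, nrow(data))
  pfo <- percent_fluid_overload(fin, fout, data$weight_kg)

  risk <- risk_score(data, config)
  inj <- injury_score(delta, if (config$mrai_mode) NA_real_ else pfo, config)
  rai <- risk * inj

  out <- data
  out$baseline_scr_used <- base$bscr
  out$imputed_baseline <- base$imputed
  out$delta_scr <- delta
  out$percent_fo <- pfo
  out$fo_available <- !is.na(pfo)
  out$risk_score <- risk
  out$injury_score <- inj
  out$rai <- rai
  out$rai_positive <- rai >= config$positivity_cutoff
  structure(out, config = config, class = c("rai_scored", "data.frame"))
}

#' @export
summary.rai_scored <- function(object, ...) {
  cfg <- attr(object, "config")
  cat(sprintf("RAI-scored cohort: %d admissions (%s preset)\n",
              nrow(object), cfg$preset))
  cat(sprintf("  positive (score >= %g): %d (%.1f%%)\n", cfg$positivity_cutoff,
              sum(object$rai_positive),
              round_half_up(100 * mean(object$rai_positive), 1)))
  cat(sprintf("  baseline creatinine imputed from height: %d (%.1f%%)\n",
              sum(object$imputed_baseline),
              round_half_up(100 * mean(object$imputed_baseline), 1)))
  cat(sprintf("  fluid overload undocumented: %d (%.1f%%)\n",
              sum(!object$fo_available),
              round_half_up(100 * mean(!object$fo_available), 1)))
  invisible(object)
}

rai_result <- function(scored_row, config) {
  structure(list(
    patient_id = scored_row$patient_id %||% NA_character_,
    delta_scr = scored_row$delta_scr,
    percent_fo = scored_row$percent_fo,
    fo_available = scored_row$fo_available,
    risk_score = scored_row$risk_score,
    injury_score = scored_row$injury_score,
    rai = scored_row$rai,
    positive = scored_row$rai_positive,
    imputed_baseline = scored_row$imputed_baseline,
    mrai_mode = config$mrai_mode
  ), class = "rai_result")
}

#' Renal angina index for a single admission
#'
#' @param record a one-row data.frame or named list with the patient fields
#'   used by [score_cohort()].
#' @param config a [score_config()].
#' @return object of class `"rai_result"`: the component scores, the
#'   product, the positivity flag and the inputs that produced them.
#' @examples
#' compute_rai(list(d0_scr_umol_l = 60, height_cm = 120, weight_kg = 20,
#'                  age_years = 6))
#' @export
compute_rai <- function(record, config = score_config()) {
  record <- as.data.frame(record, stringsAsFactors = FALSE)
  if (nrow(record) != 1) stop_invalid("record", "must describe exactly one admission")
  rai_result(score_cohort(record, config)[1, ], config)
}

#' Modified renal angina index for a single admission
#'
#' The locally modified index: sum of applicable risk weights multiplied by
#' the creatinine-based injury score (fluid overload does not enter).
#'
#' @inheritParams compute_rai
#' @param config a config with `mrai_mode = TRUE`, e.g.
#'   `score_config("mrai_local")`.
#' @return a `"rai_result"`.
#' @export
compute_mrai <- function(record, config = score_config("mrai_local")) {
  if (!isTRUE(config$mrai_mode))
    stop("configuration error: compute_mrai requires mrai_mode = TRUE", call. = FALSE)
  compute_rai(record, config)
}

#' @export
print.rai_result <- function(x, ...) {
  cat(if (x$mrai_mode) "Modified renal angina index\n" else "Renal angina index\n")
  cat(sprintf("  creatinine ratio: %.3f%s\n", x$delta_scr,
              if (x$imputed_baseline) " (baseline imputed from height)" else ""))
  cat("  fluid overload:   ",
      if (x$fo_available) sprintf("%.1f%%", x$percent_fo) else "unavailable", "\n")
  cat(sprintf("  risk %g x injury %g = %g  ->  %s\n", x$risk_score,
              x$injury_score, x$rai, if (x$positive) "POSITIVE" else "negative"))
  invisible(x)
}

#' All scores a configuration can produce
#'
#' Exhaustive enumeration: every achievable risk value (each maximum, or in
#' `mrai_mode` each subset sum, over independently togglable conditions,
#' with `icu_admission` — if configured — always present) times every
#' injury-tier score. Useful for sanity-checking a local re-weighting.
#'
#' @param config a [score_config()].
#' @return sorted vector of achievable scores.
#' @examples
#' enumerate_achievable_scores(score_config())
#' @export
enumerate_achievable_scores <- function(config = score_config()) {
  w <- config$risk_weights
  if (length(w) == 0) stop("configuration error: risk_weights is empty", call. = FALSE)
  if (length(w) > 20) stop("configuration error: too many risk conditions to enumerate",
                           call. = FALSE)
  mandatory <- names(w) == "icu_admission"
  opt <- w[!mandatory]
  base <- sum(w[mandatory])
  risks <- numeric(0)
  for (k in 0:length(opt)) {
    for (idx in if (k == 0) list(integer(0)) else utils::combn(seq_along(opt), k, simplify = FALSE)) {
      sel <- c(w[mandatory], opt[idx])
      if (length(sel) == 0) next  # no applicable condition: no score defined
      risks <- c(risks, if (config$mrai_mode) sum(sel) else max(sel))
    }
  }
  risks <- unique(risks)
  injuries <- unique(config$injury_dscr_tiers$score)
  if (!config$mrai_mode) injuries <- unique(c(injuries, config$injury_fo_tiers$score))
  sort(unique(as.vector(outer(risks, injuries))))
}
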