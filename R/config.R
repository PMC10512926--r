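#' Scoring configuration for the renal angina index
#'
#' Bundles the tier boundaries, risk weights and positivity cutoff that
#' define an RAI variant. Two presets are provided:
#' \describe{
#'   \item{`"rai_original"`}{the published index: risk is the single highest
#'     applicable stratum (ICU admission 1, transplant history 3, mechanical
#'     ventilation plus vasopressor support 5); injury is the higher of the
#'     creatinine-ratio tier and the fluid-overload tier; positive at
#'     RAI >= 8.}
#'   \item{`"mrai_local"`}{a locally re-weighted variant: risk is the SUM of
#'     all applicable condition weights and injury uses the creatinine ratio
#'     only. The bundled weights are illustrative placeholders for the local
#'     risk factors (sepsis, severe malaria, infancy, organ support); supply
#'     your own via `risk_weights` when validating a local derivation.}
#' }
#'
#' @param preset `"rai_original"` or `"mrai_local"`.
#' @param risk_weights named numeric vector of positive weights; names must
#'   be risk-condition identifiers understood by [risk_score()] (see
#'   [risk_conditions()]).
#' @param injury_dscr_tiers data.frame with columns `lower` (tier lower
#'   bound on the creatinine ratio), `score`, and `strict` (`TRUE` when the
#'   bound is open, i.e. the ratio must exceed `lower`). Tiers must be
#'   strictly increasing in both bound and score.
#' @param injury_fo_tiers data.frame with columns `lower` (percent fluid
#'   overload lower bound) and `score`; left-closed bounds.
#' @param positivity_cutoff score at and above which the index is positive.
#' @param mrai_mode logical; `TRUE` selects sum-of-weights risk and
#'   creatinine-only injury.
#' @param schwartz_k_umol Schwartz constant in \eqn{\mu}mol/L per cm
#'   (0.413 mg/dL/cm x 88.4) for baseline-creatinine imputation.
#' @param assumed_ecrcl assumed creatinine clearance (mL/min/1.73m2) when
#'   the baseline creatinine is unknown.
#' @return object of class `"score_config"`.
#' @examples
#' cfg <- score_config()
#' cfg$positivity_cutoff
#' mcfg <- score_config("mrai_local")
#' @export
score_config <- function(preset = c("rai_original", "mrai_local"),
                         risk_weights = NULL,
                         injury_dscr_tiers = NULL,
                         injury_fo_tiers = NULL,
                         positivity_cutoff = 8L,
                         mrai_mode = NULL,
                         schwartz_k_umol = 36.5,
                         assumed_ecrcl = 120) {
  preset <- match.arg(preset)
  if (is.null(mrai_mode)) mrai_mode <- preset == "mrai_local"
  if (is.null(risk_weights)) {
    risk_weights <- if (preset == "rai_original") {
      c(icu_admission = 1, transplant = 3, ventilation_and_vasopressors = 5)
    } else {
      # placeholder local weights: base admission risk plus the conditions
      # over-represented among severe-AKI admissions in the unit
      c(icu_admission = 1, sepsis = 4, severe_malaria = 2,
        age_under_1 = 2, ventilation = 3, vasopressors = 3)
    }
  }
  if (is.null(injury_dscr_tiers)) {
    # ratio exactly 1 ("no change") scores 1; (1, 1.5) scores 2;
    # [1.5, 2) scores 4; >= 2 scores 8
    injury_dscr_tiers <- data.frame(
      lower  = c(-Inf, 1, 1.5, 2),
      score  = c(1L, 2L, 4L, 8L),
      strict = c(FALSE, TRUE, FALSE, FALSE)
    )
  } else {
    injury_dscr_tiers <- as.data.frame(injury_dscr_tiers)
    if (is.null(injury_dscr_tiers$strict)) injury_dscr_tiers$strict <- FALSE
  }
  if (is.null(injury_fo_tiers)) {
    injury_fo_tiers <- data.frame(
      lower = c(-Inf, 5, 10, 15),
      score = c(1L, 2L, 4L, 8L)
    )
  } else {
    injury_fo_tiers <- as.data.frame(injury_fo_tiers)
  }

  cfg <- structure(list(
    preset = preset,
    risk_weights = risk_weights,
    injury_dscr_tiers = injury_dscr_tiers,
    injury_fo_tiers = injury_fo_tiers,
    positivity_cutoff = positivity_cutoff,
    mrai_mode = isTRUE(mrai_mode),
    schwartz_k_umol = schwartz_k_umol,
    assumed_ecrcl = assumed_ecrcl
  ), class = "score_config")
  validate_score_config(cfg)
}

validate_score_config <- function(cfg) {
  if (length(cfg$risk_weights) == 0)
    stop("configuration error: risk_weights is empty", call. = FALSE)
  if (is.null(names(cfg$risk_weights)) || any(!nzchar(names(cfg$risk_weights))))
    stop("configuration error: risk_weights must be a named vector", call. = FALSE)
  if (any(cfg$risk_weights <= 0))
    stop("configuration error: risk weights must be positive", call. = FALSE)
  unknown <- setdiff(names(cfg$risk_weights), names(risk_conditions()))
  if (length(unknown))
    stop("configuration error: unknown risk condition(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  for (nm in c("injury_dscr_tiers", "injury_fo_tiers")) {
    t <- cfg[[nm]]
    if (!all(c("lower", "score") %in% names(t)))
      stop("configuration error: ", nm, " needs columns lower, score", call. = FALSE)
    if (nrow(t) < 1 || is.unsorted(t$lower, strictly = TRUE) ||
        is.unsorted(t$score, strictly = TRUE))
      stop("configuration error: ", nm,
           " must be strictly increasing in lower bound and score", call. = FALSE)
  }
  check_positive(cfg$positivity_cutoff, "positivity_cutoff")
  check_positive(cfg$schwartz_k_umol, "schwartz_k_umol")
  check_positive(cfg$assumed_ecrcl, "assumed_ecrcl")
  cfg
}

#' Built-in risk-condition predicates
#'
#' Each maps a cohort data.frame to a logical vector marking the patients in
#' whom the condition applies. `risk_weights` names in [score_config()] must
#' come from this registry.
#'
#' @return named list of predicate functions of a cohort data.frame.
#' @export
risk_conditions <- function() {
  list(
    icu_admission = function(d) rep(TRUE, nrow(d)),  # cohort-defining
    transplant = function(d) isTRUE_vec(d$transplant_history),
    ventilation = function(d) isTRUE_vec(d$mechanical_ventilation_8h),
    vasopressors = function(d) isTRUE_vec(d$vasopressor_support_8h),
    ventilation_and_vasopressors = function(d)
      isTRUE_vec(d$mechanical_ventilation_8h) & isTRUE_vec(d$vasopressor_support_8h),
    sepsis = function(d) !is.na(d$diagnosis_category) & d$diagnosis_category == "sepsis",
    severe_malaria = function(d)
      !is.na(d$diagnosis_category) & d$diagnosis_category == "severe_malaria",
    age_under_1 = function(d) !is.na(d$age_years) & d$age_years < 1,
    age_under_5 = function(d) !is.na(d$age_years) & d$age_years < 5
  )
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else !is.na(x) & as.logical(x)

#' @export
print.score_config <- function(x, ...) {
  cat("Renal angina score configuration (preset:", x$preset, ")\n")
  cat("  risk mode:        ", if (x$mrai_mode) "sum of applicable weights"
      else "highest applicable stratum", "\n")
  cat("  risk weights:     ",
      paste(sprintf("%s=%g", names(x$risk_weights), x$risk_weights), collapse = ", "), "\n")
  cat("  creatinine tiers: ",
      paste(sprintf("%s%g:%d", ifelse(x$injury_dscr_tiers$strict, ">", ">="),
                    x$injury_dscr_tiers$lower, x$injury_dscr_tiers$score), collapse = "  "), "\n")
  if (!x$mrai_mode)
    cat("  %FO tiers:        ",
        paste(sprintf(">=%g%%:%d", x$injury_fo_tiers$lower, x$injury_fo_tiers$score),
              collapse = "  "), "\n")
  cat("  positive at score >=", x$positivity_cutoff, "\n")
  cat("  baseline imputation: k =", x$schwartz_k_umol, "umol/L/cm, eCrCl =",
      x$assumed_ecrcl, "mL/min/1.73m2\n")
  invisible(x)
}

#' Read a scoring configuration from YAML or JSON
#'
#' The file may set any argument of [score_config()]; tier tables are given
#' as lists of `{lower, score}` (and optionally `strict`) records.
#'
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return a validated `score_config`.
#' @export
read_score_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- list(preset = raw$preset %||% "rai_original")
  if (!is.null(raw$risk_weights)) args$risk_weights <- unlist(raw$risk_weights)
  for (nm in c("injury_dscr_tiers", "injury_fo_tiers")) {
    if (!is.null(raw[[nm]])) args[[nm]] <- as.data.frame(do.call(rbind, lapply(raw[[nm]], as.data.frame)))
  }
  for (nm in c("positivity_cutoff", "mrai_mode", "schwartz_k_umol", "assumed_ecrcl")) {
    if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  }
  do.call(score_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
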