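cohort_columns <- function() {
  list(
    patient_id = "character",
    age_years = "numeric",
    sex = "character",
    height_cm = "numeric",
    weight_kg = "numeric",
    diagnosis_category = "character",
    icu_admission = "logical",
    transplant_history = "logical",
    mechanical_ventilation_8h = "logical",
    vasopressor_support_8h = "logical",
    baseline_scr_umol_l = "numeric",
    d0_scr_umol_l = "numeric",
    d3_scr_umol_l = "numeric",
    fluid_in_l_8h = "numeric",
    fluid_out_l_8h = "numeric",
    d3_urine_output_ml_kg_h = "numeric",
    d3_urine_output_duration_h = "numeric",
    died_in_picu = "logical",
    picu_los_days = "numeric",
    ventilation_days = "numeric",
    received_rrt = "logical"
  )
}

required_cohort_columns <- function() {
  c("patient_id", "age_years", "sex", "weight_kg", "diagnosis_category",
    "d0_scr_umol_l")
}

diagnosis_levels <- function() {
  c("CNS", "sepsis", "endocrine", "cardiovascular", "severe_malaria",
    "respiratory", "other")
}

#' Read a cohort CSV in the standard dialect
#'
#' One row per admission, UTF-8, header with the standard field names,
#' empty cells for missing values. Unknown columns are kept untouched.
#'
#' @param path CSV file path.
#' @return data.frame with typed columns.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("I/O error: cannot read ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"),
                       fileEncoding = "UTF-8")
  spec <- cohort_columns()
  for (nm in intersect(names(spec), names(d))) {
    d[[nm]] <- switch(spec[[nm]],
                      numeric = as.numeric(d[[nm]]),
                      logical = as.logical(d[[nm]]),
                      character = as.character(d[[nm]]))
  }
  d
}

#' Write a cohort (or scored/adjudicated cohort) CSV
#'
#' @param data data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate a cohort CSV against the record schema
#'
#' Checks column presence and types, value ranges (positive creatinines and
#' weights, ages inside the 1-month–16-year eligibility window, known
#' diagnosis categories, non-negative fluids), and that each row either has
#' a baseline creatinine or the height needed to impute one. Missing
#' optional fields (fluids, urine output, baseline) produce warnings with
#' cohort-level missingness percentages, not errors.
#'
#' @param path cohort CSV path, or a data.frame already in memory.
#' @return object of class `"cohort_validation"`: `n_rows`, data.frame
#'   `errors` (`row`, `field`, `problem`), character vector `warnings`,
#'   named numeric `missingness` (percent), logical `ok`.
#' @export
validate_cohort_csv <- function(path) {
  d <- if (is.data.frame(path)) as.data.frame(path) else read_cohort_csv(path)
  errors <- data.frame(row = integer(), field = character(), problem = character())
  add_err <- function(rows, field, problem) {
    if (length(rows))
      errors <<- rbind(errors, data.frame(row = rows, field = field, problem = problem))
  }
  miss_col <- setdiff(required_cohort_columns(), names(d))
  if (length(miss_col))
    add_err(0L, paste(miss_col, collapse = ", "), "required column missing")

  chk_range <- function(nm, bad, problem) {
    if (!is.null(d[[nm]])) add_err(which(!is.na(d[[nm]]) & bad(d[[nm]])), nm, problem)
  }
  chk_range("age_years", function(x) x < 1 / 12 | x > 16,
            "outside the 1-month to 16-year eligibility window")
  for (nm in c("baseline_scr_umol_l", "d0_scr_umol_l", "d3_scr_umol_l"))
    chk_range(nm, function(x) x <= 0, "creatinine must be positive")
  chk_range("weight_kg", function(x) x <= 0, "must be positive")
  chk_range("height_cm", function(x) x <= 0, "must be positive")
  for (nm in c("fluid_in_l_8h", "fluid_out_l_8h"))
    chk_range(nm, function(x) x < 0, "must be non-negative")
  chk_range("diagnosis_category",
            function(x) !(x %in% diagnosis_levels()), "unknown category")
  if (!is.null(d$baseline_scr_umol_l) || !is.null(d$height_cm)) {
    no_base <- if (is.null(d$baseline_scr_umol_l)) rep(TRUE, nrow(d)) else is.na(d$baseline_scr_umol_l)
    no_h <- if (is.null(d$height_cm)) rep(TRUE, nrow(d)) else is.na(d$height_cm)
    add_err(which(no_base & no_h), "baseline_scr_umol_l/height_cm",
            "neither baseline creatinine nor height available")
  }

  optional <- c("baseline_scr_umol_l", "fluid_in_l_8h", "fluid_out_l_8h",
                "d3_urine_output_ml_kg_h", "d3_scr_umol_l")
  missingness <- vapply(optional, function(nm) {
    if (is.null(d[[nm]])) 100 else round_half_up(100 * mean(is.na(d[[nm]])), 1)
  }, numeric(1))
  warn <- sprintf("%s missing in %.1f%% of rows",
                  names(missingness)[missingness > 0], missingness[missingness > 0])

  structure(list(n_rows = nrow(d), errors = errors, warnings = warn,
                 missingness = missingness, ok = nrow(errors) == 0),
            class = "cohort_validation")
}

#' @export
print.cohort_validation <- function(x, ...) {
  cat(sprintf("Cohort validation: %d rows, %d error(s)\n", x$n_rows, nrow(x$errors)))
  if (nrow(x$errors)) print(x$errors)
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
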