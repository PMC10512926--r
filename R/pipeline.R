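#' Pipeline configuration
#'
#' @param cohort_csv path to the input cohort CSV (or a data.frame).
#' @param out_dir output directory (created if absent).
#' @param score_configs named list of [score_config()] objects to score
#'   with; default the original index and the local modified index.
#' @param evaluate which score columns to evaluate against severe AKI:
#'   subset of `"rai"`, `"mrai"`, `"d0_gt_bscr"`, `"delta_scr"`.
#' @param subgroups named list of predicates (functions of the cohort
#'   data.frame) defining subgroup re-analyses, e.g.
#'   `list(under5 = function(d) d$age_years <= 5)`.
#' @param cutoffs numeric cutpoints for the modified-index cutoff scan.
#' @param uo_rule urine-output rule for adjudication (see [kdigo_stage()]).
#' @param seed integer recorded in the run log (the pipeline itself is
#'   deterministic given its inputs).
#' @return object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(cohort_csv, out_dir = "renangia-out",
                            score_configs = list(rai = score_config("rai_original"),
                                                 mrai = score_config("mrai_local")),
                            evaluate = c("rai", "mrai", "d0_gt_bscr", "delta_scr"),
                            subgroups = list(under5 = function(d) d$age_years <= 5),
                            cutoffs = c(4, 6, 8, 10, 12, 14, 20, 28, 40),
                            uo_rule = "cohort",
                            seed = 1L) {
  if (length(evaluate) == 0)
    stop("configuration error: at least one score must be selected", call. = FALSE)
  evaluate <- match.arg(evaluate, several.ok = TRUE)
  structure(as.list(environment()), class = "pipeline_config")
}

evaluate_binary <- function(pred, outcome, label) {
  m <- screening_metrics(confusion_matrix(pred, outcome))
  cbind(score = label, as.data.frame(m))
}

#' Run the full screening-evaluation pipeline
#'
#' Validates the cohort, scores it with every configured index,
#' adjudicates day-3 severe AKI, and evaluates the selected predictors:
#' screening-metric tables (overall and per subgroup), a cutoff scan of
#' the modified index with Youden's index, empirical ROC curves, and a
#' DeLong comparison of the original-index AUC against the
#' creatinine-ratio AUC. When `out_dir` is set the scored and adjudicated
#' CSVs, metric tables, ROC points and a JSON run summary are written
#' there; partial outputs are removed if the run fails.
#'
#' @param config a [pipeline_config()].
#' @return object of class `"pipeline_result"` (list of the tables
#'   described above), invisibly written to disk when `out_dir` is not
#'   `NULL`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  val <- validate_cohort_csv(config$cohort_csv)
  if (!val$ok) {
    stop("cohort validation failed:\n",
         paste(sprintf("  row %d: %s %s", val$errors$row, val$errors$field,
                       val$errors$problem), collapse = "\n"), call. = FALSE)
  }
  d <- if (is.data.frame(config$cohort_csv)) as.data.frame(config$cohort_csv)
       else read_cohort_csv(config$cohort_csv)

  wrote <- character(0)
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(obj, name) {
    if (is.null(out_dir)) return(invisible(NULL))
    p <- file.path(out_dir, name)
    write_cohort_csv(obj, p)
    wrote <<- c(wrote, p)
  }
  on.exit({
    # remove partial outputs on failure
    if (!is.null(out_dir) && length(wrote)) unlink(wrote)
  })

  base_cfg <- config$score_configs[[1]]
  scored_all <- lapply(config$score_configs, function(cfg) score_cohort(d, cfg))
  scored <- scored_all[[1]]
  for (nm in names(scored_all)) scored[[paste0("score_", nm)]] <- scored_all[[nm]]$rai
  adj <- adjudicate_cohort(d, base_cfg, uo_rule = config$uo_rule)
  scored$aki_stage <- adj$aki_stage
  scored$saki <- adj$saki
  emit(scored, "scored_adjudicated.csv")

  outcome <- adj$saki
  predictors <- list(
    rai = list(binary = scored_all[["rai"]]$rai_positive, score = scored_all[["rai"]]$rai),
    mrai = if ("mrai" %in% names(scored_all))
      list(binary = scored_all[["mrai"]]$rai_positive, score = scored_all[["mrai"]]$rai),
    d0_gt_bscr = list(binary = scored$delta_scr > 1, score = scored$d0_scr_umol_l),
    delta_scr = list(binary = scored$delta_scr > 1, score = scored$delta_scr)
  )

  metric_rows <- list(); roc <- list()
  for (nm in config$evaluate) {
    p <- predictors[[nm]]
    if (is.null(p)) next
    metric_rows[[nm]] <- evaluate_binary(p$binary, outcome, nm)
    roc[[nm]] <- roc_emp(p$score, outcome)
  }
  metrics <- do.call(rbind, metric_rows)
  rownames(metrics) <- NULL
  emit(metrics, "screening_metrics.csv")

  sub_metrics <- list()
  for (snm in names(config$subgroups)) {
    idx <- config$subgroups[[snm]](d)
    idx[is.na(idx)] <- FALSE
    if (sum(outcome[idx]) == 0 || sum(!outcome[idx]) == 0) next
    for (nm in config$evaluate) {
      p <- predictors[[nm]]
      if (is.null(p)) next
      sub_metrics[[paste(snm, nm, sep = ".")]] <-
        cbind(subgroup = snm, evaluate_binary(p$binary[idx], outcome[idx], nm))
    }
  }
  if (length(sub_metrics)) {
    sub_tab <- do.call(rbind, sub_metrics)
    rownames(sub_tab) <- NULL
    emit(sub_tab, "subgroup_metrics.csv")
  } else sub_tab <- NULL

  scan <- if ("mrai" %in% config$evaluate && !is.null(predictors$mrai)) {
    cutoff_scan(predictors$mrai$score, outcome, config$cutoffs)
  }
  if (!is.null(scan)) emit(as.data.frame(scan), "mrai_cutoff_scan.csv")

  comparison <- if (all(c("rai", "delta_scr") %in% config$evaluate)) {
    delong_test(predictors$rai$score, predictors$delta_scr$score, outcome)
  }

  for (nm in names(roc)) {
    emit(data.frame(threshold = roc[[nm]]$thresholds,
                    sensitivity = roc[[nm]]$sensitivity,
                    specificity = roc[[nm]]$specificity),
         paste0("roc_", nm, ".csv"))
  }

  result <- structure(list(
    validation = val, scored = scored, adjudication = attr(adj, "prevalence"),
    metrics = metrics, subgroup_metrics = sub_tab, cutoff_scan = scan,
    auc = vapply(roc, `[[`, numeric(1), "auc"), roc = roc,
    delong = comparison, out_dir = out_dir, seed = config$seed
  ), class = "pipeline_result")

  if (!is.null(out_dir)) {
    summary_path <- file.path(out_dir, "run_summary.json")
    jsonlite::write_json(list(
      n_rows = val$n_rows, seed = config$seed,
      evaluated = config$evaluate,
      saki_prevalence_pct = round_half_up(100 * result$adjudication$estimate, 1),
      auc = lapply(result$auc, round_half_up, 3),
      optimal_mrai_cutoff = if (!is.null(scan)) attr(scan, "best_cutoff"),
      outputs = basename(wrote)
    ), summary_path, auto_unbox = TRUE, pretty = TRUE, null = "null")
    wrote <- c(wrote, summary_path)
  }
  on.exit()  # success: keep outputs
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  pr <- x$adjudication
  cat(sprintf("Pipeline run over %d admissions\n", x$validation$n_rows))
  cat(sprintf("  severe-AKI prevalence: %s%%\n",
              fmt_pct_ci(100 * pr$estimate, 100 * pr$ci_low, 100 * pr$ci_high)))
  cat("\nScreening metrics (percent, 95% Wald CI):\n")
  for (sc in unique(x$metrics$score)) {
    rows <- x$metrics[x$metrics$score == sc, ]
    cat(sprintf("  %-10s %s\n", sc,
                paste(sprintf("%s %s", substr(rows$metric, 1, 4),
                              fmt_pct_ci(100 * rows$estimate, 100 * rows$ci_low,
                                         100 * rows$ci_high)),
                      collapse = "  ")))
  }
  cat("\nAUCs:", paste(sprintf("%s=%.2f", names(x$auc),
                               round_half_up(x$auc, 2)), collapse = "  "), "\n")
  if (!is.null(x$cutoff_scan))
    cat("Optimal modified-index cutoff (Youden): >=",
        attr(x$cutoff_scan, "best_cutoff"), "\n")
  if (!is.null(x$delong)) {
    cat("\nOriginal index vs creatinine ratio (DeLong): ")
    cat(sprintf("z = %.3f, p = %.3f\n", x$delong$z, x$delong$p_two_sided))
  }
  if (!is.null(x$out_dir)) cat("\nOutputs in", x$out_dir, "\n")
  invisible(x)
}
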