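# Two-phase study orchestration: cut-point estimation on a training cohort,
# frozen-cutoff assessment on a validation cohort, and the report tables.

score_cols <- function() c("lus_tot", "lus_v", "lus_i", "lus_d")

#' Normalize a cohort to labeled regional scores
#'
#' Accepts either an exam-level cohort (columns `field_01`..`field_12` plus
#' `morphology`), a score-level cohort (any of `lus_tot`, `lus_v`, `lus_i`,
#' `lus_d` plus `morphology`), or a reconstruction fixture (`score` column,
#' interpreted as the ventral score `lus_v`).
#'
#' @param x cohort data.frame.
#' @return data.frame with `morphology` and the available score columns.
#' @export
as_score_cohort <- function(x) {
  if (!is.data.frame(x)) fail("cohort must be a data.frame")
  if (all(field_cols() %in% names(x))) {
    if (!"morphology" %in% names(x)) fail("cohort lacks morphology labels")
    return(regional_scores(x))
  }
  if ("score" %in% names(x) && !"lus_v" %in% names(x)) {
    names(x)[names(x) == "score"] <- "lus_v"
  }
  if (!"morphology" %in% names(x)) fail("cohort lacks morphology labels")
  have <- intersect(score_cols(), names(x))
  if (!length(have)) fail("cohort carries neither exams nor scores")
  x$morphology <- as_truth(x$morphology)
  x
}

#' Median and interquartile range of scores by morphology
#'
#' Quantiles use linear interpolation between order statistics
#' (`stats::quantile()` type 7); this convention is fixed package-wide.
#' Empty strata are omitted rather than reported as zero.
#'
#' @param cohort cohort accepted by [as_score_cohort()].
#' @return data.frame with `morphology`, `score`, `n`, `median`, `q1`, `q3`.
#' @export
#' @examples
#' summarize_cohort(training_fixture())
summarize_cohort <- function(cohort) {
  sc <- as_score_cohort(cohort)
  have <- intersect(score_cols(), names(sc))
  out <- NULL
  for (morph in morphology_levels()) {
    stratum <- sc[sc$morphology == morph, , drop = FALSE]
    if (nrow(stratum) == 0L) next
    for (col in have) {
      q <- stats::quantile(stratum[[col]], c(0.25, 0.5, 0.75),
                           type = 7, names = FALSE)
      out <- rbind(out, data.frame(
        morphology = morph, score = col, n = nrow(stratum),
        median = q[2], q1 = q[1], q3 = q[3], stringsAsFactors = FALSE
      ))
    }
  }
  out
}

#' Run the two-phase diagnostic accuracy study
#'
#' Phase 1: empirical ROC tables for every available regional score on the
#' training cohort; the operating cutoff is the Youden-optimal cutoff of
#' `cutoff_region` (ventral by default), chosen from the training cohort
#' only. Phase 2: the frozen cutoff is applied unchanged to the validation
#' cohort and summarized with exact 95% CIs.
#'
#' @param training,validation cohorts accepted by [as_score_cohort()]; each
#'   must contain both morphology classes.
#' @param cutoff_region score column used for cut-point selection
#'   (default `"lus_v"`).
#' @param group_tests also compute pass-through focal vs non-focal
#'   Mann-Whitney p-values per score column (`stats::wilcox.test()`; routine
#'   statistics, not part of the package's tested surface).
#' @return object of class `lus_study`: list with `training_summary`,
#'   `validation_summary`, `roc` (per-score `lus_roc` list, training),
#'   `auc`, `chosen_cutoff`, `cutoff_region`, `validation_accuracy`
#'   (`lus_diag`), and optionally `group_tests`.
#' @export
#' @examples
#' run_study(training_fixture(), validation_fixture())
run_study <- function(training, validation, cutoff_region = "lus_v",
                      group_tests = FALSE) {
  tr <- as_score_cohort(training)
  va <- as_score_cohort(validation)
  have <- intersect(score_cols(), names(tr))
  if (!cutoff_region %in% have) {
    fail("training cohort lacks the cutoff region column %s", cutoff_region)
  }
  if (!cutoff_region %in% names(va)) {
    fail("validation cohort lacks the cutoff region column %s", cutoff_region)
  }
  roc <- lapply(have, function(col) empirical_roc(tr[[col]], tr$morphology))
  names(roc) <- have
  chosen <- youden_cutoff(roc[[cutoff_region]])
  acc <- diagnostic_summary(va[[cutoff_region]], va$morphology, chosen)
  out <- list(
    training_summary = summarize_cohort(tr),
    validation_summary = summarize_cohort(va),
    roc = roc,
    auc = vapply(roc, function(r) r$auc, numeric(1)),
    chosen_cutoff = chosen,
    cutoff_region = cutoff_region,
    validation_accuracy = acc
  )
  if (group_tests) {
    out$group_tests <- do.call(rbind, lapply(have, function(col) {
      p <- stats::wilcox.test(tr[[col]] ~ tr$morphology, exact = FALSE)$p.value
      data.frame(score = col, cohort = "training", p_value = p,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(out, class = "lus_study")
}

#' @export
print.lus_study <- function(x, ...) {
  cat("Two-phase LUS morphology study\n")
  cat(sprintf("Training AUCs: %s\n",
              paste(sprintf("%s %.4f", names(x$auc), x$auc), collapse = ", ")))
  cat(sprintf("Chosen cutoff (%s, Youden): >= %d\n",
              x$cutoff_region, x$chosen_cutoff))
  print(x$validation_accuracy)
  invisible(x)
}

#' Write a study report to a directory
#'
#' Emits `table2.csv` (score summaries of both cohorts), one
#' `table3_<score>.csv` per training ROC table in printed format,
#' `summary.json` (counts, estimates, CIs and the conventions in force) and
#' `conventions.txt`. Output is deterministic for identical inputs.
#'
#' @param study `lus_study` object.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  t2 <- rbind(
    cbind(cohort = "training", study$training_summary),
    cbind(cohort = "validation", study$validation_summary)
  )
  utils::write.csv(t2, file.path(dir, "table2.csv"), row.names = FALSE,
                   quote = FALSE)
  for (col in names(study$roc)) {
    write_roc(study$roc[[col]], file.path(dir, sprintf("table3_%s.csv", col)))
  }
  acc <- study$validation_accuracy
  summary <- list(
    cutoff_region = study$cutoff_region,
    chosen_cutoff = study$chosen_cutoff,
    training_auc = as.list(round(study$auc, 6)),
    validation = list(
      tp = acc$tp, fp = acc$fp, tn = acc$tn, fn = acc$fn,
      metrics = acc$metrics
    ),
    conventions = report_conventions()
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows", pretty = TRUE)
  writeLines(unlist(report_conventions()), file.path(dir, "conventions.txt"))
  invisible(dir)
}

report_conventions <- function() {
  list(
    positive_class = "non-focal; test positive at score >= cutoff",
    quantiles = "linear interpolation between order statistics (type 7)",
    table_rounding = "percentages 2 decimals, likelihood ratios 4 decimals",
    narrative_rounding = "whole percent, half away from zero",
    ci_method = "Clopper-Pearson exact, 95%",
    rounding_rule_version = "1"
  )
}
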