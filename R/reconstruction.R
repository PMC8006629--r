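# Reconstruction of the study cohorts from printed results.
#
# A complete empirical ROC table determines the per-class score multisets
# exactly: between consecutive listed cutoffs the sensitivity drop gives the
# number of positives holding the lower cutoff's value, and the specificity
# rise gives the number of negatives there (a value absent from the cutoff
# column was held by no patient, else it would be an operating point). The
# published training table (20 non-focal / 5 focal ventral scores) and the
# validation confusion matrix (16 non-focal / 6 focal at cutoff 3) are both
# uniquely invertible.

#' Published training-set ROC operating points
#'
#' The printed operating-point table of the ventral LUS score for non-focal
#' morphology in the 25-patient training set: cutoffs 0, 1, 3, 4, 6, 7, 8, 9
#' and the "> 9" sentinel, with sensitivity/specificity percentages and the
#' derived correctly-classified and likelihood-ratio columns (blank LRs,
#' i.e. division by zero, stored as `NA`). The printed trapezoidal ROC area
#' for this table is 0.9600.
#'
#' @return data.frame with columns `cutoff` (`Inf` for the sentinel row),
#'   `sensitivity_pct`, `specificity_pct`, `correct_pct`, `lr_pos`,
#'   `lr_neg`.
#' @export
table3_operating_points <- function() {
  data.frame(
    cutoff = c(0, 1, 3, 4, 6, 7, 8, 9, Inf),
    sensitivity_pct = c(100, 95, 95, 85, 75, 40, 35, 15, 0),
    specificity_pct = c(0, 40, 100, 100, 100, 100, 100, 100, 100),
    correct_pct = c(80, 84, 96, 88, 80, 52, 48, 32, 20),
    lr_pos = c(1.0000, 1.5833, NA, NA, NA, NA, NA, NA, NA),
    lr_neg = c(NA, 0.1250, 0.0500, 0.1500, 0.2500, 0.6000, 0.6500,
               0.8500, 1.0000)
  )
}

new_fixture_cohort <- function(score_pos, score_neg, provenance) {
  out <- data.frame(
    score = as.integer(c(score_pos, score_neg)),
    morphology = factor(
      rep(c("non-focal", "focal"), c(length(score_pos), length(score_neg))),
      levels = morphology_levels()
    ),
    stringsAsFactors = FALSE
  )
  attr(out, "provenance") <- provenance
  out
}

#' Invert a printed ROC table into per-class score multisets
#'
#' Reconstructs the exact labeled cohort behind an empirical ROC table. For
#' consecutive cutoffs `c_k < c_{k+1}` the number of positives with score
#' `c_k` is `n_pos * (sens(c_k) - sens(c_{k+1})) / 100`, and the number of
#' negatives there is `n_neg * (spec(c_{k+1}) - spec(c_k)) / 100`; values
#' absent from the cutoff column were held by no patient. Implied counts
#' must be integers (up to print rounding), otherwise the offending row is
#' reported. The round trip `empirical_roc()` on the result reproduces the
#' input rows exactly.
#'
#' @param rows data.frame with columns `cutoff` (increasing, starting at 0,
#'   ending with an `Inf` sentinel), `sensitivity_pct`, `specificity_pct`.
#' @param n_pos,n_neg class sizes (positives = non-focal).
#' @param tol tolerance for the integrality check on implied counts.
#' @return fixture cohort data.frame (`score`, `morphology`) with a
#'   `provenance` attribute `"inverted_roc"`.
#' @export
#' @examples
#' fix <- invert_roc_table(table3_operating_points(), n_pos = 20, n_neg = 5)
#' table(fix$score, fix$morphology)
invert_roc_table <- function(rows, n_pos, n_neg, tol = 0.1) {
  need <- c("cutoff", "sensitivity_pct", "specificity_pct")
  if (!is.data.frame(rows) || !all(need %in% names(rows))) {
    fail("rows must have columns %s", paste(need, collapse = ", "))
  }
  rows <- rows[order(rows$cutoff), need]
  k <- nrow(rows)
  if (k < 2L) fail("need at least the cutoff-0 row and the sentinel row")
  if (rows$cutoff[1] != 0 || !is.infinite(rows$cutoff[k])) {
    fail("table must start at cutoff 0 and end with the sentinel row")
  }
  if (rows$sensitivity_pct[1] != 100 || rows$specificity_pct[1] != 0 ||
      rows$sensitivity_pct[k] != 0 || rows$specificity_pct[k] != 100) {
    fail("anchor rows must be (sens 100, spec 0) and (sens 0, spec 100)")
  }
  if (any(diff(rows$sensitivity_pct) > 1e-9) ||
      any(diff(rows$specificity_pct) < -1e-9)) {
    fail("sensitivity must be non-increasing and specificity non-decreasing")
  }
  vals <- rows$cutoff[-k]
  d_sens <- -diff(rows$sensitivity_pct)
  d_spec <- diff(rows$specificity_pct)
  pos_counts <- n_pos * d_sens / 100
  neg_counts <- n_neg * d_spec / 100
  check_integral <- function(counts, what) {
    off <- abs(counts - round(counts))
    if (any(off > tol)) {
      i <- which.max(off)
      fail("non-integral implied %s count %.4f at cutoff %s",
           what, counts[i], format(vals[i]))
    }
    as.integer(round(counts))
  }
  pos_counts <- check_integral(pos_counts, "positive")
  neg_counts <- check_integral(neg_counts, "negative")
  if (sum(pos_counts) != n_pos || sum(neg_counts) != n_neg) {
    fail("implied counts do not sum to the stated class sizes")
  }
  new_fixture_cohort(
    rep(vals, pos_counts), rep(vals, neg_counts), "inverted_roc"
  )
}

#' Reconstructed 25-patient training cohort
#'
#' Inverts the published training ROC table ([table3_operating_points()])
#' with class sizes 20 non-focal / 5 focal, yielding the exact ventral-score
#' multisets: non-focal `{0, 3, 3, 4, 4, 6 x7, 7, 8 x4, 9 x3}`, focal
#' `{0, 0, 1, 1, 1}`.
#'
#' @return fixture cohort data.frame with provenance `"training_table3"`.
#' @export
training_fixture <- function() {
  fix <- invert_roc_table(table3_operating_points(), n_pos = 20, n_neg = 5)
  attr(fix, "provenance") <- "training_table3"
  fix
}

#' Deterministic 22-patient validation cohort
#'
#' The validation confusion matrix at cutoff 3 is uniquely determined by the
#' published accuracy metrics: sensitivity 94% of 16 non-focal patients
#' forces 15 true positives and 1 false negative, specificity 100% of 6
#' focal patients forces 6 true negatives. Within those strata the ventral
#' scores are fixed constants chosen to match the published validation
#' medians and quartiles: non-focal 6 (IQR 4-7); focal median 2 with upper
#' quartile capped at 2 (the printed upper bound 3 is unattainable when all
#' focal patients score below the cutoff).
#'
#' @return fixture cohort data.frame with provenance `"validation_results"`.
#' @export
validation_fixture <- function() {
  nonfocal <- c(2, 3, 3, 4, 4, 5, 5, 6, 6, 6, 7, 7, 7, 8, 9, 10)
  focal <- c(1, 1, 2, 2, 2, 2)
  new_fixture_cohort(nonfocal, focal, "validation_results")
}

#' Write a fixture cohort to CSV
#'
#' @param fixture cohort from [training_fixture()], [validation_fixture()]
#'   or [invert_roc_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(fixture, path) {
  utils::write.csv(fixture, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
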