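# Diagnostic accuracy machinery: empirical ROC tables, Youden cut-point,
# confusion-matrix summaries with exact binomial CIs, Cohen's kappa.
#
# Conventions, fixed package-wide:
#   * positive class  = "non-focal" morphology;
#   * test positive  <=> score >= cutoff;
#   * one ROC row per element of {0} U {observed scores}, plus a final
#     "greater than max" sentinel row (sensitivity 0, specificity 100);
#   * AUC by the trapezoidal rule over the (1 - specificity, sensitivity)
#     polyline, anchored at (0,0) and (1,1) by the sentinel and zero rows.

positive_class <- function() "non-focal"

as_truth <- function(truth) {
  tr <- factor(as.character(truth), levels = morphology_levels())
  if (anyNA(tr)) {
    fail("truth labels must be in {%s}",
         paste(morphology_levels(), collapse = ", "))
  }
  tr
}

check_cohort <- function(score, truth) {
  if (length(score) != length(truth)) fail("score and truth lengths differ")
  if (anyNA(score) || any(score < 0) || any(score != floor(score))) {
    fail("scores must be non-negative integers")
  }
  tr <- as_truth(truth)
  if (nlevels(droplevels(tr)) < 2L) {
    fail("cohort must contain both focal and non-focal patients")
  }
  tr
}

#' Empirical ROC table for a labeled score cohort
#'
#' Builds the full operating-point table of the score as a test for
#' non-focal morphology (test positive at `score >= cutoff`), one row per
#' cutoff in `{0}` plus every observed score value, closed by a sentinel row
#' one past the maximum observed score ("> max", sensitivity 0, specificity
#' 100). The area under the curve is the trapezoidal area of the
#' `(1 - specificity, sensitivity)` polyline.
#'
#' @param score integer vector of non-negative scores.
#' @param truth morphology labels (`focal` / `non-focal`); both classes must
#'   be present.
#' @return object of class `lus_roc`: list with elements `table` (data.frame
#'   of `cutoff`, `label`, `tp`, `fn`, `tn`, `fp`, `sensitivity_pct`,
#'   `specificity_pct`, `correct_pct`, `lr_pos`, `lr_neg`; likelihood ratios
#'   are `NA` where their denominator is zero), `auc`, `n_pos`, `n_neg`.
#' @export
#' @examples
#' roc <- empirical_roc(c(0, 1, 3, 5), c("focal", "focal", "non-focal", "non-focal"))
#' roc$auc
empirical_roc <- function(score, truth) {
  tr <- check_cohort(score, truth)
  pos <- tr == positive_class()
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  maxs <- max(score)
  cutoffs <- c(sort(unique(c(0L, as.integer(score)))), maxs + 1L)
  rows <- lapply(cutoffs, function(cf) {
    test_pos <- score >= cf
    tp <- sum(test_pos & pos)
    fp <- sum(test_pos & !pos)
    fn <- n_pos - tp
    tn <- n_neg - fp
    sens <- tp / n_pos
    spec <- tn / n_neg
    data.frame(
      cutoff = cf,
      label = if (cf > maxs) sprintf("> %d", maxs) else sprintf(">= %d", cf),
      tp = tp, fn = fn, tn = tn, fp = fp,
      sensitivity_pct = 100 * sens,
      specificity_pct = 100 * spec,
      correct_pct = 100 * (tp + tn) / (n_pos + n_neg),
      lr_pos = if (spec < 1) sens / (1 - spec) else NA_real_,
      lr_neg = if (spec > 0) (1 - sens) / spec else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  x <- 1 - tab$specificity_pct / 100
  y <- tab$sensitivity_pct / 100
  ord <- order(x, y)
  x <- x[ord]; y <- y[ord]
  auc <- sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
  structure(
    list(table = tab, auc = auc, n_pos = n_pos, n_neg = n_neg),
    class = "lus_roc"
  )
}

# printed rendering of a ROC table: percentages to 2 decimals, likelihood
# ratios to 4, undefined LRs blank
format_roc_table <- function(roc) {
  tab <- roc$table
  data.frame(
    cutoff = tab$label,
    sensitivity_pct = sprintf("%.2f", round_half_up(tab$sensitivity_pct, 2)),
    specificity_pct = sprintf("%.2f", round_half_up(tab$specificity_pct, 2)),
    correct_pct = sprintf("%.2f", round_half_up(tab$correct_pct, 2)),
    lr_pos = ifelse(is.na(tab$lr_pos), "",
                    sprintf("%.4f", round_half_up(tab$lr_pos, 4))),
    lr_neg = ifelse(is.na(tab$lr_neg), "",
                    sprintf("%.4f", round_half_up(tab$lr_neg, 4))),
    stringsAsFactors = FALSE
  )
}

#' @export
print.lus_roc <- function(x, ...) {
  cat(sprintf(
    "Empirical ROC, positive class %s (%d positive / %d negative)\n",
    positive_class(), x$n_pos, x$n_neg
  ))
  print(format_roc_table(x), row.names = FALSE)
  cat(sprintf("Trapezoidal AUC: %.4f\n", x$auc))
  invisible(x)
}

#' Write a ROC table to CSV in its printed format
#'
#' @param roc `lus_roc` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_roc <- function(roc, path) {
  utils::write.csv(format_roc_table(roc), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Youden-optimal cutoff of a ROC table
#'
#' Maximizes the Youden index J = sensitivity + specificity - 1 over the
#' table's operating points; ties are broken toward the smallest cutoff.
#'
#' @param roc `lus_roc` object from [empirical_roc()].
#' @return single integer cutoff.
#' @export
youden_cutoff <- function(roc) {
  if (!inherits(roc, "lus_roc")) fail("roc must be an lus_roc object")
  tab <- roc$table
  j <- tab$sensitivity_pct + tab$specificity_pct - 100
  best <- which(j >= max(j) - 1e-9)
  as.integer(min(tab$cutoff[best]))
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Tail-inversion interval for a binomial proportion via Beta quantiles;
#' matches `stats::binom.test()`. Conservative: coverage is at least the
#' nominal level.
#'
#' @param x number of successes (vectorized).
#' @param n number of trials.
#' @param conf confidence level, default 0.95.
#' @return data.frame with columns `estimate`, `lower`, `upper`.
#' @export
#' @examples
#' cp_interval(15, 16) # lower bound ~ 0.698, printed as 70%
cp_interval <- function(x, n, conf = 0.95) {
  if (any(x < 0 | x > n) || any(n < 1)) fail("need 0 <= x <= n, n >= 1")
  a <- (1 - conf) / 2
  lower <- ifelse(x == 0, 0, stats::qbeta(a, x, n - x + 1))
  upper <- ifelse(x == n, 1, stats::qbeta(1 - a, x + 1, n - x))
  data.frame(estimate = x / n, lower = lower, upper = upper)
}

#' Diagnostic accuracy summary at a fixed cutoff
#'
#' Confusion counts and sensitivity, specificity, PPV and NPV (with exact
#' 95% Clopper-Pearson CIs) of `score >= cutoff` as a test for non-focal
#' morphology. Predictive values come from the cohort's own confusion
#' matrix, with no external prevalence adjustment; a predictive value whose
#' predicted class is empty is reported as `NA` (absent), not 0.
#'
#' @param score integer vector of scores.
#' @param truth morphology labels (`focal` / `non-focal`).
#' @param cutoff single integer cutoff.
#' @param conf confidence level, default 0.95.
#' @return object of class `lus_diag`: list with `cutoff`, counts `tp`,
#'   `fp`, `tn`, `fn`, and `metrics` (data.frame of `metric`, `x`, `n`,
#'   `estimate`, `lower`, `upper`).
#' @export
#' @examples
#' fix <- validation_fixture()
#' diagnostic_summary(fix$score, fix$morphology, cutoff = 3)
diagnostic_summary <- function(score, truth, cutoff, conf = 0.95) {
  tr <- check_cohort(score, truth)
  if (length(cutoff) != 1L || is.na(cutoff) || cutoff != floor(cutoff)) {
    fail("cutoff must be a single integer")
  }
  pos <- tr == positive_class()
  test_pos <- score >= cutoff
  tp <- sum(test_pos & pos); fp <- sum(test_pos & !pos)
  fn <- sum(!test_pos & pos); tn <- sum(!test_pos & !pos)
  cell <- function(metric, x, n) {
    if (n == 0L) {
      return(data.frame(metric = metric, x = NA_integer_, n = 0L,
                        estimate = NA_real_, lower = NA_real_,
                        upper = NA_real_))
    }
    ci <- cp_interval(x, n, conf)
    data.frame(metric = metric, x = x, n = n, estimate = ci$estimate,
               lower = ci$lower, upper = ci$upper)
  }
  metrics <- rbind(
    cell("sensitivity", tp, tp + fn),
    cell("specificity", tn, tn + fp),
    cell("ppv", tp, tp + fp),
    cell("npv", tn, tn + fn)
  )
  structure(
    list(cutoff = as.integer(cutoff), tp = tp, fp = fp, tn = tn, fn = fn,
         conf = conf, metrics = metrics),
    class = "lus_diag"
  )
}

#' @export
print.lus_diag <- function(x, ...) {
  cat(sprintf("Diagnostic accuracy at cutoff >= %d (positive = %s)\n",
              x$cutoff, positive_class()))
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  for (i in seq_len(nrow(x$metrics))) {
    m <- x$metrics[i, ]
    if (is.na(m$estimate)) {
      cat(sprintf("  %-11s absent (no patients in predicted class)\n",
                  m$metric))
    } else {
      cat(sprintf(
        "  %-11s %d/%d = %.0f%% (%.0f%% CI %.0f-%.0f%%)\n",
        m$metric, m$x, m$n, round_half_up(100 * m$estimate),
        100 * x$conf, round_half_up(100 * m$lower),
        round_half_up(100 * m$upper)
      ))
    }
  }
  invisible(x)
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with `p_e`
#' from the product of marginal category frequencies, and a 95% CI from the
#' Fleiss-Cohen-Everitt large-sample standard error.
#'
#' @param ratings_a,ratings_b equal-length vectors of categorical ratings
#'   over the same category set.
#' @param conf confidence level, default 0.95.
#' @return list with `kappa`, `se`, `ci` (length-2 numeric, clipped to
#'   `[-1, 1]`), `p_o`, `p_e`, `n`.
#' @export
#' @examples
#' cohens_kappa(c("N", "B1", "B2"), c("N", "B1", "B2"))$kappa # 1
cohens_kappa <- function(ratings_a, ratings_b, conf = 0.95) {
  if (length(ratings_a) != length(ratings_b)) {
    fail("rating vectors must have equal length")
  }
  n <- length(ratings_a)
  if (n < 2L) fail("need at least 2 paired ratings")
  cats <- sort(unique(c(as.character(ratings_a), as.character(ratings_b))))
  if (length(cats) < 2L) {
    fail("fewer than 2 categories observed; kappa is undefined")
  }
  a <- factor(as.character(ratings_a), levels = cats)
  b <- factor(as.character(ratings_b), levels = cats)
  p <- table(a, b) / n
  pi_ <- rowSums(p)   # marginal of rater a
  p_j <- colSums(p)   # marginal of rater b
  p_o <- sum(diag(p))
  p_e <- sum(pi_ * p_j)
  kappa <- (p_o - p_e) / (1 - p_e)
  # Fleiss, Cohen & Everitt large-sample variance
  k1 <- 1 - kappa
  a_term <- sum(diag(p) * (1 - (pi_ + p_j) * k1)^2)
  b_mat <- p * outer(p_j, pi_, "+")^2
  diag(b_mat) <- 0
  b_term <- k1^2 * sum(b_mat)
  c_term <- (kappa - p_e * k1)^2
  var_k <- (a_term + b_term - c_term) / (n * (1 - p_e)^2)
  se <- sqrt(max(var_k, 0))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- pmin(1, pmax(-1, kappa + c(-1, 1) * z * se))
  list(kappa = kappa, se = se, ci = ci, p_o = p_o, p_e = p_e, n = n)
}
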