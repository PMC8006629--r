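# Independent oracles and small generators used across the suite.

# Mann-Whitney tie-corrected probability that a non-focal score exceeds a
# focal one: brute force over all class pairs.
mw_auc <- function(score, truth) {
  s_pos <- score[truth == "non-focal"]
  s_neg <- score[truth == "focal"]
  cmp <- outer(s_neg, s_pos, function(a, b) (a < b) + 0.5 * (a == b))
  mean(cmp)
}

# per-pixel if/else aeration binning, independent of classify_hu
brute_fractions <- function(hu) {
  counts <- c(hyperinflated = 0, normal = 0, poor = 0, non_aerated = 0,
              excluded = 0)
  for (v in hu) {
    lab <- if (v < -1000) "excluded"
      else if (v < -900) "hyperinflated"
      else if (v < -500) "normal"
      else if (v < -100) "poor"
      else if (v <= 100) "non_aerated"
      else "excluded"
    counts[lab] <- counts[lab] + 1
  }
  counts / length(hu)
}

# random labeled cohort guaranteed to hold both classes
random_labeled_cohort <- function(n, max_score = 12) {
  truth <- c("focal", "non-focal",
             sample(c("focal", "non-focal"), n - 2, replace = TRUE))
  list(score = sample(0:max_score, n, replace = TRUE), truth = truth)
}

# random 12-field exam table
random_exam_df <- function(n) {
  m <- matrix(sample(c("N", "B1", "B2", "C"), 12 * n, replace = TRUE), n, 12)
  out <- data.frame(patient_id = sprintf("R%03d", seq_len(n)), m,
                    stringsAsFactors = FALSE)
  names(out)[-1] <- sprintf("field_%02d", 1:12)
  out
}
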