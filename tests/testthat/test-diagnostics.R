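test_that("ROC tables carry the anchor rows and monotone columns", {
  roc <- empirical_roc(c(0, 0, 1, 1), c("focal", "focal", "non-focal", "non-focal"))
  tab <- roc$table
  expect_equal(tab$sensitivity_pct[1], 100)
  expect_equal(tab$specificity_pct[1], 0)
  expect_equal(tab$sensitivity_pct[nrow(tab)], 0)
  expect_equal(tab$specificity_pct[nrow(tab)], 100)
  expect_equal(roc$auc, 1) # perfect separation
  # uninformative test: every patient identical -> trapezoidal ties give 0.5
  flat <- empirical_roc(rep(4, 6), rep(c("focal", "non-focal"), 3))
  expect_equal(flat$auc, 0.5)
  expect_error(empirical_roc(1:3, rep("focal", 3)), "both")
  expect_error(empirical_roc(c(-1, 2), c("focal", "non-focal")), "integer")
})

test_that("ROC columns are monotone and AUC equals the rank statistic", {
  set.seed(303)
  for (i in 1:300) {
    co <- random_labeled_cohort(sample(4:50, 1))
    roc <- empirical_roc(co$score, co$truth)
    expect_true(all(diff(roc$table$sensitivity_pct) <= 1e-9))
    expect_true(all(diff(roc$table$specificity_pct) >= -1e-9))
    expect_equal(roc$auc, mw_auc(co$score, co$truth), tolerance = 1e-12)
  }
})

test_that("trapezoidal AUC agrees with pROC on random cohorts", {
  skip_if_not_installed("pROC")
  set.seed(404)
  for (i in 1:20) {
    co <- random_labeled_cohort(sample(6:40, 1))
    ours <- empirical_roc(co$score, co$truth)$auc
    ref <- suppressMessages(pROC::auc(pROC::roc(
      response = co$truth, predictor = co$score,
      levels = c("focal", "non-focal"), direction = "<"
    )))
    expect_equal(ours, as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("Youden selection maximizes J and breaks ties downward", {
  sep <- empirical_roc(c(0, 0, 5, 5), c("focal", "focal", "non-focal", "non-focal"))
  expect_equal(youden_cutoff(sep), 5) # the only listed cutoff attaining J = 1
  gap <- empirical_roc(c(0, 1, 3), c("focal", "non-focal", "non-focal"))
  expect_equal(youden_cutoff(gap), 1) # smallest listed cutoff attaining J = 1
  flat <- empirical_roc(rep(4, 6), rep(c("focal", "non-focal"), 3))
  expect_equal(youden_cutoff(flat), 0) # J = 0 everywhere
  expect_error(youden_cutoff(list()), "lus_roc")
})

test_that("Clopper-Pearson intervals match binom.test and the closed forms", {
  for (n in c(6, 10, 16, 25)) {
    for (x in c(0, 1, floor(n / 2), n - 1, n)) {
      ci <- cp_interval(x, n)
      ref <- binom.test(x, n)$conf.int
      expect_equal(c(ci$lower, ci$upper), as.numeric(ref), tolerance = 1e-9)
    }
  }
  expect_equal(cp_interval(6, 6)$lower, 0.025^(1 / 6), tolerance = 1e-12)
  expect_equal(cp_interval(15, 16)$lower, 0.6977, tolerance = 1e-4)
  expect_error(cp_interval(7, 6), "x <= n")
})

test_that("exact intervals cover the true proportion at least 95% of the time", {
  set.seed(505)
  for (p in c(0.1, 0.5, 0.9)) {
    for (n in c(10, 25)) {
      x <- rbinom(2000, n, p)
      ci <- cp_interval(x, n)
      expect_gte(mean(ci$lower <= p & p <= ci$upper), 0.95)
    }
  }
})

test_that("diagnostic summaries behave at the degenerate cutoffs", {
  co <- random_labeled_cohort(30)
  everyone <- diagnostic_summary(co$score, co$truth, 0)
  m <- everyone$metrics
  expect_equal(m$estimate[m$metric == "sensitivity"], 1)
  expect_equal(m$estimate[m$metric == "specificity"], 0)
  expect_true(is.na(m$estimate[m$metric == "npv"])) # nobody predicted focal
  nobody <- diagnostic_summary(co$score, co$truth, max(co$score) + 1)
  m <- nobody$metrics
  expect_equal(m$estimate[m$metric == "sensitivity"], 0)
  expect_equal(m$estimate[m$metric == "specificity"], 1)
  expect_true(is.na(m$estimate[m$metric == "ppv"])) # nobody predicted non-focal
  expect_true(all(m$lower <= m$estimate & m$estimate <= m$upper, na.rm = TRUE))
})

test_that("Cohen's kappa matches its definition and reference values", {
  expect_equal(cohens_kappa(c("N", "B1", "B2"), c("N", "B1", "B2"))$kappa, 1)
  # constructed 2x2 table with p_o = 0.9, p_e = 0.5 -> kappa = 0.8
  a <- rep(c("x", "x", "y", "y"), c(9, 1, 1, 9))
  b <- rep(c("x", "y", "x", "y"), c(9, 1, 1, 9))
  k <- cohens_kappa(a, b)
  expect_equal(k$p_o, 0.9)
  expect_equal(k$p_e, 0.5)
  expect_equal(k$kappa, 0.8)
  expect_true(k$ci[1] <= 0.8 && 0.8 <= k$ci[2])
  # independent raters agree only by chance
  set.seed(606)
  r1 <- sample(c("N", "B1", "B2", "C"), 5000, replace = TRUE)
  r2 <- sample(c("N", "B1", "B2", "C"), 5000, replace = TRUE)
  expect_lt(abs(cohens_kappa(r1, r2)$kappa), 0.05)
  expect_error(cohens_kappa(1:3, 1:4), "equal length")
  expect_error(cohens_kappa(rep("N", 5), rep("N", 5)), "2 categories")
})

test_that("kappa point estimate agrees with e1071's", {
  skip_if_not_installed("e1071")
  set.seed(707)
  for (i in 1:10) {
    r1 <- sample(c("a", "b", "c"), 60, replace = TRUE)
    r2 <- ifelse(runif(60) < 0.6, r1, sample(c("a", "b", "c"), 60, replace = TRUE))
    ref <- e1071::classAgreement(table(factor(r1, levels = c("a", "b", "c")),
                                       factor(r2, levels = c("a", "b", "c"))))
    expect_equal(cohens_kappa(r1, r2)$kappa, ref$kappa, tolerance = 1e-12)
  }
})
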