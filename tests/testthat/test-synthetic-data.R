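# Generator and calibration. Cohort-scale checks use modest n so the suite
# stays fast; the acceptance tests run the full 2000-patient design.

test_that("cohorts are reproducible and patient substreams are stable", {
  cfg <- generator_config(n_patients = 60, seed = 123)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  bigger <- generate_cohort(generator_config(n_patients = 90, seed = 123))
  expect_identical(bigger[1:60, names(a)], a)
  different <- generate_cohort(generator_config(n_patients = 60, seed = 124))
  expect_false(identical(different$morphology, a$morphology) &&
                 identical(different$field_01, a$field_01))
})

test_that("prevalence extremes and invalid configurations are handled", {
  all_focal <- generate_cohort(
    generator_config(n_patients = 30, prevalence_nonfocal = 0, seed = 5)
  )
  expect_true(all(all_focal$morphology == "focal"))
  all_nf <- generate_cohort(
    generator_config(n_patients = 30, prevalence_nonfocal = 1, seed = 5)
  )
  expect_true(all(all_nf$morphology == "non-focal"))
  expect_error(generator_config(0, seed = 1), "positive")
  expect_error(generator_config(10, prevalence_nonfocal = 1.2), "prevalence")
  bad <- default_calibration()$region_pattern_probs
  bad$focal$ventral$probs[1, ] <- c(0.5, 0.5, 0.5, 0.5)
  expect_error(generator_config(10, region_pattern_probs = bad), "sum to 1")
})

test_that("calibration reproduces the published regional quantiles", {
  cal <- default_calibration()
  expect_true(all(cal$achieved$median_dev == 0))
  expect_true(all(cal$achieved$iqr_dev <= 1))
  expect_true(all(cal$achieved$median_margin >= 0.05))
  expect_equal(cal$ventral$youden_cutoff, 3)
  expect_gte(cal$ventral$auc, 0.9)
  # focal dorsal needs the latent severity mixture; the rest stay i.i.d.
  ach <- cal$achieved
  expect_equal(ach$n_regimes[ach$morphology == "focal" &
                               ach$region == "dorsal"], 2)
})

test_that("degenerate all-zero targets calibrate to the all-normal pattern", {
  targets <- table2_targets()
  targets$median <- targets$q1 <- targets$q3 <- 0
  cal <- suppressWarnings(calibrate_to_table2(targets))
  expect_true(all(cal$achieved$median_dev == 0))
  expect_true(all(cal$achieved$iqr_dev == 0))
  # score 0 dominates every cell; quantiles are met exactly
  p_n <- vapply(morphology_levels(), function(m) {
    cal$region_pattern_probs[[m]]$dorsal$probs[1, 1]
  }, numeric(1))
  expect_true(all(p_n > 0.5))
  expect_true(all(cal$achieved$median == 0 & cal$achieved$q1 == 0 &
                    cal$achieved$q3 == 0))
  bad <- table2_targets()
  bad$q3[1] <- 13
  expect_error(calibrate_to_table2(bad), "0..12")
})

test_that("synthetic ROIs are truncated and shift with the field score", {
  cfg <- generator_config(n_patients = 5, seed = 31)
  set.seed(99)
  hu0 <- generate_roi(0, "focal", cfg, n_pixels = 20000)
  hu3 <- generate_roi(3, "focal", cfg, n_pixels = 20000)
  expect_true(all(hu0 >= -1000 & hu0 <= 100))
  expect_true(all(hu3 >= -1000 & hu3 <= 100))
  f0 <- quantify_roi(hu0)
  f3 <- quantify_roi(hu3)
  # score 0 is dominated by normal aeration; consolidation flips the balance
  expect_equal(names(which.max(f0[1:4])), "normal")
  expect_gt(f3[["non_aerated"]], f0[["non_aerated"]])
  expect_lt(f3[["normal"]], f0[["normal"]])
  expect_error(generate_roi(4, "focal", cfg), "0..3")
})

test_that("empirical compartment fractions converge to the mixture weights", {
  cfg <- generator_config(n_patients = 5, seed = 31)
  set.seed(1234)
  for (case in list(c(0, "focal"), c(2, "non-focal"), c(3, "focal"))) {
    sc <- as.integer(case[1])
    f <- quantify_roi(generate_roi(sc, case[2], cfg, n_pixels = 1e5))
    w <- cfg$hu_mixture$weights[[case[2]]][sc + 1, ]
    expect_lt(max(abs(f[names(w)] - w)), 0.02)
  }
})

test_that("simulated focal patients show the gravity gradient", {
  cfg <- generator_config(n_patients = 500, seed = 77)
  sc <- regional_scores(generate_cohort(cfg))
  s <- summarize_cohort(sc)
  focal_v <- s$median[s$morphology == "focal" & s$score == "lus_v"]
  focal_d <- s$median[s$morphology == "focal" & s$score == "lus_d"]
  expect_gt(focal_d, focal_v)
})

test_that("exam fields and ROI profiles stay consistent within a patient", {
  cfg <- generator_config(n_patients = 4, seed = 55, roi_pixels = 4000)
  co <- generate_cohort(cfg, include_rois = TRUE)
  expect_equal(length(co$rois), 4)
  expect_true(all(vapply(co$rois, length, integer(1)) == 12))
  # a consolidated field's ROI must be less normally aerated than a clear one
  sc <- matrix(score_field(as.vector(as.matrix(
    co[, sprintf("field_%02d", 1:12)]
  ))), nrow = 4)
  hi <- which(sc == 3, arr.ind = TRUE)
  lo <- which(sc == 0, arr.ind = TRUE)
  if (nrow(hi) > 0 && nrow(lo) > 0) {
    f_hi <- quantify_roi(co$rois[[hi[1, 1]]][[hi[1, 2]]])
    f_lo <- quantify_roi(co$rois[[lo[1, 1]]][[lo[1, 2]]])
    expect_gt(f_lo[["normal"]], f_hi[["normal"]])
  }
  # toggling ROIs must not change the drawn exams
  plain <- generate_cohort(generator_config(n_patients = 4, seed = 55))
  expect_identical(plain$field_05, co$field_05)
})
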