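test_that("pattern scores follow the N/B1/B2/C map and reject unknown labels", {
  expect_identical(score_field(c("N", "B1", "B2", "C")), c(0L, 1L, 2L, 3L))
  expect_identical(score_field("C"), 3L)
  expect_error(score_field("B3"), "B3")
  expect_error(score_field(c("N", "X")), "X")
})

make_exam <- function(labels) {
  out <- data.frame(patient_id = "P1", t(labels), stringsAsFactors = FALSE)
  names(out)[-1] <- sprintf("field_%02d", 1:12)
  out
}

test_that("regional sums follow the ventral/intermediate/dorsal field map", {
  all_n <- regional_scores(make_exam(rep("N", 12)))
  expect_equal(unlist(all_n[, c("lus_tot", "lus_v", "lus_i", "lus_d")]),
               c(lus_tot = 0L, lus_v = 0L, lus_i = 0L, lus_d = 0L))
  all_c <- regional_scores(make_exam(rep("C", 12)))
  expect_equal(unlist(all_c[, c("lus_tot", "lus_v", "lus_i", "lus_d")]),
               c(lus_tot = 36L, lus_v = 12L, lus_i = 12L, lus_d = 12L))
  labels <- rep("N", 12)
  labels[c(1, 2, 7, 8)] <- "B1"
  ventral_only <- regional_scores(make_exam(labels))
  expect_equal(unlist(ventral_only[, c("lus_tot", "lus_v", "lus_i", "lus_d")]),
               c(lus_tot = 4L, lus_v = 4L, lus_i = 0L, lus_d = 0L))
  # one field per region, mixed severities
  labels <- rep("N", 12)
  labels[1] <- "B2"; labels[9] <- "C"; labels[12] <- "B1"
  mixed <- regional_scores(make_exam(labels))
  expect_equal(unlist(mixed[, c("lus_v", "lus_i", "lus_d", "lus_tot")]),
               c(lus_v = 2L, lus_i = 3L, lus_d = 1L, lus_tot = 6L))
})

test_that("incomplete or inadmissible exams are rejected, never imputed", {
  exam <- make_exam(rep("N", 12))
  exam$field_07 <- NA_character_
  expect_error(regional_scores(exam), "missing")
  exam2 <- make_exam(rep("N", 12))
  exam2$field_03 <- "b1"
  expect_error(regional_scores(exam2), "b1")
  expect_error(regional_scores(make_exam(rep("N", 12))[, -4]), "field_03")
  expect_error(regional_scores(make_exam(rep("N", 12))[0, ]), "empty")
})

test_that("score conservation, bounds and severity monotonicity hold", {
  set.seed(101)
  exams <- random_exam_df(200)
  sc <- regional_scores(exams)
  expect_true(all(sc$lus_tot == sc$lus_v + sc$lus_i + sc$lus_d))
  expect_true(all(sc$lus_tot >= 0 & sc$lus_tot <= 36))
  expect_true(all(sc[, c("lus_v", "lus_i", "lus_d")] >= 0 &
                    sc[, c("lus_v", "lus_i", "lus_d")] <= 12))
  # upgrading one random field to a more severe pattern never lowers a score
  sev <- c("N", "B1", "B2", "C")
  for (i in 1:50) {
    j <- sample(200, 1)
    f <- sample(12, 1)
    cur <- match(exams[j, sprintf("field_%02d", f)], sev)
    if (cur == 4) next
    worse <- exams[j, , drop = FALSE]
    worse[[sprintf("field_%02d", f)]] <- sev[cur + 1]
    expect_true(all(
      unlist(regional_scores(worse)[, c("lus_tot", "lus_v", "lus_i", "lus_d")]) >=
        unlist(sc[j, c("lus_tot", "lus_v", "lus_i", "lus_d")])
    ))
  }
})

test_that("morphology classification thresholds the ventral score", {
  expect_equal(as.character(classify_morphology(6, 3)), "non-focal")
  expect_equal(as.character(classify_morphology(2, 3)), "focal")
  expect_equal(as.character(classify_morphology(0, 0)), "non-focal")
  expect_equal(as.character(classify_morphology(12, 13)), "focal")
  expect_error(classify_morphology(5, 14), "cutoff")
  expect_error(classify_morphology(5, -1), "cutoff")
  expect_error(classify_morphology(13, 3), "0..12")
  # monotone in cutoff: raising it never flips focal -> non-focal
  set.seed(7)
  v <- sample(0:12, 40, replace = TRUE)
  prev <- classify_morphology(v, 0)
  for (cf in 1:13) {
    cur <- classify_morphology(v, cf)
    expect_true(all(!(prev == "focal" & cur == "non-focal")))
    prev <- cur
  }
})

test_that("exam CSV reading validates and scores round-trip through disk", {
  set.seed(11)
  exams <- random_exam_df(10)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(exams, path, row.names = FALSE)
  back <- read_exams(path)
  expect_equal(regional_scores(back), regional_scores(exams))
  out <- withr::local_tempfile(fileext = ".csv")
  write_scores(regional_scores(exams), out)
  rt <- read.csv(out, stringsAsFactors = FALSE)
  expect_equal(rt$lus_tot, regional_scores(exams)$lus_tot)
})
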