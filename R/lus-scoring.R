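# Semi-quantitative lung ultrasound (LUS) aeration scoring.
#
# Each of 12 thoracic fields (1-6 right hemithorax, 7-12 left) is graded by
# its worst aeration pattern:
#   N  - normal aeration (A-lines, < 3 isolated B-lines)        -> 0
#   B1 - moderate loss (>= 3 well-spaced B-lines per space)     -> 1
#   B2 - severe loss (coalescent B-lines)                       -> 2
#   C  - lung consolidation (tissue pattern)                    -> 3
# The total score ranges 0-36; regional scores (ventral, intermediate,
# dorsal) each sum 4 fields and range 0-12.

#' Admissible LUS field patterns
#'
#' @return character vector `c("N", "B1", "B2", "C")`, ordered by increasing
#'   severity; the integer score of a pattern is its position minus one.
#' @export
lus_patterns <- function() c("N", "B1", "B2", "C")

#' Morphology class labels
#'
#' @return character vector `c("focal", "non-focal")`. `"non-focal"` is the
#'   positive class throughout the package's diagnostic machinery.
#' @export
morphology_levels <- function() c("focal", "non-focal")

#' Regional membership of the 12 LUS fields
#'
#' Fields 1-2 and 7-8 are ventral, 3-4 and 9-10 intermediate, 5-6 and 11-12
#' dorsal (fields 1-6 on the right hemithorax, 7-12 mirrored on the left;
#' within a region the anterior field carries the lower index). Regional sums
#' are invariant to the within-region ordering.
#'
#' @return named list of integer vectors with elements `ventral`,
#'   `intermediate`, `dorsal`.
#' @export
lus_regions <- function() {
  list(
    ventral      = c(1L, 2L, 7L, 8L),
    intermediate = c(3L, 4L, 9L, 10L),
    dorsal       = c(5L, 6L, 11L, 12L)
  )
}

# canonical exam column names field_01..field_12
field_cols <- function() sprintf("field_%02d", 1:12)

#' Score a LUS field pattern
#'
#' Maps aeration pattern labels to the semi-quantitative score
#' N = 0, B1 = 1, B2 = 2, C = 3.
#'
#' @param pattern character vector of pattern labels (see [lus_patterns()]).
#' @return integer vector of scores in 0..3.
#' @export
#' @examples
#' score_field(c("N", "B1", "B2", "C"))
score_field <- function(pattern) {
  idx <- match(pattern, lus_patterns())
  if (anyNA(idx)) {
    bad <- unique(pattern[is.na(idx)])
    fail(
      "unknown LUS pattern label(s): %s (admissible: %s)",
      paste(sQuote(bad), collapse = ", "),
      paste(lus_patterns(), collapse = ", ")
    )
  }
  idx - 1L
}

# Validate an exam table: patient_id + field_01..field_12, complete, labels
# admissible. Missing fields are an error, never imputed.
validate_exams <- function(exams) {
  if (!is.data.frame(exams)) fail("exams must be a data.frame")
  need <- c("patient_id", field_cols())
  missing <- setdiff(need, names(exams))
  if (length(missing)) {
    fail("exam table lacks column(s): %s", paste(missing, collapse = ", "))
  }
  if (nrow(exams) == 0L) fail("exam table is empty")
  fm <- as.matrix(exams[, field_cols()])
  if (anyNA(fm) || any(fm == "")) {
    bad <- exams$patient_id[rowSums(is.na(fm) | fm == "") > 0][1]
    fail("patient %s has missing LUS fields (all 12 are required)", bad)
  }
  score_field(as.vector(fm)) # errors on inadmissible labels
  invisible(exams)
}

#' Total and regional LUS scores for a cohort of exams
#'
#' Sums field scores over all 12 fields (total, 0-36) and over the three
#' 4-field regions (0-12 each): ventral = fields 1, 2, 7, 8; intermediate =
#' 3, 4, 9, 10; dorsal = 5, 6, 11, 12.
#'
#' @param exams data.frame with columns `patient_id` and `field_01` ..
#'   `field_12` holding pattern labels in `{N, B1, B2, C}`. A `morphology`
#'   column, when present, is carried through.
#' @return data.frame with columns `patient_id`, `lus_tot`, `lus_v`, `lus_i`,
#'   `lus_d` (and `morphology` if supplied).
#' @export
#' @examples
#' exam <- as.data.frame(as.list(setNames(rep("B1", 12), sprintf("field_%02d", 1:12))))
#' exam$patient_id <- "P1"
#' regional_scores(exam)
regional_scores <- function(exams) {
  validate_exams(exams)
  sm <- matrix(
    score_field(as.vector(as.matrix(exams[, field_cols()]))),
    nrow = nrow(exams)
  )
  reg <- lus_regions()
  out <- data.frame(
    patient_id = exams$patient_id,
    lus_tot = as.integer(rowSums(sm)),
    lus_v = as.integer(rowSums(sm[, reg$ventral, drop = FALSE])),
    lus_i = as.integer(rowSums(sm[, reg$intermediate, drop = FALSE])),
    lus_d = as.integer(rowSums(sm[, reg$dorsal, drop = FALSE])),
    stringsAsFactors = FALSE
  )
  if ("morphology" %in% names(exams)) {
    out$morphology <- factor(as.character(exams$morphology),
                             levels = morphology_levels())
  }
  out
}

#' Classify ARDS morphology from the ventral LUS score
#'
#' Predicts non-focal morphology when the ventral score reaches the cutoff
#' (test positive at `score >= cutoff`), focal otherwise. The study cutoff is
#' 3.
#'
#' @param ventral integer vector of ventral LUS scores (0-12).
#' @param cutoff single integer in 0..13; 13 encodes "greater than any
#'   attainable score" (everyone classified focal).
#' @return factor with levels `focal`, `non-focal`.
#' @export
#' @examples
#' classify_morphology(c(0, 2, 3, 6), cutoff = 3)
classify_morphology <- function(ventral, cutoff) {
  if (length(cutoff) != 1L || is.na(cutoff) || cutoff != as.integer(cutoff) ||
      cutoff < 0 || cutoff > 13) {
    fail("cutoff must be a single integer in 0..13")
  }
  if (anyNA(ventral) || any(ventral < 0 | ventral > 12)) {
    fail("ventral scores must lie in 0..12 with no missing values")
  }
  factor(
    ifelse(ventral >= cutoff, "non-focal", "focal"),
    levels = morphology_levels()
  )
}

#' Read a LUS exam table from CSV
#'
#' Expects one row per patient with columns `patient_id`,
#' `field_01`..`field_12` (values in `{N, B1, B2, C}`) and optionally
#' `morphology`.
#'
#' @param path CSV file path.
#' @return validated exam data.frame.
#' @export
read_exams <- function(path) {
  exams <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  validate_exams(exams)
  exams
}

#' Write a LUS score table to CSV
#'
#' @param scores data.frame as returned by [regional_scores()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
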