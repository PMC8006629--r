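# Quantitative CT aeration compartments.
#
# Each pixel of a lung region of interest is binned by its attenuation in
# Hounsfield units: hyperinflated [-1000, -900), normally aerated
# [-900, -500), poorly aerated [-500, -100), non-aerated [-100, 100].
# Bins are half-open on the right except the last, which is closed; the
# shared printed edges (-900, -500, -100) therefore belong to the
# more-aerated side deterministically. Pixels outside [-1000, 100] (bone,
# contrast, artifact) are tracked as `excluded` so that fractions always
# conserve to 1.

#' HU aeration compartment definitions
#'
#' @return data.frame with columns `compartment`, `lower`, `upper` describing
#'   the four aeration bins; each bin is `[lower, upper)` except the last,
#'   which is `[lower, upper]`.
#' @export
hu_compartments <- function() {
  data.frame(
    compartment = c("hyperinflated", "normal", "poor", "non_aerated"),
    lower = c(-1000, -900, -500, -100),
    upper = c(-900, -500, -100, 100),
    stringsAsFactors = FALSE
  )
}

hu_compartment_levels <- function() {
  c("hyperinflated", "normal", "poor", "non_aerated", "excluded")
}

#' Classify Hounsfield-unit values into aeration compartments
#'
#' @param hu numeric vector of HU values; must be finite.
#' @return factor with levels `hyperinflated`, `normal`, `poor`,
#'   `non_aerated`, `excluded`.
#' @export
#' @examples
#' classify_hu(c(-950, -700, -300, 0, 250))
classify_hu <- function(hu) {
  if (!is.numeric(hu)) fail("hu must be numeric")
  if (length(hu) && any(!is.finite(hu))) {
    fail("non-finite HU value(s) at position(s) %s",
         paste(utils::head(which(!is.finite(hu)), 5), collapse = ", "))
  }
  edges <- c(-1000, -900, -500, -100, 100)
  idx <- findInterval(hu, edges, rightmost.closed = TRUE)
  lab <- rep("excluded", length(hu))
  inside <- idx >= 1L & idx <= 4L
  lab[inside] <- hu_compartment_levels()[idx[inside]]
  factor(lab, levels = hu_compartment_levels())
}

#' Aeration compartment fractions of one CT region of interest
#'
#' @param hu_values non-empty numeric vector of HU values for the ROI.
#' @return named numeric vector of length 5 (`hyperinflated`, `normal`,
#'   `poor`, `non_aerated`, `excluded`) summing to 1, with attribute
#'   `n_pixels`.
#' @export
#' @examples
#' quantify_roi(c(-950, -700, -300, 0))
quantify_roi <- function(hu_values) {
  if (length(hu_values) == 0L) fail("ROI is empty: no HU values")
  counts <- table(classify_hu(hu_values))
  frac <- as.numeric(counts) / length(hu_values)
  names(frac) <- names(counts)
  structure(frac, n_pixels = length(hu_values))
}

#' Quantify a set of ROIs
#'
#' @param rois list of records, each with elements `patient_id`,
#'   `field_index` (1..12) and `hu` (numeric vector), as produced by
#'   [read_rois()].
#' @return data.frame with one row per ROI: `patient_id`, `field_index`,
#'   `f_hyper`, `f_normal`, `f_poor`, `f_non`, `f_excluded`, `n_pixels`.
#' @export
quantify_rois <- function(rois) {
  rows <- lapply(rois, function(r) {
    if (is.null(r$patient_id) || is.null(r$field_index) || is.null(r$hu)) {
      fail("each ROI record needs patient_id, field_index and hu")
    }
    if (!(r$field_index %in% 1:12)) {
      fail("field_index must be in 1..12 (got %s)", r$field_index)
    }
    f <- quantify_roi(as.numeric(unlist(r$hu)))
    data.frame(
      patient_id = r$patient_id, field_index = as.integer(r$field_index),
      f_hyper = f[["hyperinflated"]], f_normal = f[["normal"]],
      f_poor = f[["poor"]], f_non = f[["non_aerated"]],
      f_excluded = f[["excluded"]], n_pixels = attr(f, "n_pixels"),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Read CT ROI records from JSON
#'
#' The file holds an array of objects `{patient_id, field_index, hu}` where
#' `hu` is an array of Hounsfield-unit values.
#'
#' @param path JSON file path.
#' @return list of ROI records suitable for [quantify_rois()].
#' @export
read_rois <- function(path) {
  jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
}

#' Write an aeration fraction table to CSV
#'
#' @param aeration data.frame from [quantify_rois()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_aeration <- function(aeration, path) {
  utils::write.csv(aeration, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
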