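# Seeded synthetic cohorts: morphology labels, 12-field LUS exams and
# optional per-field CT HU arrays with the statistical structure the
# analysis assumes (ventro-dorsal aeration gradient; compartment mixtures
# shifting with the field score).

#' Default HU mixture parameters for synthetic CT ROIs
#'
#' Four-component mixture with one component per aeration compartment.
#' Locations sit centrally in each HU bin (-950, -700, -300, 0 HU; common
#' scale 40 HU). Component weights depend on the field score and the
#' morphology: the normally-aerated weight decreases and the non-aerated
#' weight increases strictly with the score; the poorly-aerated weight is
#' constant across scores in focal disease and increases in non-focal
#' disease.
#'
#' @return list with `locations`, `scales` (length-4 numeric, compartment
#'   order hyperinflated / normal / poor / non-aerated) and `weights` (per
#'   morphology, a 4x4 matrix with one row per field score 0..3).
#' @export
default_hu_mixture <- function() {
  w_focal <- rbind(
    c(0.05, 0.75, 0.15, 0.05),
    c(0.05, 0.55, 0.15, 0.25),
    c(0.05, 0.35, 0.15, 0.45),
    c(0.05, 0.15, 0.15, 0.65)
  )
  w_nonfocal <- rbind(
    c(0.05, 0.80, 0.10, 0.05),
    c(0.05, 0.55, 0.15, 0.25),
    c(0.05, 0.30, 0.20, 0.45),
    c(0.05, 0.10, 0.25, 0.60)
  )
  dimnames(w_focal) <- dimnames(w_nonfocal) <-
    list(paste0("score", 0:3), hu_compartment_levels()[1:4])
  list(
    locations = c(-950, -700, -300, 0),
    scales = rep(40, 4),
    weights = list("focal" = w_focal, "non-focal" = w_nonfocal)
  )
}

check_probs <- function(p, what) {
  if (any(p < -1e-9) || abs(sum(p) - 1) > 1e-6) {
    fail("%s must be non-negative and sum to 1", what)
  }
}

#' Construct a synthetic-cohort generator configuration
#'
#' @param n_patients cohort size.
#' @param prevalence_nonfocal probability a patient is non-focal (study
#'   value 36/47).
#' @param seed master seed; each patient draws from a deterministic
#'   substream so earlier patients are unchanged when the cohort grows.
#' @param region_pattern_probs per-(morphology, region) field-score
#'   distributions: nested list `[[morphology]][[region]]` with elements
#'   `weights` (regime mixture weights) and `probs` (matrix, one row per
#'   regime, columns P(score 0..3)). Defaults to the cached
#'   [calibrate_to_table2()] result.
#' @param hu_mixture HU mixture parameters, see [default_hu_mixture()].
#' @param roi_pixels pixels drawn per synthetic ROI.
#' @return object of class `lus_gen_config`.
#' @export
generator_config <- function(n_patients, prevalence_nonfocal = 36 / 47,
                             seed = 1,
                             region_pattern_probs =
                               default_calibration()$region_pattern_probs,
                             hu_mixture = default_hu_mixture(),
                             roi_pixels = 400) {
  if (n_patients < 1) fail("n_patients must be positive")
  if (prevalence_nonfocal < 0 || prevalence_nonfocal > 1) {
    fail("prevalence_nonfocal must lie in [0, 1]")
  }
  for (morph in morphology_levels()) {
    for (region in names(lus_regions())) {
      cell <- region_pattern_probs[[morph]][[region]]
      if (is.null(cell)) fail("missing pattern probs for %s %s", morph, region)
      check_probs(cell$weights, sprintf("regime weights (%s %s)", morph, region))
      if (!is.matrix(cell$probs) || ncol(cell$probs) != 4 ||
          nrow(cell$probs) != length(cell$weights)) {
        fail("probs for %s %s must be a (n regimes) x 4 matrix", morph, region)
      }
      for (r in seq_len(nrow(cell$probs))) {
        check_probs(cell$probs[r, ],
                    sprintf("pattern probs (%s %s regime %d)", morph, region, r))
      }
    }
  }
  for (morph in morphology_levels()) {
    w <- hu_mixture$weights[[morph]]
    if (!is.matrix(w) || !all(dim(w) == c(4, 4))) {
      fail("hu_mixture weights for %s must be a 4x4 matrix", morph)
    }
    for (r in 1:4) check_probs(w[r, ], sprintf("HU weights (%s score %d)", morph, r - 1))
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      prevalence_nonfocal = prevalence_nonfocal,
      seed = as.integer(seed),
      region_pattern_probs = region_pattern_probs,
      hu_mixture = hu_mixture,
      roi_pixels = as.integer(roi_pixels)
    ),
    class = "lus_gen_config"
  )
}

# inverse-CDF truncated normal on [lo, hi], vectorized over means
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Draw one synthetic CT ROI conditional on a field's LUS score
#'
#' HU values come from the configured four-component mixture (one component
#' per aeration compartment), truncated to [-1000, 100]. Uses the current
#' RNG state; seed externally (or via [generate_cohort()]) for
#' reproducibility.
#'
#' @param field_score LUS field score 0..3.
#' @param morphology `"focal"` or `"non-focal"`.
#' @param config `lus_gen_config` object.
#' @param n_pixels number of pixels to draw (default `config$roi_pixels`).
#' @return numeric vector of HU values in [-1000, 100].
#' @export
generate_roi <- function(field_score, morphology, config,
                         n_pixels = config$roi_pixels) {
  if (!(field_score %in% 0:3)) fail("field_score must be in 0..3")
  morphology <- match.arg(as.character(morphology), morphology_levels())
  mix <- config$hu_mixture
  w <- mix$weights[[morphology]][field_score + 1, ]
  comp <- sample.int(4, n_pixels, replace = TRUE, prob = w)
  rtrunc_norm(n_pixels, mix$locations[comp], mix$scales[comp], -1000, 100)
}

# field scores for one patient: one latent regime per region, 4 i.i.d.
# fields given the regime
draw_fields <- function(morphology, rpp) {
  scores <- integer(12)
  regions <- lus_regions()
  for (region in names(regions)) {
    cell <- rpp[[morphology]][[region]]
    regime <- if (length(cell$weights) == 1L) 1L else {
      sample.int(length(cell$weights), 1L, prob = cell$weights)
    }
    scores[regions[[region]]] <- sample.int(4, 4, replace = TRUE,
                                            prob = cell$probs[regime, ]) - 1L
  }
  scores
}

#' Generate a seeded synthetic cohort
#'
#' For each patient: morphology ~ Bernoulli(prevalence); per region a latent
#' severity regime, then 4 i.i.d. field patterns; optionally one synthetic
#' CT ROI per field, drawn conditional on that field's score. Patient `i`
#' always uses the same RNG substream, so the first `m` patients of an
#' `n > m` cohort equal the `m`-patient cohort.
#'
#' @param config `lus_gen_config` from [generator_config()].
#' @param include_rois also draw 12 HU arrays per patient (list column
#'   `rois`).
#' @return data.frame with `patient_id`, `morphology`, `field_01` ..
#'   `field_12` (and `rois` when requested).
#' @export
#' @examples
#' cfg <- generator_config(n_patients = 20, seed = 7)
#' cohort <- generate_cohort(cfg)
#' head(regional_scores(cohort))
generate_cohort <- function(config, include_rois = FALSE) {
  if (!inherits(config, "lus_gen_config")) {
    fail("config must come from generator_config()")
  }
  n <- config$n_patients
  labels <- lus_patterns()
  fields <- matrix(NA_character_, n, 12)
  morph <- character(n)
  rois <- if (include_rois) vector("list", n)
  for (i in seq_len(n)) {
    with_seed(substream_seed(config$seed, i), {
      morph[i] <- if (stats::runif(1) < config$prevalence_nonfocal) {
        "non-focal"
      } else {
        "focal"
      }
      sc <- draw_fields(morph[i], config$region_pattern_probs)
      fields[i, ] <- labels[sc + 1L]
      if (include_rois) {
        rois[[i]] <- lapply(sc, function(s) {
          generate_roi(s, morph[i], config)
        })
      }
    })
  }
  out <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    morphology = factor(morph, levels = morphology_levels()),
    fields, stringsAsFactors = FALSE
  )
  names(out)[3:14] <- field_cols()
  if (include_rois) out$rois <- rois
  out
}
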