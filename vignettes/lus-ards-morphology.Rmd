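---
title: "Methods: LUS-based discrimination of ARDS morphology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LUS-based discrimination of ARDS morphology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lusmorph)
```

## The clinical problem

ARDS presents in two CT phenotypes with different ventilatory management:
*focal* morphology (lobar/segmental aeration loss, typically dorsal and
caudal) and *non-focal* morphology (diffuse or patchy loss). Patients with
focal disease risk ventral hyperinflation under recruitment maneuvers and
high PEEP, while non-focal disease may benefit from them. CT is the
reference for phenotyping but requires transport; lung ultrasound (LUS) is
a bedside alternative. The package implements the computational chain of a
two-phase diagnostic accuracy study of a simple rule: *a ventral LUS score
of 3 or more excludes focal morphology*.

## The score

Each of 12 thoracic fields (six per hemithorax) is graded by its worst
aeration pattern: N = 0 (normal aeration), B1 = 1 (≥ 3 well-spaced B-lines),
B2 = 2 (coalescent B-lines), C = 3 (consolidation). The total score
LUS~TOT~ ∈ 0–36 sums all fields; regional scores sum 4 fields each
(∈ 0–12): ventral = fields 1, 2, 7, 8; intermediate = 3, 4, 9, 10;
dorsal = 5, 6, 11, 12. Field numbering within a region follows
anterior-before-posterior, right hemithorax (1–6) before left (7–12); only
file I/O depends on this ordering since regional sums are permutation
invariant. Missing fields are rejected, never imputed: the scoring protocol
grades all 12 fields in every patient, so an incomplete exam indicates a
data error upstream.

## Diagnostic machinery

**Positive class and cutoff semantics.** The positive class is *non-focal*
throughout; a test is positive when `score >= cutoff`. An empirical ROC
table lists one operating point per element of {0} ∪ {observed scores},
closed by a sentinel row one past the maximum ("> max": sensitivity 0,
specificity 100). AUC is the trapezoidal area of the
(1 − specificity, sensitivity) polyline, which for a discrete score equals
the tie-corrected Mann–Whitney statistic
P(S~non-focal~ > S~focal~) + ½ P(tie) — an identity the test suite verifies
by brute force over random cohorts.

**Cut-point selection** maximizes the Youden index J = sensitivity +
specificity − 1 over the table's operating points, breaking ties toward the
smallest cutoff. Because rows exist only at observed values, "the smallest
cutoff attaining the maximum" means the smallest *listed* cutoff.

**Confidence intervals** for sensitivity, specificity, PPV and NPV use the
exact Clopper–Pearson tail inversion (Beta quantiles; identical to
`binom.test()`). This choice reproduces the published lower bounds 70%
(15/16) and 54% (6/6 = 0.025^(1/6)); the source study does not name its CI
method, so exactness and conservative coverage decided the default. A
predictive value whose predicted class is empty is reported absent (`NA`),
not zero. Likelihood ratios with zero denominators print as blank cells.

**Rounding.** ROC tables print percentages to two decimals and likelihood
ratios to four; narrative metrics round to whole percent, half away from
zero (93.75% → 94%). `round_half_up()` is exported because R's `round()`
rounds half to even.

**Cohen's κ** uses marginal-product chance agreement and the
Fleiss–Cohen–Everitt large-sample variance for its CI. The study's printed
inter-observer κ = 0.87 needs the raw rater pairs, which are not published;
κ is therefore exercised only on constructed and simulated rater pairs.

## CT aeration compartments

ROI pixels are binned by attenuation: hyperinflated [−1000, −900), normally
aerated [−900, −500), poorly aerated [−500, −100), non-aerated [−100, 100].
The published bin edges overlap at −900, −500 and −100; the package fixes a
half-open convention (closed left, last bin closed both ends) so shared
edges belong to the more-aerated bin. The choice is declared, not inferred
from the source software, and has measure-zero effect on continuous data.
Pixels outside [−1000, 100] (bone, contrast, artifact) are counted as
`excluded` rather than dropped, so the five fractions always sum to 1 and
conservation is testable. ROI geometry and DICOM handling are out of scope:
inputs are flat HU arrays per field.

## Reconstructing the study cohorts

A complete empirical ROC table determines the per-class score multisets
exactly. Between consecutive listed cutoffs c~k~ < c~k+1~, the sensitivity
drop gives the number of positives holding value c~k~
(n~pos~ · (sens(c~k~) − sens(c~k+1~))/100) and the specificity rise the
number of negatives there; a value absent from the cutoff column was held
by no patient, else it would be an operating point. Implied counts must be
integral up to print rounding — `invert_roc_table()` rejects the offending
row otherwise. Applied to the published training table (20 non-focal,
5 focal) this yields non-focal ventral scores
{0, 3, 3, 4, 4, 6 ×7, 7, 8 ×4, 9 ×3} and focal {0, 0, 1, 1, 1}, and the
round trip reprints all nine published rows exactly, with trapezoidal
AUC 0.9600:

```{r training}
fix <- training_fixture()
empirical_roc(fix$score, fix$morphology)
```

The validation cohort is determined at the confusion-matrix level:
sensitivity 94% of 16 non-focal patients has the unique integral solution
15/16, specificity 100% of 6 focal patients forces 6/6. Within the strata,
`validation_fixture()` fixes constant score values matching the published
validation medians/IQRs (non-focal 6, IQR 4–7). One inconsistency is
inherent: the published focal IQR upper bound of 3 cannot hold when all six
focal patients must score below the cutoff 3, so the fixture's focal upper
quartile is 2, the closest attainable value. Patient-level totals and
intermediate/dorsal scores are *not* reconstructed — medians and IQRs alone
underdetermine them.

```{r validation}
vf <- validation_fixture()
diagnostic_summary(vf$score, vf$morphology, cutoff = 3)
```

## The synthetic-cohort generator

`generate_cohort()` emulates the study conditions so the whole pipeline is
testable without patient data: morphology ~ Bernoulli(prevalence; study
value 36/47 ≈ 0.77), then per (morphology, region) a categorical field-score
distribution, then optional per-field CT ROIs whose compartment mixture
shifts with the field score.

**Exchangeable fields, not i.i.d.** Fields within a region are i.i.d.
*given a per-(patient, region) latent severity regime* (at most two
regimes). Pure i.i.d. fields were the first design, but the sum of four
i.i.d. scores on 0–3 provably cannot reproduce the published focal dorsal
dispersion (median 10 with IQR 6–12: forcing the median and upper quartile
caps the lower quartile at 8). A two-regime mixture — roughly "consolidated
dorsal region" vs "partially spared" — is also the more realistic model,
since gravity-dependent consolidation affects a region as a whole. All
other cells remain single-regime. No within-region correlation beyond the
shared regime, and no between-region correlation beyond morphology, is
modeled; real exams are likely more correlated, so passing tests speak to
the score arithmetic and the estimator pipeline, not to anatomical realism.

**Calibration.** `calibrate_to_table2()` searches a simplex grid
(step 0.02) per cell with a lexicographic objective:

1. the population regional-sum median must equal the published median;
2. the CDF must clear 0.5 by ≥ 0.05 on both sides of the median, so
   finite-cohort sample medians are stable (0.05 ≈ 2–4 standard errors of
   an empirical CDF at the design scale of 2000 patients, 0.77 prevalence);
3. minimal L1 deviation of the quartiles (all cells reach ≤ 1 point, the
   published IQRs being small-sample statistics themselves);
4. maximal entropy of the regional-sum pmf, which prefers smooth
   full-support score distributions over degenerate gapped ones.

The ventral pair is selected jointly under two further constraints that are
themselves properties of the study the generator emulates: the population
Youden-optimal ventral cutoff must be 3, with J(3) exceeding every other
cutoff's J by ≥ 0.08 (≈ 3 standard errors of the empirical Youden index at
the design scale), and population ventral AUC ≥ 0.9. The calibrated
configuration achieves all six published regional medians exactly, IQR
deviations ≤ 1, ventral J-separation 0.08 and population ventral AUC 0.933;
at n = 2000 the simulated cohort reproduces all six medians, recovers
cutoff 3 and a ventral AUC ≈ 0.94, and shows the expected dorsal
non-discrimination (AUC < 0.5, since focal dorsal scores exceed non-focal
ones). Calibration is deterministic (exact convolutions, no simulation) and
cached per session.

**Synthetic CT ROIs.** HU values are drawn from a four-component truncated
normal mixture, one component per compartment, locations −950, −700, −300,
0 HU (bin centers) and common scale 40 HU, truncated to [−1000, 100]. Per
field score 0→3 the normally-aerated weight decreases strictly and the
non-aerated weight increases strictly; the poorly-aerated weight is flat in
focal disease and rises in non-focal disease, mirroring the published
qualitative trends (whose exact fractions are graphical only and are not
digitized). With scale 40 the inter-bin leakage is < 0.01, so empirical
compartment fractions converge to the configured weights (tested at
10^5 pixels, L∞ < 0.02). Default 400 pixels per ROI keeps cohorts cheap;
real ROIs have thousands of pixels, and the parameter is configuration, not
a constant.

**Reproducibility.** Each patient draws from a deterministic substream of
the master seed (two mixed Lehmer steps modulo 2^31 − 1), so growing a
cohort never reshuffles earlier patients and toggling ROI generation never
changes the drawn exams.

## Two-phase pipeline

`run_study()` computes ROC tables for every available regional score on the
training cohort, selects the Youden cutoff on the ventral score only, and
applies it frozen to the validation cohort — permuting validation labels
cannot change the chosen cutoff (tested). Quantiles throughout use linear
interpolation between order statistics (`quantile()` type 7); the source
study's software default is unknown, so the convention is fixed and
versioned in the report output. Reports are byte-deterministic.

## Numerical choices and degenerate inputs

* Integrality tolerance in table inversion: 0.1 of a patient — far above
  the ≤ 0.005% error of two-decimal printing, far below a real
  half-patient discrepancy.
* Single-class cohorts, empty ROIs, non-finite HU values, unknown pattern
  labels, and out-of-range cutoffs are rejected with the offending token or
  row named.
* Youden ties break toward the smallest cutoff; J is compared with a 1e−9
  slack so floating error cannot reorder exact ties.
* Problem sizes in the test suite: property loops use 200–300 random
  exams/cohorts, rank-statistic equivalence 1000 cohorts of n ≤ 50,
  coverage simulation 2000 draws per (p, n) condition, generator checks one
  2000-patient cohort — the package's chosen balance of statistical
  resolution against a fast default test run.

## Known limitations

* The generator's regional independence given morphology understates
  real-world spatial correlation; its calibration targets are the published
  medians/quartiles, not full score distributions.
* The published AUC standard error (0.0405) and AUC CI, the narrative
  training AUC 0.958 (the printed table supports 0.9600), the NPV CI
  "47–98%" for 6/7, and the inter-observer κ = 0.87 are not reproducible
  from published information and are deliberately out of scope.
* Pattern adjudication from raw ultrasound video and CT segmentation are
  upstream of this package; inputs are labels and HU arrays.
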