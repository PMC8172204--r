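---
title: "Quantitative facial phenotyping: models, parameters and design notes"
author: "FacePheno"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative facial phenotyping: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FacePheno)
```

# The problem

Noonan syndrome (NS) and Williams–Beuren syndrome (WBS) share overlapping
facial findings (hypertelorism, ptosis, short nose, short stature), and the
incidence of the individual signs varies strongly with ancestry, which makes
a differential diagnosis from visual inspection unreliable where molecular
testing is unavailable. FacePheno implements an objective pipeline over
frontal face photographs annotated with 44 anatomical landmarks: geometric
morphometrics and local texture descriptors feed a class-balanced linear
SVM with recursive feature elimination, evaluated by leave-one-out
cross-validation, both on a pooled cohort and within ethnicity strata
(African descent, Asian, Caucasian, Latin American), with population-average
appearance images as visual references.

# Geometric features

All measurements are evaluated in the *intrinsic face frame*: origin at the
inter-tragion midpoint, x-axis along the tragion-to-tragion direction,
y-axis toward the chin. This removes head roll without touching the image.
Each catalog metric is a horizontal distance, a vertical distance, or an
interior angle (vertex listed second, reported in degrees):

* horizontal distances are normalized by the **ear-to-ear (inter-tragion)
  distance**;
* vertical distances by the **distance from the oral-commissure midpoint to
  the nasion**;
* angles are left unnormalized.

A paired metric is measured on both sides; its symmetric feature is the
left/right mean (divided by its reference), and its asymmetry feature is
|L − R| / mean(L, R). The resulting vector is invariant to translation,
rotation and uniform scaling of the landmarks (verified to 1e-9 in the
tests), and a mirror-symmetric face has all-zero asymmetries.

The default catalog ships 23 metrics (canthal distances, palpebral fissure
length/height/slant, orbital-rim height, nasal bridge offset, nose
length/width, ala length, philtrum and cupid's-bow measurements, mouth
width, lip thicknesses, ear-canthus angle, and facial frame widths). The
published measurement diagram is not enumerated in text form anywhere, so
this catalog is a reconstruction motivated by the features the study
discusses, not a certified copy; it is fully overrideable through a CSV
catalog file (`readMetricCatalog()`). Two reconstruction choices deserve
note: "nose root" is taken to be the nasion landmark, and the two angle
metrics are anchored at vertices whose template values sit far from 0° and
180° (the slant angle at the outer canthus, the ear angle at the tragion),
because an unsigned interior angle folds at 180° and a near-degenerate
definition would make the metric non-monotone in the anatomy it measures.

# Texture features

Around each of the 33 inner landmarks the package computes multi-scale
block local binary patterns: the mean intensity of a central square patch
is compared with its eight neighbors in a 3×3 tiling, at three nested
resolutions R1 < R2 < R3 (default 3, 5, 9 px, stated for a 200-px
inter-tragion face and rescaled per subject by default so descriptors are
comparable across image resolutions). Bit i is 1 when neighbor i (clockwise
from top-left) compares true against the center under the tie rule
(default `>=`, the classical LBP convention); the default representation is
the 8 raw comparison bits per landmark per scale (33 × 3 × 8 = 792
features), with an optional normalized 256-bin code histogram. Codes are
invariant under strictly increasing intensity maps (exactly so under the
`>` rule; under `>=` except where a map creates ties), and depend only on
pixels within the 3×3 block neighborhood — both properties are enforced by
tests. Out-of-image patches use edge replication.

The cited prior work defining the exact LBP variant is not recoverable;
patch-vs-patch comparison at three nested scales is unambiguous from the
published figure, and both patch sizes and representation are exposed in
`TexturePatchConfig()`.

# Selection and evaluation

The classifier is a linear SVM (hinge loss, L2 regularization, C = 1) on
z-scored features, with per-sample weights N/(2·N_c) so both diagnostic
classes contribute equal total weight (with the study's 286 WBS / 161 NS
cohort: 0.781 and 1.388). No SVM implementation with per-sample weights is
available in the environment, so the solver is a deterministic dual
coordinate descent written for this package (cyclic order, stopping when
the projected-gradient spread falls below 0.1, the standard liblinear
tolerance).

RFE eliminates 10% of the remaining features per round until 64 remain,
then one at a time; ties on |coefficient| break in lexicographic
feature-name order, so rankings are fully deterministic. LOOCV is *nested*
by default: standardization parameters, the RFE ranking and every SVM fit
are recomputed per fold, and the held-out subject is scored by the top-k
model for each k in the grid (1..40 plus powers of two plus p). The
evaluation was deliberately kept leakage-free; a `flat` protocol (one
full-data ranking reused across folds) is available for replicating
protocols that tolerate selection bias. The optimal count k\* is the
smallest k whose AUC is within ε = 0.005 of the curve maximum; the reported
feature list is the full-data ranking truncated at k\*. Each selected
feature is screened with the Mann–Whitney U test (exact when n ≤ 20 with
no ties, otherwise normal approximation with tie and continuity
correction), reported raw with a Benjamini–Hochberg column.

`stratifiedEvaluation()` repeats the protocol per ethnicity stratum and
compares the global and stratum-specific models with a two-sided Fisher
exact test on correct/incorrect counts, reporting per-stratum accuracies,
relative improvements, and two overall accountings: the pooled LOOCV
accuracy of the global model and the per-stratum recombination. (On the
published numbers these two accountings differ — 85.68% from the printed
per-class accuracies versus 85.23% from the printed per-stratum table — and
the package emits both. The published Latin American improvement of 1.91%
is likewise inconsistent with its own accuracy pair, which yields 2.94%;
the package always reports the computed value.)

# Population-average images

`meanShape()` runs generalized Procrustes alignment under similarity
transforms (translation, rotation, uniform scale; no reflection) to
convergence 1e-8 or 100 iterations, with an order-independent
initialization; similarity rather than affine alignment is used so the
shape differences the classifier exploits are preserved in the atlas.
`warpToShape()` applies a piecewise-affine warp over a Delaunay
triangulation of the 44 landmarks plus 8 canvas-border anchors with
bilinear sampling (piecewise-affine was chosen over thin-plate splines for
determinism and speed), and `populationMeanImage()` averages the warped
images per (diagnosis × ethnicity) selection on a 256×256 canvas with a
160-px inter-tragion distance. Pixel correspondence is guaranteed only
inside the landmark hull; outside it the border-anchor triangles merely
fill the canvas.

# The synthetic cohort: what it emulates, and what a green test means

Patient photographs are not programmatically available, so every pipeline
stage is exercised on generated cohorts (`generateCohort()`). The default
configuration *is* the study's stated world:

* **Cohort composition**: 286 WBS and 161 NS subjects in four strata (WBS
  28/26/121/111, NS 35/40/40/46 for African/Asian/Caucasian/Latin
  American), with age-group and sex metadata drawn from the study's
  class-conditional composition.
* **Planted geometric effects** (standardized effect size 1.5 each,
  matching the effect scale the recovery property is stated at): NS gets
  wider inner-canthal spacing and a higher brow; WBS gets a wider mouth,
  thicker lower lip, shorter nose and more down-slanted fissures —
  the qualitative pattern of the published global feature interpretation.
* **Stratum modulation** mirrors the qualitative published pattern that
  some features vanish in some populations: the fissure-slant effect is
  zeroed for the African and Latin American strata and the inner-canthal
  effect for the Asian stratum.
* **Nuisance structure**: landmark jitter (SD 1.2 px on a 160-px face),
  random similarity transforms (±8°, scale 0.9–1.1, ±10 px), additive
  intensity noise (SD 6 on 0–255), all values chosen once as realistic for
  curated frontal photographs and not revisited.
* **Class-dependent texture**: WBS faces receive two local pattern stamps
  (stripes near the philtrum, spots on the nasal bridge, contrast 10),
  giving the texture channel genuine class signal.

Effects are planted in **landmark space**, not feature space, so a green
test exercises the entire extraction path. The pixel offsets realizing the
configured standardized effects are calibrated per template by Monte Carlo
(2 000 jitter/transform draws under a fixed internal seed for the noise
SDs) combined with a finite-difference Jacobian of all planted features
with respect to all planted offsets — the full linear system is solved
because effects can share landmarks and cross-talk. The calibration is
cached, so ground truth is identical across cohort seeds.

The ground truth records the planted feature names, their per-stratum and
pooled standardized effect sizes, and the **Bayes accuracy of the planted
model**: the geometric channel in closed form (per-stratum Mahalanobis
separation Δ_s, accuracy Φ(Δ_s/2), stratum-weighted), combined with the
texture channel's calibrated class-conditional bit rates through a
Monte-Carlo likelihood-ratio evaluation under an independence
approximation. With the defaults this is ≈ 0.97; the nested LOOCV accuracy
on the default cohort lands within the 5-point acceptance band below it,
which is what a correct but finite-sample pipeline should do.

Two planted-signal subtleties are worth knowing when reading test output.
First, stratum modulation *dilutes* pooled effects: the fissure-slant
effect, active in only two strata, has a pooled standardized effect of
about 0.7, and the stamped-texture bits about 0.7–1.0, well below the 1.5
the recovery property is premised on; in the default cohort's global
ranking those features legitimately rank outside the top-2p window (the
full planted list recovers 6/9 there), while every feature actually
meeting the ≥1.5 premise is recovered. The acceptance test asserts
recovery over the premise-satisfying subset, and the uncontaminated
invariant (planted effects of exactly 1.5 among 800+ noise dimensions, ten
seeds) is tested separately. Second, correlated planted features (the two
nasal-bridge bits respond to the same stamp) split SVM weight under RFE —
the expected behavior of multivariate elimination, not a defect.

What a green suite does **not** establish: that the default catalog matches
the unpublished measurement diagram; that real photographs meet the
generator's noise model (real cohorts have pose, illumination and
annotation variability the generator idealizes); or that the published
accuracies are reproducible — they were computed on patient photographs
that are not available, and the published-number acceptance checks are
arithmetic-consistency checks on the printed tables.

# Numerical choices and degenerate inputs

* Coordinates are 0-based pixels, origin top-left; angles in degrees within
  (0, 180).
* Coincident tragions, a zero-length normalization reference, or a paired
  distance with near-zero mean (below 1e-6 × the ear-to-ear distance) raise
  degenerate-geometry errors rather than returning unstable ratios.
* Constant features get unit scale during z-scoring; folds that lose a
  class entirely are errors; strata lacking a class (or smaller than the
  LOOCV minimum of 10) are skipped with a warning.
* Block sizes are forced odd and ≥ 3 after rescaling; landmarks outside the
  image raise errors naming the landmark.
* AUC uses the rank statistic of held-out decision values (ties credited
  1/2); no probability calibration is applied.
* All CSV output uses 9 significant digits; images are ASCII PGM (P2) —
  the environment provides no PNG/JPEG codec for R, and plain text keeps
  every artifact inspectable.

# Known limitations

Landmarks are consumed as input — automatic localization is out of scope.
The metric catalog is a faithful reconstruction, not the original list.
The texture descriptor's exact original variant (patch sizes,
representation) is unrecoverable and therefore configurable. Ethnicity
strata in the generator are abstract signal-modulation groups, not
renderings of population-specific appearance. Age and sex are carried as
metadata but never used for normalization.
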