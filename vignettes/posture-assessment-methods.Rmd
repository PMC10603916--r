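---
title: "Methods: marker-based photogrammetric posture assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker-based photogrammetric posture assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posturekit)
```

`posturekit` measures static posture from four-view photographs of a
subject wearing colored spherical markers, with a scale rectangle and a
plumb line in frame. This vignette is the package's account of its
methods: the model behind each stage, the parameters that matter and their
defaults, the conventions we fixed where the problem left them open, what
the synthetic data emulate, and the known limitations.

## Coordinate conventions

Everything downstream depends on three frames, fixed once:

* **Image frame**: origin at the top-left, x right, y down, pixel centers
  at integer coordinates.
* **World frame**: obtained by rotating image coordinates about the
  calibration origin so the plumb direction becomes vertical, flipping y
  (world y grows upward) and scaling to cm. A single global scale per
  image; no perspective or parallax model (see Limitations).
* **Subject frame**: world frame with +x toward the subject's *anatomical
  right*. Anterior photographs mirror the subject (image-left is
  subject-right), posterior photographs do not; the two lateral views
  carry only one side's markers, so their handedness does not influence
  any feature. Signed alignment angles are always computed in the subject
  frame, so "positive = right side higher" means the same thing in every
  view.

## Marker detection

A pixel belongs to a color of interest when its HSV coordinates fall in
the color's ranges. Hue is kept on the half-degree scale (0–180), the
common convention for 8-bit hue channels; red therefore carries two hue
intervals to absorb the wraparound. Defaults: green markers H ∈ [40, 80],
blue rectangle H ∈ [100, 130], red string H ∈ [0, 10] ∪ [170, 180], all
with saturation and value at least 0.3 — low-saturation backgrounds
(white, gray) fall out of every mask regardless of hue. These ranges are
package defaults, configurable under `colors:` in the YAML config; the
acquisition protocol itself fixes only the object colors.

Masks are labeled with 8-connected components so the anti-aliased rim of a
disk cannot split it. Each component is measured with four descriptors:

* **area** — pixel count;
* **circularity** — `4π·area / perimeter²`, 1 for a circle. The perimeter
  of a rasterized shape is delicate: the staircase polygon through the
  boundary pixel centers overestimates smooth outlines by ≈ 5%, which
  would push a circle's circularity down to ≈ 0.9. We therefore trace the
  outer contour (Moore neighborhood) and smooth it with a circular moving
  average (window 5) before measuring its length; a digitized circle then
  scores ≈ 1 and a square ≈ π/4 + 0.03, close to the ideal π/4. Values
  marginally above 1 (a digitized circle can exceed it) are clamped;
* **convexity** — component area over the area of its convex hull,
  counted in lattice pixels via Pick's theorem so that a convex component
  scores exactly 1;
* **inertia ratio** — `√(λ_min / λ_max)` of the second-central-moment
  eigenvalues of the pixel set: 1 for a circle, ≈ b/a for an a×b
  rectangle, 0 for a one-pixel-wide line.

Components pass the marker filter when all four descriptors lie within
bounds. Defaults — area [80, 8000] px², circularity ≥ 0.6, convexity
≥ 0.85, inertia ratio ≥ 0.4 — accept a 20 mm spherical marker over the
scales the default scene geometry produces (≈ 0.16 cm · px⁻¹, disk
diameter ≈ 12 px) and reject both reference objects. The continuous-domain
analogue `polygon_shape_descriptors()` computes the same quantities
exactly on polygons (Green's-theorem area and moments) and is the surface
the property tests verify against independent brute-force geometry.

## Calibration

The scale rectangle is the largest low-circularity component of its color;
its pixel length is the span of the pixel centers along the principal
axis. With anti-aliased edges the thresholded set reaches the physical
edge of the object, so no half-pixel inflation is applied; the residual
bias is a few tenths of a percent, well inside the 1% accuracy the
round-trip tests require. Two candidates of comparable area are an
ambiguity error rather than a guess, and an absent rectangle is a
`scale reference not found` error.

The plumb line is the most elongated component of the string color
(inertia ratio ≤ 0.1). When the background shares the string's color the
string merges into one compact blob, no component qualifies, and detection
fails with `plumb line not found` — the one background/object color
combination the acquisition protocol cannot tolerate, surfaced as an
explicit error with a remediation hint rather than a wrong calibration.

The calibration rotates coordinates so the plumb direction is vertical
(rotation constrained to (−45°, 45°]), which makes alignment angles
measurements *against gravity*: under a camera roll, naive image-horizontal
angles shift by exactly the roll while calibrated angles are invariant.
Whether the original clinical workflow rotated coordinates or used the
plumb only for operator guidance is not documented; we rotate, because it
makes the measurement model self-consistent and testable.

## Landmark labeling

Detected blobs carry no identity. We label them by exact minimum-cost
one-to-one assignment (Hungarian algorithm, solved exactly — problem size
≤ 29) between blob centroids and template site positions, after
normalizing both point sets: translate to the coordinate-wise median and
scale by the 70th-percentile radius. This normalization is exactly
invariant to uniform scale and offset, stable when many sites cluster near
the body center, and barely perturbed by one occluded marker or a few
spurious blobs — the failure modes that break bounding-box normalization.
Individual pairs with normalized squared distance above 0.1 are treated as
far-off: blobs that are far from *every* site are discarded as spurious
and the assignment re-solved, while ambiguous far pairs are left
unmatched (site flagged `missing`) rather than guessed. A configuration
whose *median* pair cost exceeds 0.04 is rejected outright as implausible.
Occluded markers can be supplied manually via `apply_overrides()`, with
provenance recorded as `manual` — mirroring clinical practice, where
markers hidden by body parts are drawn in by the operator.

## The 38 features

`feature_definitions()` enumerates the full parameter table: 13 anterior,
15 posterior and 5 features per lateral view; 15 names occur as left/right
pairs (38 values from 23 parameter families). Each feature is exactly one
of four primitives — alignment angle, line-pair angle, vertex angle,
distance — applied to named anatomical points. Conventions we fixed:

* Line-pair angles are reported acute, in [0°, 90°], so left and right
  versions of the same bilateral feature are directly comparable;
  `obtuse_line_angles = TRUE` switches to the [0°, 180°] medial angle.
* Vertex angles report the raw angle at the middle point (a collinear
  spine scores 180°), not its supplement.
* Alignment angles are signed, positive when the subject's anatomical
  right end is higher, anchored through the view mirroring described
  above.
* The posterior knee parameter is read as the vertex angle at the
  popliteal fossa between the trochanter and the posterior intermalleolar
  point; the published description groups its three points ambiguously,
  and this is the reading consistent with its sibling parameters.
* Distances use the per-view calibration; scales are never averaged
  across photographs, since each photo has its own rectangle.

Features whose landmarks are missing are emitted as `NA`, never imputed.

## Synthetic scenes and populations

Study photographs are rarely shareable, so the package generates its own
ground-truthed scenes. A posture template stores normalized body-frame
landmark positions per view (isotropic: one unit is one subject height),
with bilaterally symmetric neutral geometry. Deformations are applied as
minimal affine displacements of exactly the landmarks each deviation
moves: `pelvic_obliquity_deg` rotates the ASIS and PSIS pairs about the
pelvic midpoint, `shoulder_drop_deg` rotates the acromion pair,
`kyphosis_gain` / `lordosis_gain` scale the sagittal offset of the spinal
apices from their chords, and `scoliosis_offset` displaces the spinal
apices laterally in the posterior view.

`render_view()` rasterizes anti-aliased disks (20 mm default diameter), a
20 × 4 cm rectangle and a 3 px-wide plumb string at an 800 × 1200 px
default geometry in which a 166.4 cm subject spans 85% of the image
height (≈ 0.16 cm · px⁻¹). Camera roll rotates the whole scene about the
image center, so the plumb tilts *with* the subject, exactly as a rolled
camera would see it. Gaussian sensor noise is added on the 8-bit intensity
scale. Ground truth records the continuous disk centers — not rasterized
centroids — so round-trip tests measure true sub-pixel accuracy; the
detection tests require ≤ 0.5 px and observe ≈ 0.2 px.

`make_feature_population()` draws per-subject deformations from
class-conditional distributions and computes features through the same
geometry, plus independent Gaussian measurement noise (default SD 0.5 in
native units) and a stature distribution (166.4 ± 9.3 cm, matching the
reference screening cohort's demographics). Default class counts are
16 / 25 / 16 (`none` / `mild` / `moderate_severe`), the reference cohort's
split. No quantitative clinical definition of "mild" versus
"moderate-to-severe" postural deviation exists in the source material;
the defaults — mild ≈ 3° obliquity and shoulder drop, moderate-to-severe
≈ 8° plus substantial kyphosis gain — are conventions chosen to express
*ordered severity* at magnitudes a physiotherapist would plausibly grade
that way, and they are deliberately well separated. Consequently the
synthetic classes are nearly noiseless caricatures: classifiers reach
100% on them where the real study sat near 50–80%. Passing classification
tests therefore demonstrates that the evaluation machinery (stratified
schemes, pooled confusion matrices, cascade chaining) is correct — not
that the features separate real clinical classes. The generator also does
not emulate photographic confusers (skin tones near the marker hue,
clothing folds, partial marker coloring) that caused false or missed
detections in practice.

## Statistical validation protocol

Two feature tables over the same subjects are compared feature by
feature, at significance levels 0.05 and 0.1 throughout:

1. **Normality gate.** Shapiro–Wilk on each source's sample (the
   published protocol gates on the sources, not the differences; a config
   switch gates on differences instead). Both normal at the level → paired
   t test on the differences; otherwise Wilcoxon signed-rank (zeros
   discarded; exact null for n ≤ 25, normal approximation with continuity
   correction above).
2. **Outlier re-analysis**, triggered only when the difference is
   significant at *both* levels: pairs whose difference lies outside the
   Tukey fences (1.5 × IQR beyond the quartiles, type-7 quantiles) are
   removed from both sources and the comparison repeated. The fence
   multiplier is configurable; the protocol source names no rule, and
   Tukey's is the conventional default.
3. **Equivalence.** Paired TOST — two one-sided t tests with n − 1
   degrees of freedom of the mean difference against the bounds, p = the
   larger one-sided p — over the widening ladder ±0.01 → ±0.05 → ±0.06,
   stopping at the first rung that declares equivalence at the stricter
   level. Bounds are in the feature's native units (degrees or cm); the
   source does not state its units, and native units are the reading under
   which a ladder shared by all features is meaningful. TOST p is monotone
   non-increasing in bound width, which the tests assert on every dataset
   tried.

Degenerate inputs are handled explicitly rather than numerically:
identical tables take an exact-agreement branch; a constant nonzero
difference is reported as a certain shift (p = 0); zero-variance
differences under TOST are equivalent iff the constant lies strictly
inside the bounds. Note the published post-outlier table labels p-values
of 0.01–0.02 as "not significant", contradicting the conventional p < α
rule its own text states; this package follows the conventional rule.

Monte-Carlo calibration (n = 57, ≥ 1000 replicates, run by both the test
suite and `scripts/acceptance.R`) checks that Shapiro–Wilk and the gated
comparison hold their nominal 5% type-I rate and that TOST at a true
boundary-sized effect declares equivalence at ≈ the nominal rate.

## Classification

Three filter rankings are implemented as the field's screening toolboxes
define them: information gain and the chi-squared statistic on
equal-frequency 4-bin discretizations, and ReliefF (k = 5 nearest
hits/misses over all instances, min–max scaled features, miss classes
weighted by priors). Ties break by feature name so rankings are
deterministic; constant features score zero (information gain, ReliefF)
or are excluded with a warning (chi-squared).

kNN uses Euclidean distance on z-scored features (statistics fit on the
training portion only) and breaks vote ties by smaller mean neighbor
distance, then class order — fully deterministic, which the reference
implementations' random tie-breaking is not; `class::knn` serves as an
independent cross-check in the tests on tie-free data. LDA is delegated
to `MASS::lda`. Both evaluation schemes are stratified by default — with
16-subject classes an unstratified 10-fold split can easily starve a fold
— and cv10 pools out-of-fold predictions into one confusion matrix before
computing accuracy and one-vs-rest F1. `knn_k_candidates()` scans
k = 1…21 (covering every k the reference configurations used) and keeps
the five lowest-error values, ties toward smaller k.

The two-level cascade trains level 1 on evidence-vs-none over all
subjects and level 2 on the truly-with-evidence subset only (41 subjects
under the 16/25/16 split). The combined three-class report chains each
subject's level-1 out-of-sample prediction through level 2, using the
level-2 out-of-sample prediction when the subject has one and otherwise a
level-2 model fit on the full evidence subset (the only subjects needing
the fallback are no-evidence subjects misrouted by level 1, which level 2
never saw by construction). Published feature subsets for the three
problems ship as presets (`feature_set_preset()`); automatic selection
inside training partitions avoids test-label leakage, and the
whole-dataset selection mode that reproduces the original workflow is
available but flagged as leakage-prone.

## Problem sizes used in testing

The test suite and acceptance script choose deliberately moderate problem
sizes: 200 rendered scenes (plus 20 with one occluded marker) for the
detection round-trip, 15 tilted scenes for calibration recovery, 200
random convex polygons and 300 random point configurations for the
geometry oracles, 1000–1200 Monte-Carlo replicates at n = 57 for the
statistical calibration, and 300–500 replicates for the chance-level
classification check. These sizes give the assertions comfortable margins
(e.g. binomial SE ≈ 0.7% on a 5% rate at 1000 replicates) while keeping a
full run in single-digit minutes on one CPU.

## Known limitations

* **No perspective or parallax correction.** The rectangle and string do
  not lie exactly in the subject's plane; a single global scale ignores
  that, and camera-height/distance variation propagates into angle
  parameters. Vanishing-point or sensor-geometry corrections are out of
  scope here.
* **Template-based labeling** assumes the photographed posture is a
  moderate deformation of the standing template; extreme poses would need
  operator overrides.
* **Synthetic realism**: see above — geometric ground truth is faithful,
  photographic nuisance factors are not modeled, and synthetic class
  separations are conventions, not clinical claims.
* The classifiers are parameter evaluators for screening support, not
  diagnostic instruments.
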