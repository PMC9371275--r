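---
title: "Methods: landmark morphometry, floating feature selection, and progression modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: landmark morphometry, floating feature selection, and progression modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curveprog)
```

# The problem

Adolescent idiopathic scoliosis (AIS) is a three-dimensional spinal
deformity whose severity is graded by the Cobb angle — the angle between
the two most tilted (end) vertebrae of a curve on a coronal radiograph.
Curves progress at very different rates, and the clinical question is
which patients presenting with a moderate curve will progress to a
severe one. `curveprog` implements a complete, testable pipeline for
this question: it measures curve geometry from vertebral corner
landmarks, encodes the standard clinical features, selects a predictive
feature subset by sequential backward floating selection (SBFS) under
cross-validated mean absolute error (MAE), and fits a tuned
random-forest regressor of the final major Cobb angle. Because patient
radiographs cannot be redistributed, the package ships first-class
synthetic generators — for landmark-level spines and for tabular
cohorts — with known ground truth, and the whole validation suite runs
against them.

# Landmark geometry

## From four corners to an orientation

Each vertebra enters as four corner landmarks (superior-left,
superior-right, inferior-right, inferior-left) in image coordinates.
Internally y increases caudally-to-cranially; `normalize_coordinates()`
flips raw y-down pixels and rejects corner labellings inconsistent with
the convention.

A four-point "ellipse fit" is underdetermined (an ellipse has five
parameters), so the package defines the vertebra's equivalent ellipse
through the polygon's second central area moments: the centroid is the
area centroid of the quadrilateral and the orientation is the angle of
the major principal axis of the moment tensor, in degrees from the
horizontal, in (−90°, 90°]. This construction is unique, rotation-
equivariant, and exact for rectangles (the property the test suite
asserts to 1e−6 degrees). A perfectly square vertebra has an isotropic
moment tensor with no defined principal axis; the orientation then falls
back to the superior endplate direction and the row is flagged
`isotropic`. The wedge angle is the angle between the superior and
inferior endplate lines, folded to [0°, 90°].

## Centreline, apices, ends, Cobb

A natural cubic interpolating spline of lateral centroid position
against cranio-caudal position is fitted through the (at least four)
centroids. Lateral position is parameterised over the cranio-caudal
coordinate, not arc length: it is the simplest reading of "maxima and
minima" of a centreline, and for anatomically plausible tilts (< 90°)
the centroid height is strictly monotone so the function is well
defined.

Interior extrema of the spline nominate apices. An extremum qualifies
only if its lateral deviation from the chord joining the endmost
centroids exceeds `min_deviation` (default 2 px) — a guard against
numerical ripple on near-straight spines; a straight spine therefore
yields zero curves rather than an error. The apex is the vertebra whose
centroid is nearest the extremum (ties to the more cranial one).

For each apex the end vertebrae are the most tilted vertebrae —
maximum *absolute* orientation — above and below it. Two deliberate
choices here:

* **Tie rule.** Exact ties go to the vertebra farther from the apex
  (maximising the captured extent, and deterministic). The one
  exception is a degenerate segment in which *no* candidate is tilted
  at all; then there is no "most tilted" vertebra and the end defaults
  to the vertebra adjacent to the apex, so an all-zero spine measures
  Cobb 0 over the minimal three levels rather than claiming the whole
  spine.
* **Bounded search.** On multi-curve spines the search for one curve's
  ends stops at the neighbouring apex. Without this bound a lumbar
  curve on an S-shaped spine would claim the top thoracic vertebra
  (equally tilted, opposite sign) as its upper end and its Cobb angle
  would collapse; with it, adjacent curves share the inflection
  vertebra, as in clinical practice.

The Cobb angle is the absolute difference of the signed end-vertebra
orientations, which equals the angle between their major axes and
reduces to the classical definition for opposite tilts. The curve with
the greatest Cobb angle is flagged major; sidedness comes from the sign
of the apex deviation and flips under mirror reflection.

# Clinical features

* **Flexibility** = 100 × (standing − bending)/standing Cobb, clipped
  to [0, 100] with a warning when bending exceeds standing. When both
  bending views exist the bend minimising the measured Cobb (the
  corrective bend) is the intended input.
* **Structural rule**: a minor curve is structural when its Cobb is at
  least 80% of the major's. The boundary is read as inclusive.
* **Modified Lenke types 1–6** are classified from the regions of the
  structural curves. The apex bands (proximal thoracic T2–T5, main
  thoracic T6–T11, thoracolumbar/lumbar T12–L4) are not part of the
  published definition, so they follow the standard Lenke convention
  and are configurable. Patterns outside the six rules (e.g. a lone
  proximal-thoracic structural curve) raise an explicit
  "unclassifiable" error — never a silent default. Equal thoracic and
  lumbar Cobb angles classify as type 3 (the "thoracic ≥ lumbar" side
  of the double-major split).
* **Risser "+"** maturity is an eight-grade ordinal scale that adds
  triradiate-cartilage status below the classical Risser grades; the
  encoder maps the grades 0−, 0+, 1, 2, 3, 3/4, 4, 5 to 0–7 and
  rejects anything else.
* **Feature vector.** The 15 model inputs keep a fixed index order
  (`feature_table()`); every subset anywhere in the package is reported
  in these indices. Gender (F→0, M→1), brace status (no-brace→0,
  brace→1) and Lenke type (its integer label) are integer-coded —
  adequate for trees and kept so the index bookkeeping survives
  selection; the SVM and neural-network adapters one-hot nominal
  features and standardize continuous ones internally, leaving the
  shared matrix untouched. Records with missing fields are rejected
  outright (complete-case, no imputation).

# Feature selection

`sbfs_select()` is a native implementation of sequential backward
floating selection:

1. start from the full set and record it;
2. *exclusion*: remove the feature whose removal minimises the k-fold
   cross-validated MAE;
3. *floating inclusion*: while re-adding some excluded feature
   *strictly* beats the best subset recorded at the target size, add
   the best such feature;
4. repeat until the minimum size (default 1).

Scores are 5-fold cross-validated MAEs on one fold partition drawn
once per call, so all subset comparisons are paired; evaluations are
memoized (each subset scored at most once — removing memoization
changes cost, not results, which the suite verifies). The strict-
improvement acceptance in the floating step is the standard floating-
selection semantics and guarantees termination. Every accepted working
set is recorded as a trace (so a size can appear more than once, as in
published SBFS tables); the best subset is the trace with minimal mean
MAE, ties to the smaller then lexicographically smallest set.

Two reporting conventions: the per-size SD is the *population* SD over
fold scores, and the tabulated confidence bound is `ci_multiplier × SD`
with default 1.2816. Published SBFS tables of this kind show a
CI-to-SD ratio of ≈1.28 on every row — consistent with neither
1.96·SD nor a t-interval over five folds — so the multiplier is exposed
rather than hard-coded to a formula the tables do not follow.

The pipeline runs selection on the training split only, preventing
selection leakage into the held-out evaluation (full-cohort selection
can be emulated by calling `sbfs_select()` directly).

# Progression model

`split_cohort()` holds out a seeded 25% of patients. `grid_search()`
exhaustively scores hyperparameter combinations by seeded 5-fold CV
MAE; ties go to the first combination in grid order, and a failing
combination scores +Inf with a warning instead of aborting. The default
random-forest grid spans trees 100–500, candidate features per split
1–7, depth 10–50 and node sizes 2–11 / 1–2 — a deliberately coarse
cover of those tuning ranges (3·3·3·3·2 = 162 points) chosen so a full
tuned pipeline runs in well under a minute.

The forest itself is delegated to `ranger` (single-threaded, seeded,
so runs are byte-reproducible); the five grid names map onto
`num.trees`, `mtry`, `max.depth`, `min.node.size`, `min.bucket`.
Importances are impurity-based (they are non-negative and sum to one,
matching how forest importance tables are usually printed);
permutation importance is available via the factory. The SVM adapter
uses an RBF kernel with regularization constant 1 and maps a zero tube
width to 1e−3 (a zero-width tube is degenerate); its grid tunes epsilon
and gamma. The neural-network adapter is a single-hidden-layer
perceptron (16 rectified-equivalent units by default, linear output,
standardized inputs and target) whose natural tuning surface in this
implementation is size, weight decay and optimizer iterations — batch
size and SGD-optimizer choice have no analogue in a BFGS-trained
network, so the adapter exposes what it actually has. Both adapters are
stand-ins behind a uniform factory interface, and `compare_models()`
reports one training-CV/test row per family.

`predict_final_cobb()` annotates each point prediction with the
training-CV MAE as an error band and warns when any feature lies
outside the training range: a forest predicts constants beyond its
training support and cannot extrapolate.

# Synthetic data

## Spines

The single-bump centreline is `x(y) = A sin(πy/L)` with
`A = (L/π) tan(θ*/2)`, so the maximal tangent angles are exactly ±θ*/2
and the analytic Cobb angle is θ*. Vertebrae are rectangles (45×24 px
by default, spine length 850 px — radiograph-like proportions) placed
at equal arc-length intervals including both ends, rotated to the local
tangent; the end vertebrae therefore sit exactly at the maximal-tangent
points and the measured Cobb converges to θ* as the vertebra count
grows. Configurations whose vertebra height reaches the arc spacing are
rejected (overlapping vertebrae). An s-curve concatenates two opposed
bumps with independent Cobb angles; its curves share the junction
vertebra as an end. Landmark noise is isotropic Gaussian, seeded.
`generate_bending_set()` regenerates the same spine with
θ* × (1 − flexibility/100), emulating the corrective side-bend.

## Cohorts

`generate_cohort()` draws the eight continuous features from truncated
normals (inverse-CDF sampling — exact and seedable) matching the study
population's means, SDs and ranges (initial major Cobb
48.9 ± 13.9° on 10.9–99.5°, flexibility 57 ± 19.3%, ...), and the six
categorical features from the observed frequencies (169/193 female,
Lenke mix, apex support T6–L3, Risser "+" counts). Two published rows
are internally inconsistent and were resolved once: the apex wedge
angle's printed mean (56.7°) cannot sit in its printed 0–21° range, so
it is read as 5.7° (a plausible decimal-point slip, consistent with the
4.1° SD); flexibility is kept in percent with its fraction-scale range
rescaled to [5, 99]. Age at last visit is derived as age at first visit
plus time span, keeping records internally consistent.

The outcome is generated by a stated progression model:

final = initial + δ₀ + Σ βⱼ zⱼ + ε,  ε ~ N(0, σ²),

with standardized features zⱼ, δ₀ = 10.5° (the population's mean
progression), σ = 4° — putting the irreducible MAE σ·√(2/π) ≈ 3.19°
under the 5° clinical-acceptability bound with headroom for estimation
error — and effects in degrees per SD: initial Cobb +5, flexibility
−3.5, lumbar lordosis +2.0, thoracic kyphosis +1.7, age at last visit
+1.4, levels involved +1.0, Risser stage −0.7, all others 0. Because
the initial angle also enters through the identity term, its total
standardized effect (≈13.9 + 5) dominates, flexibility is second, and
the rest follow in the order above — the qualitative importance
structure reported for real cohorts. Final angles are floored at 25°
(a surgical-cohort floor). The generating coefficients travel with the
table (`cohort_truth()`).

An optional fixture, `inject_null_features()`, appends standard-normal
columns independent of the outcome — the specificity probe for
selection.

## What the generators do and do not emulate

Features are drawn independently (no Risser-age correlation, no
curve-type/apex coupling), the outcome is linear-Gaussian in scaled
features, and landmark noise is isotropic. Passing tests therefore
demonstrate that the machinery recovers known truth under controlled
conditions — correct geometry, honest cross-validation, selection
specificity, importance recovery — not that the trained model
generalises to clinical populations, whose joint feature structure and
nonlinearity the generators deliberately do not claim.

# Validation problem sizes

The test suite validates geometry on noiseless 17-vertebra spines over
true Cobb 10–90° (2° tolerance) and convergence at 9/17/33 vertebrae;
selection against exhaustive-search oracles at p ≤ 4 (n = 300,
linear-model factory for speed) and null-feature exclusion with the
random-forest factory (50 trees) on 20 cohorts of n = 200 with 3
injected nulls; the noise floor at n ∈ {200, 1000}; importance
recovery on 20 cohorts of n = 1000 (300-tree forests, Spearman ≥ 0.8
against the generated effect order); and the full pipeline bound —
10-seed mean held-out MAE ≤ 5° at the study size n = 193. The
linear-model factory appears in the selection *oracles* because its
exhaustive reference must be computed many times; the specificity and
pipeline checks use the forest the method actually wraps. (With a
linear selector the null-exclusion rate is intrinsically ~60%: the
overfit penalty of one null feature and the paired CV noise both scale
like σ/n, so the comparison is scale-free; the forest's split
competition penalises pure-noise features far more decisively.)

# Known limitations

* Landmarks are inputs; there is no image processing or landmark
  detection, and no sagittal-plane or axial-rotation geometry
  (kyphosis, lordosis and apical rotation enter as numeric features
  only).
* The Lenke classification implemented is the modified (coronal-only)
  variant; sagittal modifiers of the original system are out of scope.
* The equivalent-ellipse orientation is exact for parallelogram-like
  vertebrae but is a moment summary for strongly wedged ones — which is
  precisely what makes it robust, but it is not an endplate tangent.
* Cross-model comparability: the SVM/ANN adapters are reasonable
  defaults, not tuned architectures; conclusions about family rankings
  on real data should not be drawn from them.
* The synthetic cohort's independence and linearity assumptions are
  stated above; any acceptance figure computed on it measures pipeline
  correctness, not clinical accuracy.
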