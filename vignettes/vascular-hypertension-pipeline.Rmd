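---
title: "Cerebrovascular morphology and blood-pressure classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cerebrovascular morphology and blood-pressure classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`vascmap` implements a full analysis chain for asking whether cerebrovascular
morphology predicts a subject's blood-pressure class, and which pressure
summary — systolic, diastolic, or mean arterial pressure (MAP) — it predicts
best. This vignette is the package's own account of the models, the tunable
parameters, the numerical choices, and what the synthetic experiments do and
do not demonstrate.

## The scientific setting

Chronic hypertension remodels cerebral vessels: lumina narrow and vessels
become more tortuous, and clinical work suggests these changes begin before
pressure readings cross diagnostic thresholds. Given a bright-vessel
angiographic volume (flowing blood bright against tissue, as in
time-of-flight MRA), the analysis is:

1. clean the volume (bias, noise, non-brain voxels);
2. segment the vasculature;
3. summarise its morphology in a 17-value feature vector;
4. label the subject under a blood-pressure rule;
5. train classifiers to predict the label from the features.

Real angiographic cohorts with paired pressure measurements are rarely
shareable, so the package ships a phantom/cohort generator that reproduces
the statistical structure the analysis assumes. Every stage is tested
against that generator.

## The phantom generator

`vessel_tree_spec()` / `generate_vessel_tree()` build branching tubular
trees: a configurable number of root branches started near the volume
centre, bifurcating over a set number of levels, with child radii scaled by
a decay factor (so radii never increase from parent to child). Tortuosity is
injected as a two-axis sinusoidal displacement of each branch around its
chord — amplitude in voxels is the knob, wavelength is tied to the branch
radius (`max(12, 6r)`). Branches steer back toward the centre whenever they
would leave a safety ellipsoid one maximal radius inside the simulated head
boundary, so rasterization margins always hold. Root length is 0.28 of the
smallest volume edge, which keeps a straight root inside the safety region
without steering; the default volume is 128^3 voxels so that a full pipeline
run stays at desk scale (the cohort generator defaults to 64^3).

`rasterize_tree()` paints every voxel whose centre lies within the local
radius of the centerline (a capsule union, verified against the analytic
capsule volume to within lattice error), then draws vessel voxels from a
bright Gaussian (mean 200 by default) and tissue from a darker one
(mean 100), optionally multiplies by a smooth random second-order polynomial
bias field scaled to `[1 - a, 1 + a]`, and adds white Gaussian noise. With
`halo = TRUE` tissue fills an ellipsoid surrounded by near-zero air, which
gives brain-mask extraction something genuine to strip.

What the generator does *not* emulate: realistic circle-of-Willis anatomy,
MR acquisition physics (partial volume, coil profiles beyond a smooth bias,
Rician noise), flow artefacts, or pathology other than the radius/tortuosity
shifts. Tests passing on phantoms therefore demonstrate algorithmic
correctness and robustness to the modelled degradations — not clinical
performance on real angiograms.

## The cohort generator

`cohort_spec()` / `generate_cohort()` draw class-conditional systolic and
diastolic pressures from normal distributions. Each subject gets four noisy
readings (reading SD 3 mmHg — a typical within-visit repeatability figure;
the source demographics give no within-subject variance), which are averaged
into the resting value, exercising the same aggregation rule the labeling
uses.

The default class parameters pool the demographics of the three
rule-selected sub-cohorts the analysis mirrors (normotensive 119 ± 8 /
78.3 ± 5 mmHg; hypertensive 132 ± 9 / 85.9 ± 5.5 mmHg). Pooling matters: a
subject who is normal under the single-component rules (SBP < 120 and
DBP < 80) necessarily has MAP below 93.33 mmHg — the *optimal* category,
which the MAP rule excludes — so no single narrow class distribution can
give all three rules usable two-class subsets. The pooled spread mimics the
wider source population from which each rule selects its own subset.

Morphology couples to hypertension through an effect size in `[0, 1]`:
severity (either the binary class, or a ramp in the subject's MAP for
`coupling = "map"`) shrinks the root radius by up to 25% and raises
tortuosity by up to 120% at effect 1, directions that follow the clinical
literature on hypertensive remodeling; the magnitudes are free generator
parameters, not measured values. With `output = "features"` the 17-value
descriptor is emulated directly from the subject's radius law (skeleton
radii with 0.25-voxel discretization jitter; per-point mean curvature
`1/(2r)` inflated by tortuosity; near-zero Gaussian curvature whose spread
widens with tortuosity). With `output = "volumes"` each subject instead
carries a rasterized phantom for the image pipeline.

## Preprocessing

`correct_bias()` fits a first- or second-order polynomial to the
log-intensities. The fit floors intensities at a small positive value rather
than shifting the whole volume: an additive shift breaks the multiplicative
structure (`log(S·f + c)` is no longer linear in the field `f`) and leaves a
structured residual. The exponentiated field is normalised to mean 1 over
the fitted region (pass the brain mask when the volume contains air —
otherwise air dominates the normalisation), clamped to `[0.25, 4]` against
wild extrapolation, divided out, and the output is re-centred so the
region's mean intensity is preserved.

`ggmrf_smooth()` minimises `sum (x - y)^2 / 2 + lambda sum |x_i - x_j|^beta`
over 6-neighbour pairs by fixed-step gradient descent on standardized
intensities. `beta = 2` is exactly a linear smoother (the unit test checks
this against an independent implementation); the default `beta = 1.5`
penalises large jumps sub-quadratically and so flattens noise while keeping
step edges. Defaults (`lambda = 0.5`, 8 iterations) were chosen on a noisy
cylinder phantom to reduce tissue noise SD by well over 30% while retaining
over 70% of the noiseless edge gradient (measured: roughly 80% / 76%).

`strip_skull()` thresholds between the volume minimum and its 99.9th
percentile (fraction 0.4 by default — low enough to keep all tissue, high
enough that salt noise in air stays far below the site-percolation regime of
the 26-neighbourhood), keeps the largest 26-connected component, closes it
morphologically and fills interior holes. On phantoms this is brain-mask
extraction; it deliberately replaces the published Markov–Gibbs +
deformable-surface skull stripping, which is out of scope here.

## Segmentation

`fit_intensity_model()` is a two-component univariate Gaussian-mixture EM on
the masked voxel histogram — a documented simplification of the richer
linear-combination-of-discrete-Gaussians density models used in the
literature, which the source does not specify in equation form.
Numerical choices:

* initialization is robust to the rare-bright-class geometry: tissue from
  the median and MAD, vessels from the top half-percent tail;
* component SDs are floored at `1e-3` of the intensity range so noiseless
  two-valued volumes converge instead of collapsing;
* the log-likelihood trace is recorded and is non-decreasing (tested);
* the brighter component is always reported as the vessel class.

One empirically important decision: the model is fitted on the
bias-corrected but *unsmoothed* volume (`preprocess_volume()` returns it as
`model_volume`). Edge-preserving smoothing drags vessel-adjacent tissue
upward and brain-boundary tissue downward, making the tissue marginal
heavy-tailed; the two-Gaussian maximum-likelihood solution then degenerates
into a narrow-core-plus-broad-blanket fit whose "vessel" component is a
blanket over the tails (we traced the EM trajectory to confirm). On the
pre-smoothing volume the marginal is an honest two-Gaussian mixture and the
fit recovers the generating parameters to within a couple of intensity
units.

`initial_segmentation()` assigns a voxel to the vasculature iff its
vessel-class posterior is at least the tissue posterior (log-space, so air
at intensity 0 cannot tie by underflow). `adaptive_refine()` then works
axial slice by axial slice: each 8-connected component of the initial mask
defines a search window (bounding box dilated by `window_growth` times the
component's equivalent diameter — "adaptive size" is otherwise unspecified,
so the window scales with the structure it surrounds), local vessel and
tissue means are taken from in-mask and out-of-mask window voxels, and
window voxels brighter than the local midpoint `T = (mu_b + mu_o)/2` join
the mask. `generate_seeds()` promotes every refined voxel to a seed and
repeats the window scan to append bright out-of-mask candidates.
`region_grow_3d()` grows breadth-first over 26-neighbours, accepting voxels
strictly above the global midpoint threshold, then drops components smaller
than 5 voxels (configurable). Strict inequality makes tie behaviour
explicit; ties have measure zero under continuous noise. Whether the final
growth should use the global or the per-window threshold is ambiguous in the
source; the global threshold is used, and the per-window records are
returned so the alternative is one line away.

All segmentation stages are deterministic. On the reference phantom
(128^3, intensity separation 100, noise SD 15, bias amplitude 0.2) the full
chain reaches a Dice overlap around 97%, comfortably above the 90% property
target; noiseless phantoms are recovered voxel-exactly.

## Feature extraction

`distance_map()` is an exact Euclidean distance transform (separable
lower-envelope algorithm, compiled; oracle-tested against brute force). The
skeleton is the *distance ridge*: mask voxels whose distance value is
maximal over their 26-neighbourhood, plateau-inclusive. No 3-D thinning is
available in the installed stack, and for radius statistics the ridge is the
right object: on tubes it is the medial axis, and radii are read directly
off the distance map at ridge voxels. Radii are sampled at skeleton voxels —
not all mask voxels — so a thick vessel contributes per unit length, not per
unit volume.

The 11 CDF bins evaluate the radius distribution at integer thresholds with
a half-voxel tolerance (`radius <= j + 0.5`): the nearest background lattice
point overshoots the true radius by up to ~0.25 voxels (e.g. a radius-4
cylinder reads sqrt(17) ≈ 4.12), and the tolerance assigns each radius to
its nearest integer bin. The stored vector is zero-padded: every entry after
the first bin that reaches 1 is set to 0, matching the saturation-marking
storage convention of the published sample vectors. The bins are stored as a
CDF (monotone rise to 1, then padding zeros) — the published samples show
exactly this monotone-then-zeros pattern, which a PDF could not produce.

Curvatures come from an implicit-surface formulation: the binary mask is
Gaussian-presmoothed (SD 1 voxel by default) and principal curvatures are
computed at surface voxels from the gradient and Hessian of the smoothed
indicator, with signs oriented so convex bright structures are positive.
Oracle accuracy at the defaults: sphere of radius 10 — median mean curvature
within 2% of 1/R, median Gaussian curvature within 14% of 1/R²; cylinder of
radius 6 — median mean curvature within 4% of 1/(2r) and Gaussian curvature
indistinguishable from 0. Vanishing-gradient points are skipped and counted.

One property the feature set does **not** have: the surface-averaged mean
curvature does not increase with tortuosity. For a tube bent smoothly, the
area-weighted average of mean curvature over the lateral surface equals the
straight tube's `1/(2r)` (the inner and outer sides cancel exactly), and
more tortuous branches are longer, diluting the high-curvature end caps — so
the average in fact *decreases* slightly. What does respond monotonically is
curvature dispersion: the SD of mean curvature and the mean absolute
Gaussian curvature both rise with bend amplitude in essentially every seeded
phantom, and that is the property the test suite asserts. The emulated
feature generator keeps an explicit tortuosity term in its curvature
features, mirroring the clinical association the analysis is built around.

## Labeling rules

Resting pressure is the arithmetic mean of exactly four readings.
`MAP = (1/3)·SBP + (2/3)·DBP`, reported to two decimals. The systolic rule
calls a subject hypertensive iff SBP > 130 mmHg (strict, following the
source's literal definition even though the guideline band starts at 130;
the cut and strictness are configurable), the diastolic rule iff
DBP > 80 mmHg; either rule calls a subject normotensive only when both
components are in the normal range, and anything else — notably the
120–130 mmHg systolic band — is excluded from that sub-experiment rather
than forced into a class.

The MAP categories are published as two-decimal interval endpoints with
0.01-wide gaps between them (… 99.00 | 99.01 …). Rounding MAP to two
decimals before comparison makes the partition exhaustive — every positive
MAP lands in exactly one category (tested by sweeping at 0.01 mmHg
resolution) — and places the grade-3 boundary exactly at 132.34. The binary
collapse maps normal to normotensive, high-normal and all hypertension
grades to hypertensive, and optimal to excluded (no matching category exists
under the single-component rules).

## Balancing

`smote()` implements standard SMOTE — each synthetic sample lies on the
segment between a minority point and one of its k nearest minority
neighbours (k = 5 by default), with a uniform interpolation weight — and a
weighted-accumulation variant in which one uniform weight per contributor
(the point plus its k neighbours) is normalised to sum to 1 and the weighted
vectors are accumulated, keeping every synthetic sample inside its
contributors' convex hull. Weights are per-neighbour; a per-feature reading
of the same description would scatter samples off the minority manifold.
Standard SMOTE is the default variant. Balancing happens in raw feature
space (no standardization) by default, matching the feature-space
description of the technique; synthetic rows are always flagged
`source = "synthetic"`.

## Experiments

`train_eval()` fits on training portions only and pools accuracy
(`100 × correct / total`) over held-out portions; leave-one-out is
deterministic and equals the mean of the n single-sample evaluations. Splits
whose training portion contains a single class are redrawn with a shifted
seed and the redraw count is reported. Columns with zero variance in a
training fold (e.g. saturated CDF bins) are dropped for that fold.

By default SMOTE runs *inside* training folds only (`leakage_safe = TRUE`):
balancing before splitting lets synthetic neighbours of test subjects into
training and inflates accuracy. `leakage_safe = FALSE` reproduces that
balance-then-split order for fidelity with the published protocol, with this
caveat.

The classifier registry covers the published grid. Hyperparameters beyond
kernel/metric/architecture are the conventional defaults of the underlying
implementations; the KNN Minkowski order is 3 (it must differ from Euclidean
to be a distinct grid entry); quadratic discriminants are exposed as their
own family since a "linear discriminant with quadratic kernel" is
contradictory. The two-hidden-layer perceptron (needed for the (10, 8) and
(13, 9) architectures) is trained by BFGS on an analytic-gradient
cross-entropy with weight decay 0.01; discrete AdaBoost (and its
random-undersampling variant RUSBoost) boosts depth-1 CART stumps for 40
rounds; bagged trees are a random forest with `mtry = p`. "Validation
15.0%" style entries are read as hold-out test fractions.

## Problem sizes used by the test suite

The suite validates the image chain end-to-end on one 128^3 reference
phantom and a handful of 48^3–64^3 phantoms; the cohort-level recovery
experiment uses 20 seeded replicates of 300 subjects each in feature mode
(the generator's cached-feature output), with the volume mode exercised on a
small cohort — sizes chosen so the whole suite runs on a laptop in about a
minute while still exercising every stage at realistic scale. The
permutation-null check runs every registry classifier over 50 label
permutations of a 200-subject feature table.

## Known limitations

* The phantom's two-Gaussian intensity world is kinder than real MRA;
  partial-volume effects, Rician noise and flow artefacts are absent, so the
  reported Dice figures bound what the algorithm can do only under the
  modelled degradations.
* The distance-ridge skeleton can thicken to 2-voxel plateaus on
  even-diameter tubes and fragment on very noisy masks; radius statistics
  are robust to this, branch counting would not be.
* Curvature estimates degrade for structures thinner than the presmoothing
  SD; radius-1 vessels report inflated mean curvature.
* The emulated feature generator reproduces the *direction* of
  morphology–pressure coupling, not any measured effect size; classification
  accuracies on synthetic cohorts characterise the pipeline, not clinical
  performance.
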