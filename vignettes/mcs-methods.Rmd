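---
title: "Methods: a multiple classifier system for breast DCE-MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a multiple classifier system for breast DCE-MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dcemcs)
```

This vignette documents the models, parameter choices and numerical
conventions behind `dcemcs`, and what the synthetic phantom does and does
not establish about behaviour on clinical data.

## Problem and rationale

In breast DCE-MRI, radiologists weigh two complementary signals: lesion
*kinetics* (malignant lesions typically enhance early and wash out; benign
lesions enhance slowly and persist) and lesion *morphology* (benign lesions
tend to be round with smooth margins; malignant ones irregular). A single
classifier fed the concatenation of both feature families tends to be
dominated by whichever family is noisier. The multiple-classifier
alternative trains one classifier per family — a Gaussian naive Bayes on
voxel-level kinetic features, a decision tree on lesion-level shape
features — and fuses their class probabilities with a single mixing
coefficient, so each channel is modelled on its own terms and the ensemble
can only be as bad as the channel the data favour.

## Segmentation

The automatic path builds, per voxel, the sum of intensity differences
`SOD = Pre + sum_i |Post(i) - Post(i-1)|`, taking `Post(0) := Pre` so that
the first inter-scan term is defined and a flat curve yields `SOD = Pre`.
The SOD map is a whole-curve activity summary: enhancing tissue scores high
regardless of curve shape, air scores near zero.

* **Otsu threshold.** A 256-bin equal-width histogram over `[min, max]`;
  the returned threshold is the bin edge maximising between-class variance,
  ties broken toward the lowest edge, and the foreground rule downstream is
  strictly `value > threshold`. The bin count, tie rule and strictness are
  fixed so that two implementations of the definition agree bit-for-bit;
  the test suite holds the function to an exhaustive search over all 255
  candidate edges. Thresholding is whole-volume (not per slice).
* **Cleanup.** Closing with a discrete ball (radius 2 voxels by default,
  `segmentation$struct_radius`), hole filling (2D slice-wise with
  4-connectivity, then 3D with 6-connectivity), then erosion by the same
  ball. Closing and the final erosion treat out-of-grid voxels as
  foreground, so structures touching the image border (the chest-wall side
  of the breast) are not eaten from outside; this keeps closing extensive,
  which the containment tests rely on.
* **Suspicious voxels.** Inside the breast mask, a voxel is suspicious iff
  (C1) its maximum relative enhancement exceeds 0.3 — a deliberately
  sensitive threshold, below the 40–50% used for diagnostic reads, chosen
  to limit false negatives — and (C2) its maximum post-contrast signal is
  first attained strictly before the final scan. "First attained" makes a
  late plateau count as peaked (the plateau pattern is suspicious) while a
  curve still rising at the last scan (persistent benign pattern) is
  excluded. Voxels with zero basal signal are never suspicious: relative
  enhancement is undefined there, and in the phantom a zero pre-contrast
  value marks non-tissue.
* **VOIs.** 26-connected components of the suspicious mask, discarding
  components below `min_voi_size` (10 voxels), returned largest-first. The
  pipeline takes the largest component of a single-lesion series as the
  lesion; separating touching lesions is out of scope.

## Features

Shape features are computed slice by slice where the definitions are 2D
(area `n_k dx dy`, boundary-voxel perimeter under 4-connectivity with the
grid border as background) and summarised by the median over the slices the
VOI intersects (even counts: mean of the middle two). The perimeter is a
voxel *count* by default, faithful to the stated formula; set
`features$perimeter_mm` to scale by the in-plane spacing. The 3D features
are compactness `S^2/V` — surface `S` = 6-connectivity boundary count ×
`dx` × slice thickness (the linear in-plane spacing stands in for the
"voxel size" length so that `S` has units of area; in-plane spacing is
isotropic in the targeted acquisitions) and `V = n dx dy dz` — and the
eccentricity `sqrt(a^2 - b^2)/a` of the voxel cloud's principal semi-axes
in physical coordinates (semi-axis = `2 sqrt(eigenvalue)` of the
second-moment tensor; only the axis ratio matters to the result). Whether
eccentricity was meant per slice or in 3D is ambiguous in the source
material (it is listed among 3D features but defined with two axes); we
implement the 3D principal axes and fall back to the in-plane axes for the
degenerate single-slice case.

Dynamic features per voxel: the basal signal, the ordinary least-squares
slope of `RE(t_i)` over *all* post-contrast scans (a formula was not
printed for the "relative enhancement slope"; OLS over the full series is
the least arbitrary single number, and alternatives such as wash-in slope
to peak are deliberately out of scope), and SOD.

The wider catalogues these four + three features were selected from are not
reproduced: no formulas were given for the discarded entries, and only the
retained set feeds the classifiers.

## Feature selection

`select_features()` implements CFS merit
`k r_cf / sqrt(k + k(k-1) r_ff)` (label coded 0/1; correlations as absolute
Pearson) and the consistency score (equal-width discretisation, 10 bins;
one minus the fraction of instances outside their pattern's majority
class), under five deterministic searches. Stopping rules are unstated in
the source material, so they are fixed and config-exposed: best-first
searches stop after 5 consecutive non-improving expansions, greedy stops at
the first non-improvement, ranking cuts at the largest consecutive score
drop or a cap of 10. All ties break by lexicographic feature name, making
selection a pure function of the table.

## Classifiers

The **tree** grows axis-aligned splits maximising information gain over
midpoint thresholds, stops at pure nodes or nodes below `min_leaf = 2`, and
stores Laplace-smoothed leaf probabilities `(count + 1)/(n + 2)` — so even
pure leaves never claim certainty. It is unpruned by default; the
"confidence factor 0.25" tunable is kept (a C4.5-style pessimistic
subtree-replacement pruning using the Clopper–Pearson upper error bound)
for the pruned variant, and is inert otherwise. The **naive Bayes** uses
empirical class priors and independent Gaussian class-conditionals with
per-class sample variance floored at 1e-9 (degenerate single-value classes
collapse to the floor), evaluated in log space. Both models expose
`predict_proba()` returning a `(p_malignant, p_benign)` pair that sums
to 1.

Voxel-level dynamic classification inherits each training lesion's label
for all of its voxels (all voxels are used, not a subsample), and the
lesion's dynamic probabilities are the hard-vote fractions `D_m = n_m/N`,
`D_b = n_b/N`. Vote ties go to malignant — in a screening context a false
positive is cheaper than a false negative, and the same tie rule is used
everywhere a decision can be exactly balanced.

## Fusion and the choice of alpha

The fused rule is `malignant iff alpha D_m + beta M_m > alpha D_b + beta
M_b` with `beta = 1 - alpha`; only the channel margins matter. Accuracy as
a function of alpha is piecewise constant — each lesion's decision flips at
most once along `[0, 1]` — so the maximiser is an interval, not a point.
`select_alpha()` evaluates a 0.05 grid and returns the midpoint of the
widest maximal-accuracy run (first run on ties): the midpoint of a
high-performance plateau is stable to one lesion flipping, whereas an
endpoint is not. The grid step and tie handling are design choices made
here; the qualitative picture (a plateau of good alpha values around
0.7–0.8 when the dynamic channel is the stronger one) is what the method
predicts whenever one channel dominates without being perfect.

One deliberate deviation: estimating alpha on the *test* lesions — as the
original clinical study did — leaks test information into a tuned
parameter. The default here selects alpha on the training split, scoring
each training lesion with channel probabilities from models refit with
that lesion held out (leave-one-out); without the refit, the unpruned
tree's resubstitution probabilities are perfect and alpha would always
collapse onto the morphological channel. The test split is touched exactly
once. The test-set mode remains available (`fusion$alpha_on_test`) for
comparison with the original protocol.

Lesions in which the automatic segmentation finds nothing are predicted
benign by both channels (`D_m = M_m = 0`): no suspicious enhancement was
found, which is itself the benign-pattern signature under C1/C2.

## Evaluation

`metrics()` reports sensitivity, specificity, PPV, NPV and accuracy with
malignant as the positive class, at full precision internally; display
rounding is half-up to one decimal (`format_metrics()`), matching the
convention of clinical performance tables. Zero-denominator metrics are
flagged undefined rather than imputed. `mcnemar_paired()` uses the exact
two-sided binomial on the discordant pair counts when `b + c < 25` and the
continuity-corrected chi-square above (the variant was not specified at the
source; the switch point is config-exposed), with `p = 1` when there is no
discordance.

## The phantom

`generate_cohort()` emulates exactly the contrasts the pipeline exploits.
Each lesion gets its own series: a half-ellipsoid "breast" at baseline 100
a.u. with mild enhancement (amplitude 0.08), air at exactly zero, and one
lesion whose voxels follow

    SI(t) = BS0 (1 + A (1 - exp(-k_in t)) exp(-k_out t)) + noise,

with Gaussian noise clipped at zero. Default scan times are 1 pre + 9 post
frames at 56 s spacing; spacing 1×1 mm in-plane, 2 mm slices (lesions are
rasterised with the corresponding 2:1 z-anisotropy so they are physically
round). Shapes are balls (`rho = 0`) or radius-modulated by a seeded
low-order angular field of relative amplitude `rho` (irregular margins),
kept 26-connected by construction and placed at least the cleanup-erosion
depth inside the breast so segmentation morphology never clips ground
truth. All draws flow from one integer seed through per-lesion substreams,
so enlarging a cohort never reshuffles existing lesions.

Two profiles define the study conditions:

* `default`: benign A in [0.35, 0.8], `k_out = 0` (persistent, peak at the
  final scan — fails C2 by design); malignant A in [0.8, 1.5] with `k_out`
  chosen so the continuous peak falls in scans 2–4 of 9; shape
  irregularity 0–0.25 vs 0.35–0.7; noise 2% of baseline. With noise off,
  the classes are exactly separable by the suspicious-voxel rules: this is
  the oracle cohort for the segmentation tests.
* `hard`: overlapping amplitude/rate/shape ranges, benign lesions given a
  mild wash-out (so both classes pass C1/C2 and are segmentable), noise 4%
  and 12% per-voxel amplitude heterogeneity. Neither channel is trivially
  perfect here; this is the cohort for the fusion properties.

What the phantom does **not** model: pharmacokinetic realism (no
Tofts-type exchange), Rician noise statistics (the pipeline consumes
ratios and differences of intensities, for which Gaussian noise is an
adequate stress), coil bias fields, motion, multi-focal or touching
lesions, and anatomical texture. Passing tests on phantom cohorts
establishes that the pipeline implements its stated rules and that fusion
behaves as designed when its assumptions hold — not that clinical accuracy
will match the synthetic numbers.

## Numerical conventions and problem sizes

Exact decision ties resolve to malignant with a 1e-12 tolerance (floating-
point sums of probabilities are not exact). Split gains must exceed 1e-12
to be taken. The NB variance floor is 1e-9. Medians of even counts are the
mean of the middle two. Voxel coordinates are 1-based (natural array
indexing in R); nothing on disk depends on the convention since masks are
exchanged as NIfTI volumes.

The shipped validation uses 32×32×10 grids with 10 time frames: four-lesion
noiseless cohorts for the exact segmentation properties, and ten 48-lesion
overlapping cohorts (32 training / 16 test, mirroring a 14+18 / 8+8
class-stratified split) for the end-to-end fusion property, totalling a few
minutes of compute. Grids and cohort sizes are arguments throughout, so
larger studies are a matter of budget, not code.

## Known limitations

* The morphological channel sees the *automatic* VOI when run end-to-end;
  segmentation noise therefore degrades shape features before the tree
  ever sees them, which is visible in the phantom results as a weak
  morphological channel. This mirrors the motivation for fusing channels
  rather than trusting either alone.
* CFS is indifferent between exact duplicates of a feature (the merit is
  provably equal); determinism comes from lexicographic tie-breaking, not
  from the score.
* `select_alpha()` assumes channel probabilities are comparable across
  lesions; heavily miscalibrated channels would shift the plateau.
* The McNemar p-values reported for paired classifiers on 16-lesion test
  splits are coarse; they are provided for protocol completeness.
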