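---
title: "Texture-based lesion classification: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture-based lesion classification: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesiontex)
```

`lesiontex` classifies dermoscopic lesion images from texture alone. This
vignette is the package's account of the science inside it: the models, what
their parameters mean, which choices were genuinely open and how they were
made, and what the synthetic benchmark does and does not demonstrate.

## The pipeline at a glance

Each image passes through four stages. A Chan–Vese active contour isolates
the lesion; a multi-resolution empirical mode decomposition (MREMD) produces
the first bidimensional intrinsic mode function (BIMF), a signed
fine-detail layer; max-rotation local binary pattern (LBP) histograms are
taken over the lesion area of both the image and that first BIMF; and the
concatenated 512-entry feature vector feeds a small feed-forward network.
Intensities are kept on the `[0, 255]` scale of 8-bit dermoscopy files
throughout — every stage downstream is either comparison-based (LBP,
envelope extrema) or scale-aware (Chan–Vese's `mu` default), so no
rescaling to `[0, 1]` is needed. No contrast pre-processing (e.g. CLAHE) is
applied anywhere: the region-based contour is robust to illumination
variation, which is the usual argument for skipping it.

## MREMD: fixed-window envelopes and dyadic resolution

Classical bidimensional EMD sifts a signal by subtracting the mean of upper
and lower envelope surfaces interpolated through local extrema. That makes
its cost and its output depend on how many extrema the image happens to
contain. MREMD removes both dependencies:

* **Envelopes by order-statistic filtering.** The upper/lower envelopes are
  the windowed max/min of the (box-smoothed) working copy, over a *fixed*
  `envelope_window` of 5 px. Both envelopes are then box-smoothed and
  *clamped* against the working copy (`upper = max(upper, Y)`,
  `lower = min(lower, Y)`) so that local maxima still touch the upper
  envelope after smoothing — without clamping, smoothing would cut corners
  through the extrema the envelopes are supposed to bound.
* **Coarser scales by resolution, not window growth.** Level `n` decimates
  the input by `2^(n-1)` (stride sampling; the immediate box smoothing makes
  prior anti-aliasing redundant), runs the same 5×5 envelope machinery, and
  replicates the mean envelope back to full resolution, smoothing once to
  remove the replication blockiness. At level 1 nothing is resampled and no
  post-smoothing is applied — the envelopes were already smoothed before
  averaging, and this keeps the level-1 pass identical to its closed
  description `M1 = (U1 + L1)/2`, `C1 = I − M1`.
* **One sifting pass per level.** The BIMF is always *input minus mean
  envelope of that input*, so the decomposition telescopes and
  `sum(BIMFs) + residual` reproduces the input to machine precision — an
  invariant the test suite checks on every shape it generates.

Parameters (`mremd_params()`): `envelope_window = 5` px and
`smooth_window = 5` px (tied, following the fixed-window order-statistic
BEMD family); `n_levels = 4` (only the first BIMF is consumed by the
classifier, but the full stack is useful for inspection); `min_side = 8`
stops decomposition before a level would operate on an image smaller than
its own filters. Non-power-of-two sizes use ceiling dimensions on the way
down and crop after replication on the way up, so 200 → 100 → 50 → 25
works without padding.

Border handling everywhere is replicate (edge-clamp) padding: it invents no
intensities and is the standard choice for order-statistic filters.

## Chan–Vese segmentation

The contour minimizes

$$F(C, c_1, c_2) = \mu\,\mathrm{length}(C) + \nu\,\mathrm{area}(C)
 + \lambda_1 \sum_{\text{in}} (u_0 - c_1)^2
 + \lambda_2 \sum_{\text{out}} (u_0 - c_2)^2,$$

with `lambda1 = lambda2 = 1`, `nu = 0` by default. The implementation is a
level-set gradient descent with a smoothed Heaviside of width
`epsilon = 1` px, and three numerical choices worth recording:

* **Weighted means.** For a fixed contour the minimizing `c1`, `c2` are the
  Heaviside-weighted region means, and using exactly those (rather than the
  binarized-mask means) is what guarantees the alternating scheme can never
  increase the functional. The binary-mask means are still what
  `region_means()` reports and what the discrete `fitting_energy()` uses.
* **Preconditioned descent with backtracking.** The raw gradient is
  localized by the smoothed delta, which moves the front about one pixel per
  iteration — far too slow from a centred-circle initializer. Dividing the
  gradient pointwise by the (positive) delta is a diagonal preconditioner:
  still a descent direction, but the front moves at full speed everywhere.
  The level-set function is kept in `[-5, 5]` so saturated pixels flip in a
  few unit steps. Each step is accepted only if the energy does not
  increase (halving the step up to 25 times otherwise), so the recorded
  energy trace is non-increasing by construction; evolution stops when the
  relative change falls below `tol = 1e-4`, when no decreasing step exists,
  or at `max_iter = 300`.
* **`mu` scales with contrast.** The length penalty competes with data terms
  of order (intensity range)² per pixel, so a dimensionless constant cannot
  serve all images. The default is `0.1 * range(img)^2 / sqrt(H^2 + W^2)`;
  on a constant image this gives `mu = 0`, zero force, and the initializer
  is returned unchanged. The hot loop is compiled (Rcpp) — at 200×200 the
  evolution is transcendental-function-bound in plain R.

`lesion_mask()` converts the two-phase partition into "the lesion": the side
whose mean differs most from the 5-px border ring is taken as lesion
(dermoscopy crops keep lesions central, so the ring samples skin regardless
of polarity), then the largest 8-connected component is kept and holes are
filled. The energy partition alone cannot decide which phase is the lesion,
which is why this cleanup exists. Masks below 25 px raise an error rather
than returning something meaningless.

## Max-rotation LBP features

Each pixel's 3×3 neighbourhood yields an 8-bit label string (1 where a
neighbour *strictly* exceeds the centre — ties are 0), read clockwise; the
code is the maximum over its eight cyclic rotations. Taking the maximum
(rather than the conventional minimum) changes nothing structurally — it is
a canonical representative of the rotation orbit, so the code is independent
of the starting neighbour and insensitive to in-plane texture rotation. The
map is invariant to global intensity shifts and positive rescaling because
only order comparisons enter.

Border pixels are coded with replicate padding instead of being skipped, so
lesions touching the frame lose no area; and a masked pixel's neighbours
participate in its code even if they lie outside the mask — the mask
restricts the *histogram*, not the comparisons. Histograms are normalized by
lesion area, making lesions of different sizes comparable; the 512-entry
vector (image ‖ first BIMF, same mask) therefore sums to exactly 2.

## The classifier

A 512→25→7 network: sigmoid hidden layer, softmax output, cross-entropy
loss (the canonical pairing with softmax), full-batch gradient descent with
momentum 0.9. Weights initialize uniformly in `[-0.5, 0.5]` from a seed;
everything downstream is deterministic in that seed. Early stopping is the
reproducible stand-in for manual loss monitoring: a seeded 15% validation
split is scored every epoch, training stops after `patience = 100` epochs
without improvement (or at 5000 epochs), and the best-validation weights
are restored. Gradient correctness is pinned by a finite-difference check
in the standing test suite.

Two rates, one decision: `ann_config()`'s generic default step size is
0.01, but the *pipeline* trains at 0.5. The features are bins of unit-sum
histograms (typical magnitude 10⁻²), so gradients through them are small;
at 0.01 the full-batch loss is still near its chance plateau when the epoch
cap is reached, while at 0.5 it converges cleanly. The value was chosen by
watching training-loss convergence on a small dry run — the standard
trial-and-error calibration for this kind of classifier — and is exposed in
the config like every other tunable. No input standardization is applied:
the histograms are already bounded and commensurate.

## Evaluation

`confusion_matrix()` is truth-by-prediction; per-class one-vs-rest counts
give sensitivity `100·TP/(TP+FN)`, specificity `100·TN/(TN+FP)` and
accuracy `100·(TP+TN)/total`, macro-averaged without weights — appropriate
here because test sets are balanced, in which case macro sensitivity equals
the overall recognition rate. The package ships a published benchmark
confusion matrix for a balanced 7-class dermoscopy test set
(`reference_confusion()`), whose macro sensitivity/specificity round to
96.5 / 99.4 and whose best and worst per-class recognition rates are 100%
and 93.3%; the test suite recomputes these from the counts. Note that the
macro one-vs-rest *accuracy* of that matrix is 99.0 to one decimal — a
reminder that "accuracy" for multiclass problems depends on the
aggregation convention, which is why the package reports the overall
recognition rate separately.

## The synthetic benchmark: what it shows and what it does not

`generate_sample()` builds 200×200 images with one star-convex lesion
(periodic-spline radius around a jittered centre, mean radius 0.25·side,
±30% radial jitter, redrawn if the area leaves 10–60% of the frame) on a
background of base intensity 180 with a 15-unit linear illumination drift
and Gaussian noise (sd 8). The lesion interior is base 90 plus a
class-`k` oriented sinusoid (frequency `(2+k)/64` cycles/px, orientation
`k·180/7`°, amplitude 25) plus speckle of sd `3k`. Classes therefore differ
*only* in micro-texture statistics — exactly what LBP measures — and not in
mean intensity, so the classification task cannot be solved by brightness
shortcuts. The default protocol mirrors the real study design: 7 classes,
70 training and 45 test images per class (490/315).

What passing this benchmark demonstrates: the geometry pipeline finds the
right region (Dice ≈ 1 against ground truth), the feature pipeline
separates texture families, and the trained network generalizes across
seeds (~98% test accuracy at the full protocol, seed 1). What it does not
demonstrate: performance on real dermoscopy. Real lesions have colour,
hair and ruler artifacts, diffuse borders, intra-class texture diversity
and class imbalance, none of which the generator emulates. The synthetic
accuracy is a correctness check for the implementation, not a clinical
claim.

Problem sizes in the test suite are deliberately modest — oracle
equivalence on ~100 small random images per filter, 20 noise seeds for the
segmentation benchmark, one full-protocol run — which keeps the default
suite complete on a single CPU while still exercising every contract.

## Degenerate inputs and errors

Empty regions (`region_means`), empty masks (`masked_histogram`),
single-class training sets, collapsed contours, sub-25-px segmentations,
non-finite losses and too-deep decompositions all raise classed conditions
(`empty_region`, `empty_mask`, `degenerate_labels`, `contour_collapse`,
`segmentation_too_small`, `diverged_training`, `mremd_depth_exceeded`) so
callers can branch on failure mode; the batch pipeline logs per-image
segmentation failures and continues rather than aborting a run.

## Known limitations

* Grayscale only: colour information, which carries diagnostic signal in
  real dermoscopy, is deliberately out of scope; RGB inputs are reduced by
  Rec. 601 luminance.
* The contour model is two-phase: multifocal lesions beyond the largest
  component are discarded by design.
* The max-rotation LBP coarsens texture orientation information; textures
  that differ only by rotation are (intentionally) conflated.
* Training is full-batch; at much larger sample sizes a mini-batch scheme
  would be preferable.
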