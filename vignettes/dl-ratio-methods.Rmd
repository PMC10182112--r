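---
title: "Ground-truth box scale (D/L) and detection evaluation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ground-truth box scale (D/L) and detection evaluation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dlratio)
```

## The problem

Tumor-detection models for B-mode ultrasound are trained on square
ground-truth regions of interest (ROIs) that radiologists draw around
lesions. How large that ROI is drawn *relative to the tumor* varies between
annotators, and in a pooled multi-center database it varies a lot. dlratio
quantifies this with the **D/L ratio**: the maximum tumor diameter $D$
divided by the side length $L$ of the square ROI. At $D/L = 1$ the ROI is
tangent to the tumor; at $D/L < 1$ it is larger and includes peritumoral
context (liver parenchyma, the posterior echo — the bright band behind a
cyst or the shadow behind a solid mass); at $D/L > 1$ it cuts into the
tumor.

The package implements the full experimental machinery for studying how the
training-time D/L condition affects detection metrics measured against a
*fixed* tangent ($D/L = 1$) test ground truth: annotation geometry,
preprocessing, an evaluation protocol with a calibrated IoU threshold,
synthetic data, and the two experiment designs (a fixed-D/L sweep and a
distributed-D/L comparison).

## Annotation geometry

An annotation is (case, image, tumor type, center, $D$), with the center
defined as the center of the smallest circle circumscribing the tumor. The
ground-truth ROI at ratio $r$ is the square of side $L = D/r$ centered
there; the center is never shifted. Geometry uses continuous real-valued
coordinates with the origin at the top-left and boxes as closed real
intervals, so areas are exact products of side lengths and IoU is exactly a
set-measure ratio; no pixel-grid $\pm 1$ corrections are applied anywhere.

Under a *fixed* condition every image receives the same ratio; under a
*uniform range* condition one ratio per image is drawn i.i.d. from
$\mathrm{U}(a, b)$. The per-image granularity is a design choice: a
distribution of D/L "across a training set" is most naturally realized as
one draw per annotated image, and it is what a database with
annotator-dependent ROI habits would produce.

## Preprocessing

The preparation chain for a training condition runs in this order:

1. **D/L assignment** and ROI construction in the original frame.
2. **Margin padding.** ROIs with small D/L can exceed the image, so a zero
   background margin is added first. The margin is specified at the
   *output* scale: 25 px on each side of the final 448×448 network input.
   For an original extent $d$ the per-side pad is therefore
   $m = 25d/(448 - 50)$, which makes the post-resize margin exactly 25 px.
3. **Elimination.** Images whose ROI still exceeds the padded frame are
   dropped and counted. Because ROIs shrink monotonically as D/L grows, the
   eliminated set at a smaller D/L always contains the eliminated set at a
   larger one; elimination counts are non-increasing in D/L. Elimination is
   applied per condition — an image dropped at $D/L = 0.4$ still trains the
   $D/L = 1.0$ condition.
4. **Resize** to 448×448 by bilinear interpolation (EBImage), applied to
   both down- and up-scaling. The resize is anisotropic: non-square images
   are squashed, which breaks box squareness. Rather than letterboxing
   (which the pipeline deliberately avoids — the whole ultrasound frame is
   the input), annotations carry cumulative per-axis scale factors and the
   square ROI is *re-derived* per axis in the resized frame, keeping the
   D/L semantics exact. All shipped phantoms are square, so in practice
   both scales are equal and ROIs remain square.
5. **Flip doubling.** Every surviving record is mirrored horizontally
   ($x' = W - x$); the training set size exactly doubles.

Test images go through the same margin and resize (their geometry must live
in the same frame) but are never eliminated or flipped.

**Case-wise splitting.** Images of one case are near-duplicates, so splits
assign whole cases. Cases are stratified by tumor type, shuffled under a
seed, and greedily packed into `n_splits` (default 3) pairwise-disjoint test
partitions, each targeting 20% of the type's images; a case is assigned to
the neediest partition only if that brings it closer to its target than
skipping would. Each split's training set is the complement of its own test
partition, so training sets of different splits overlap but no test image
ever appears twice. Whole-case assignment makes exact 20% unattainable; the
greedy packing typically lands within 2–3 percentage points.

## Evaluation protocol

The test ground truth is always built at $D/L = 1.0$: evaluating against
each condition's own enlarged ROI would let a loosely-annotated model grade
itself generously.

Per image, with one annotated tumor: among detections with positive IoU
against the ground truth, the highest-confidence one is evaluated; if all
detections have IoU 0, the highest-confidence detection is evaluated
anyway. The image is **TP** if the evaluated IoU clears the threshold,
**FP** if it does not, **FN** if the detector emitted nothing. IoU exactly
equal to the threshold counts as TP (ties are measure-zero; the convention
is configurable via `classify_outcome(ties =)`). FP may include correct
detections of unannotated structures (vessels, second tumors); TP and FN
are unaffected, which is what the D/L comparison needs.

Precision, recall and F1 follow the usual definitions. A metric with a zero
denominator is reported as `NA` ("absent"), never as 0 or 1, and weighted
averages skip absent values together with their weights — silently imputing
0 would bias comparisons exactly where detectors fail hardest.

**Threshold calibration.** The IoU threshold is chosen by discriminant
analysis (Otsu's method) on the IoU distribution of the $D/L = 1.0$
condition, with every FN entered as IoU = 0: the cut $t$ maximizing the
between-class variance $\sigma_B^2(t) = w_0 w_1 (\mu_0 - \mu_1)^2$.
Candidates are midpoints between consecutive sorted unique values, which is
exact for finite samples; a 256-bin mode is available for very large
samples. $\sigma_B^2$ is constant across any empty gap between the two
classes, so when several candidates tie, the center of the maximizing set
is returned. The identity $\sigma_B^2(t) + \sigma_W^2(t) = \sigma^2$ (with
population variances) holds at every candidate and is asserted in the test
suite. The constant 0.375 is shipped as the default threshold for use
without a calibration set.

**Best-of-runs reporting.** Detector training is stochastic, so each
condition is run `n_runs = 3` times; the reported figures are the maximum
of precision, recall and F1 and the minimum of FN over the runs, each
extremum taken independently (they may come from different runs; the run
index is recorded). Per-type tables are additionally averaged across the
three splits weighted by each split's test-image count.

## Synthetic phantoms

`generate_phantom_dataset()` emulates the *structure* of the reference
collection (`liver_reference_counts()`): four tumor types in the published
proportions (a 1/10-scale default of ~760 images over ~198 cases), several
images per case with shared per-case appearance, tumor diameters from 5% to
62% of the image (very small lesions up to lesions wider than half the
frame), multiplicative gamma speckle inside a fan-shaped sector, and
type-specific archetypes: near-anechoic cyst with posterior enhancement,
hyperechoic hemangioma, hypoechoic mosaic HCC, and a bull's-eye metastasis
with posterior shadowing. Rendering is deferred — annotations carry the
parameters and seed to reproduce any image bit-identically — so large
experiments run at the geometry level without touching pixels.

These are statistical look-alikes, not wave-physics simulations. They
exercise the geometry, preprocessing and evaluation machinery faithfully,
but passing tests on phantoms says nothing about how hard real tumors are
to recognize; absolute metric values here are properties of the simulator,
and only the *relative* behavior across D/L conditions is meaningful.

## The detector simulator

No GPU-trainable detector is included (out of scope); instead
`detector_behavior()` encodes how a trained detector's output depends on
its training D/L condition, with one load-bearing assumption and two
supporting ones, all stated here as modeling choices of this package:

* **Size bias** (load-bearing): predicted boxes scale like the training
  ROI, side $\approx D / \overline{D/L}_{\text{train}}$ — detectors
  trained with enlarged ROIs draw enlarged boxes. In the noiseless limit
  this yields the closed form: a contained predicted box of side $D/\rho$
  against the tangent ground truth has
  $\mathrm{IoU} = \rho^2$, so at threshold 0.375 recall collapses exactly
  for $\rho \le \sqrt{0.375} \approx 0.612$ — training at D/L 0.4–0.6
  fails, 0.7–1.0 survives.
* **Range width hurts consistency**: the lognormal box-size noise grows
  linearly with the width of the training D/L range (`0.08 + 0.25·width`),
  so distributed conditions lose IoU even at the same mean.
* **Condition-dependent misses**: the miss probability adds
  `0.3·|mean D/L − 0.9| + 0.3·width` to a 0.08 base, plus a penalty for
  very small (<4% of frame) and very large (>55%) tumors. Without such a
  term the FN count could not depend on the training condition at all,
  contradicting the observed behavior the simulator is meant to emulate
  (FN worst at D/L 0.4, and growing with range width).

Center jitter (s.d. `0.05·D` per axis), occasional spurious detections
placed off-tumor (rate 0.05), and a confidence score decreasing in the
realized localization error complete the model. All simulator defaults were
fixed once from those qualitative shapes and are deliberately not tuned.

## Experiments, seeds and problem sizes

`run_dl_sweep()` covers fixed D/L 0.4–1.1 (0.1 steps; 1.1 is annotated in
reports as the box-smaller-than-tumor regime) and
`run_distributed_dl_experiment()` the ranges [0.6,1.0], [0.7,1.0],
[0.8,1.0], each over 3 splits × 3 runs. The default study size in the test
suite and the acceptance script is the 1/10-scale phantom set; with
annotation-level simulation the full sweep takes seconds on one core while
leaving ~150 test images per split — enough that the recall ordering of
interest exceeds its Monte-Carlo noise severalfold.

Every random step draws from an explicit seed; per-(stage, split,
condition, run) child seeds are derived from the master seed by stable
string hashing (`child_seed()`), so adding a condition never perturbs the
draws of existing ones, and the whole pipeline is a pure function of
(configuration, master seed).

## Numerical conventions and degenerate inputs

* Box squareness in `dl_of_box()` uses a relative tolerance (default 1e-6).
* `assign_dl_values()` with a degenerate range [a,a] equals the fixed
  condition a; a degenerate `detector_behavior` range likewise collapses to
  the fixed behavior.
* All-identical IoU samples have no two-class split and make
  `otsu_iou_threshold()` fail loudly rather than return an arbitrary cut.
* A split requires ≥5 cases per type; fewer cannot fill three disjoint
  ~20% partitions and errors immediately.
* An elimination stage that drops *all* training images errors rather than
  returning an empty set.

## Known limitations

* The simulator's linear 1/mean-D/L size response is a declared modeling
  choice; a real detector's response to annotation scale need not be
  linear, and absolute phantom metrics do not transfer to clinical data.
* One annotated tumor per image is assumed throughout; multi-tumor
  matching (e.g. Hungarian assignment) and mAP-style multi-threshold
  evaluation are out of scope.
* The calibrated threshold on phantoms reflects the simulator's IoU
  distribution, not any clinical distribution; 0.375 is provided as a
  convention, not reproduced.
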