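---
title: "Methods: vertebra localization and standard-plane regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vertebra localization and standard-plane regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(spineplane)
```

## The problem

Intra-operative cone-beam CT volumes of the spine are acquired without a
reliable patient coordinate frame, so the anatomical standard planes of each
vertebra — axial, coronal and sagittal, mutually orthogonal and defined per
vertebra — must be recovered before the surgeon can use standard multiplanar
views. A volume may contain between one and ten vertebrae from the cervical,
thoracic or lumbar region. `spineplane` implements two pipelines for this
task and the infrastructure to train, test and compare them without access
to patient data.

Conventions used throughout: voxel indices are 0-based, world position =
index · spacing + origin (mm); patch-normalized coordinates map a continuous
index *t* to (*t* + 0.5)/*N*, half-open in [0, 1); plane triplets are stored
as two spanning vectors per plane with normal *n* = *u* × *v*, and the three
normals form a right-handed orthonormal basis (sagittal ≈ x, coronal ≈ y,
axial ≈ z).

## The detection-based pipeline

A single-shot volumetric detector in the YOLOv3 family
(`build_yolo3d()`). The backbone halves the resolution five times (five
stride-2 convolutions, one residual block per stage), so a 160³ patch
produces detection grids of 5³, 10³ and 20³ cells — with a single cubic
anchor per scale that is 5³ + 10³ + 20³ = 9125 candidate predictions. Two
upsample-and-concatenate paths feed the finer heads. Every cell predicts
28 channels: 3 center offsets, 3 log extent ratios, 1 objectness logit,
3 class logits (cervical / thoracic / lumbar) and 18 spanning-vector
components (u, v for each plane).

*Why 28:* the detection-head channel count is the only place where the
parameter set admits no other decomposition — 3 + 3 + 1 + 3 + 18 = 28. An
alternative count of 29 circulating for this architecture cannot be
reconciled with the parameter set (no extra parameter is defined anywhere),
so the package implements 28. Nothing downstream depends on the count.

Anchors are 0.15, 0.11 and 0.07 of the patch edge. For the 160 mm field of
view these are 24, 17.6 and 11.2 mm: the largest lumbar extent (24 mm) over
the 160 mm patch is exactly 0.15, a typical thoracic size matches 0.11, and
cervical sizes (8–13 mm, normalized 0.05–0.08) sit at the 0.07 anchor. Each
ground-truth vertebra is assigned to the scale whose anchor has maximal
size-IoU with its box (positions ignored), and to the cell containing its
center; a cell collision keeps the larger vertebra and warns.

The loss is a weighted sum of seven terms: binary cross-entropy on
objectness at object cells (OL) and non-object cells (NOL), mean squared
error on the decoded box parameters (BL), class cross-entropy (CL), and the
per-plane spanning-vector mean squared errors (APL, CPL, SPL). Default
weights are OL = CL = APL = CPL = SPL = 1 and NOL = BL = 10. Numerical
conventions that the defaults fix:

* MSE terms are averaged over components and object cells (not summed), so
  magnitudes are resolution-independent; each plane term divides its six
  squared component errors by the 18 total spanning components, which keeps
  APL + CPL + SPL equal to the component-wise MSE of the whole triplet.
* Box loss is computed in decoded space (center = (σ(t) + cell)/G, extents
  = anchor · e^t, exponent clamped at 8), which makes the encode/decode
  round trip the identity and keeps BL in normalized patch units.
* Objectness and class terms use logits-based cross-entropy; class
  probabilities are independent logistics, as in the YOLOv3 lineage.

At inference the volume is resampled to the input size by trilinear
interpolation, min–max normalized, and decoded candidates pass three
filters: objectness ≥ 0.10, greedy per-class non-max suppression at IoU
0.15 with objectness as the score, then a class-probability threshold of
0.25 (`select_detections()`); the thresholds are the operating point found
by hyperparameter search and every one is configurable. NMS ties are broken
by score, then lexicographic center, so results are order-independent.
"Confidence" is raw objectness (class probability is thresholded
separately). NMS is per-class so that adjacent vertebrae of different
regions cannot suppress each other. Surviving detections are mapped back to
world mm; regressed spanning vectors are projected to the nearest rotation
(SVD orthonormalization of the stacked normal matrix, det +1).

## The segmentation-based pipeline

The reference approach segments, for every vertebra, three flat cylinders
whose base normals equal the standard-plane normals (one channel per plane
family, label value = class). Cylinder geometry: diameter d = 4 h; one
(d, h) per volume, chosen as d = min(0.9 · minimum pairwise center
distance, 1.5 · median extent) — the non-overlap constraint leaves the rule
open, and this choice guarantees disjoint cylinders across vertebrae while
keeping them as large as possible (single vertebra: d = 1.5 · extent).
Planes of the *same* vertebra may overlap across channels.

`build_segnet()` is a plain 3D U-Net (stride-2 downsampling,
nearest-neighbor upsampling, skip connections; configurable depth/width)
mapping one input channel to 3 channels × 4 class logits. The loss is the
sum over channels of cross-entropy plus Dice loss (1 − soft Dice averaged
over the three foreground classes, smoothing 1e-5 so absent classes score
1), with unit weights. Softmax is over the 4 classes within each channel;
a binary-per-class variant was rejected because the label sets within one
channel are mutually exclusive by construction. Training uses mini-batch
gradient descent with momentum 0.99 (coefficient unstated upstream; 0.99 is
the nnU-Net convention).

Post-processing (`segplane_extract()`): DBSCAN over the foreground voxel
coordinates of each channel (eps = 2 voxels, min_samples = 10 — unstated
upstream, exposed in the configuration; a core point counts itself, the
scikit-learn convention), discarding noise voxels; per-channel size
filtering at half the largest cluster (θ = n_max/2); grouping of
axial/coronal/sagittal clusters into vertebra triples by pairwise voxel
bounding-box intersection, ambiguities resolved by nearest centroids and
incomplete triples dropped with a warning; the vertebra center is the mean
of the three cluster centroids; each plane normal is the smallest-variance
eigenvector of the cluster's voxel covariance (for a flat cylinder the
variance along the normal, h²/12, is far below the radial variance, d²/16).
PCA normal signs are arbitrary, so they are canonicalized to a positive dot
product with the most-aligned volume axis; all reported angle errors use
the unoriented convention arccos |n₁ · n₂| for the same reason. DBSCAN
visits voxels in ascending linear-index order, making the whole chain
deterministic.

Whole-volume inference runs the network in sliding windows with 50 %
overlap and averages logits before the per-channel argmax.

## Augmentation

Seven on-the-fly transforms, each fired by an independent draw: rotation
and/or scaling (p = 0.16 rotation only, 0.16 scaling only, 0.08 both;
angles U(−30°, 30°) per axis, scale U(0.7, 1.4)), additive Gaussian noise
(p = 0.15, variance U(0, 0.1) on intensities normalized to [0, 1]),
Gaussian blur (p = 0.2, σ U(0.5, 1.5) voxels), brightness (p = 0.15, factor
U(0.7, 1.3)), contrast (p = 0.15, factor U(0.65, 1.5), clipped to the
pre-transform range), low-resolution simulation (p = 0.25, down-sampling
factor U(1, 2) nearest-neighbor, cubic upsampling), and gamma (p = 0.15,
γ U(0.7, 1.5) on the rescaled [0, 1] range). The application order is fixed
as listed, for reproducibility; rotation and scaling share one resampling
(rotation about the patch center, out-of-field voxels filled with the
volume minimum; volumes trilinear, masks nearest-neighbor). Geometric
transforms update annotation centers, the axis-aligned extents (bounding
box of the rotated box, |R|·e), and the spanning vectors. `augment_plan()`
separates the random draws from the application so firing statistics can be
audited and plans replayed.

## The phantom generator

`phantom_sample()` builds seeded synthetic volumes with complete ground
truth. Geometry: a contiguous stretch of the spine (window centered on an
anchor vertebra; anchor-class probabilities 0.35/0.25/0.40 compensate the
thoracic segment being half of the 24-vertebra spine, keeping the three
class frequencies near 1/3 over many phantoms); class-dependent cubic
extents (cervical 8–13 mm, thoracic 17–24 mm, lumbar 21–24 mm);
face-to-face gaps U(2, 5) mm (intervertebral disc heights); stacking along
a smoothly curving axis (small random bends per step) with per-vertebra
plane triplets equal to the local stacking frame perturbed by a rotation of
at most 15° about a random axis; axis-aligned boxes are kept disjoint by
construction and chains that do not fit the field of view are truncated
with a warning. Rendering: an oblate ellipsoid body (semi-axes
0.48/0.42/0.33 of the extent — vertebral bodies are wider than tall, which
is also what makes the orientation observable) plus a posterior arc,
over a soft-tissue background with a gentle random gradient; Gaussian noise
(default sd 0.03 on the ~[0, 1] intensity scale, a mildly noisy
reconstruction) and optional bright streak artifacts emulating metal
implants (severity 0 by default; artifacts are a documented failure mode,
not part of the baseline conditions). Default geometry: at the native 512³
grid the spacing is 0.313 mm (160 mm field of view); the default spacing for
other grid sizes preserves that 160 mm field.

What the phantoms do *not* emulate: real vertebral shape (processes,
endplates, cortical/trabecular texture), realistic attenuation values and
reconstruction artifacts, pathology, or neighboring anatomy. Passing the
phantom suites therefore demonstrates that the algorithms and their
plumbing are correct — encode/decode consistency, loss behavior, the full
post-processing chain, metric definitions — not that the trained weights
transfer to clinical data.

## The scaled-down study

The full-scale configuration (160³ patch, width 1.0) is impractical for a
routine CPU test run, so the end-to-end suites train at reduced size: a 64³
patch with width multiplier 0.25, 200 training and 50 held-out phantoms
with 1–4 vertebrae each. Scaling the patch preserves the *millimetre*
geometry of the detector rather than the normalized one: the 160³/160 mm
configuration has detection cells of 32/16/8 mm and anchors of
24/17.6/11.2 mm, so the 64³ patch covers a 64 mm field of view (≈1 mm
spacing) with anchors 0.375/0.275/0.175 — the same cell and anchor sizes in
mm, and the same class-to-scale assignment. (Keeping normalized anchors
while quadrupling the cell size in mm would instead make adjacent
thoracic/lumbar vertebrae, 24–29 mm apart, systematically share responsible
cells — a degenerate encoding, not a harder version of the same task.)
Training uses Adam with a decaying four-phase schedule (2e-3 for 250
steps, 5e-4 for 150, 1e-4 for 150, 2e-5 for 50; batch 2, weight decay
1e-4, global gradient-norm clipping at 10 to guard the box-extent
exponential) chosen for convergence within a short CPU budget; the
full-scale default remains the conservative lr 1e-5 / weight decay 1e-4
used for long training runs. The convolution path of the engine runs in
single precision (im2col + BLAS sgemm) — the standard choice for
convolutional networks — while normalization, losses and the optimizer
stay in double precision. Detection-head
biases are initialized to the objectness prior (logit of 0.01) and to the
canonical anatomical frame for the plane components; weights use
Kaiming-style initialization. Per-channel spatial normalization (one
sample's statistics, learnable affine) is used inside convolution blocks:
it is deterministic at inference, has no train/eval discrepancy, and needs
no running statistics at batch size 2.

## Evaluation metrics

Predictions are matched to ground truth greedily by ascending center
distance, a pair being valid only when the predicted center lies inside the
ground-truth box (the matching criterion is not fixed upstream; this one is
parameter-free and pipeline-agnostic). Detection accuracy is
TP/(TP + FP + FN) — detection has no true negatives — with error rate its
complement. Classification metrics are computed over matched pairs only
(3×3 confusion, macro-averaged recall/precision). Localization reports the
center-to-center distance and the distances from the predicted center to
each ground-truth plane; d̄_sp averages the coronal and sagittal distances,
by default per matched pair (the per-plane aggregation — mean of the two
plane-level means — is also available, since the published tables are
ambiguous between the two). Orientation reports per-plane unoriented normal
angle errors and their per-pair mean.

## Known limitations

* The conv engine is CPU-only and single-threaded beyond BLAS; full-scale
  training (160³, width 1.0, ~1000 epochs) is out of reach here and the
  package makes no claim about clinical-data performance.
* Oriented (rotated) bounding boxes are out of scope; boxes are
  axis-aligned and oversized boxes of adjacent vertebrae can interact in
  NMS, which is precisely why the class-probability threshold exists.
* One anchor per scale: vertebra-size variability within a region is
  absorbed by the extent regression, not by anchor diversity.
* The MetaImage reader supports the uncompressed single-file and
  header+raw layouts only.
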