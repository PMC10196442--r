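# spineplane

Vertebra localization and anatomical standard-plane regression in 3D
cone-beam CT (CBCT) volumes, in pure R.

Intra-operative CBCT volumes of the spine carry no reliable patient frame:
before a surgeon can read the images in standard multiplanar views, the
axial, coronal and sagittal standard planes of every vertebra (up to ten per
volume) have to be found and the view aligned — today a manual step.
`spineplane` implements and compares two automatic pipelines for this task,
with a seeded synthetic spine-phantom generator so the whole system can be
trained and tested without patient data. It is aimed at researchers in
medical image analysis who want a transparent, dependency-light reference
implementation of both approaches.

## The two algorithms

**Detection-based.** A volumetric single-shot detector in the YOLOv3 family.
A 160³-voxel patch passes a backbone with five stride-2 stages (one residual
block each) and three detection heads at grids of 5³, 10³ and 20³ cells
(input/32, /16, /8) — with one cubic anchor per scale (0.15, 0.11, 0.07 of
the patch, matching lumbar/thoracic/cervical vertebra sizes) that is
5³ + 10³ + 20³ = 9125 candidate predictions. Each cell regresses, for one
vertebra: the box (x, y, z, w, h, d, normalized), an objectness score, class
probabilities *c* ∈ {cervical, thoracic, lumbar}, and the two spanning
vectors **u**, **v** of each standard plane (18 components; the plane normal
is **u** × **v**). Training minimizes

    L = w_OL·OL + w_NOL·NOL + w_BL·BL + w_CL·CL + w_APL·APL + w_CPL·CPL + w_SPL·SPL

with objectness / no-objectness cross-entropy, box MSE, class cross-entropy
and per-plane spanning-vector MSE, weighted w_OL = w_CL = w_APL = w_CPL =
w_SPL = 1 and w_NOL = w_BL = 10. Inference keeps candidates with objectness
≥ 0.10, applies per-class 3D non-max suppression at IoU 0.15 and drops
survivors with maximum class probability < 0.25; regressed spanning vectors
are projected to the nearest orthonormal triplet (SVD).

**Segmentation-based (reference).** A 3D U-Net segments, in three output
channels, flat cylinders centered on each vertebra whose base normals equal
the standard-plane normals (diameter d = 4·h, one size per volume chosen so
cylinders of different vertebrae stay disjoint; label value = class), with
loss L = CE + Dice summed over channels. Plane parameters are then recovered
by DBSCAN clustering of each channel, discarding clusters below half the
largest cluster size, grouping intersecting axial/coronal/sagittal clusters
into vertebrae, averaging the three cluster centroids for the center, and
taking each cluster's smallest-variance principal component as the plane
normal.

Both networks run on a compact BLAS-backed 3D convolution engine (Rcpp +
Armadillo, analytic gradients, Adam / momentum SGD) — no external
deep-learning runtime, CPU only.

## Worked example

Generate a phantom with complete ground truth and run the segmentation
post-processing chain on the ground-truth cylinder masks (no network —
this isolates the deterministic part of the pipeline):

```r
library(spineplane)

spec <- phantom_spec()            # 160^3 voxels over a 160 mm field of view
ph   <- phantom_sample(spec, seed = 2)
length(ph$annotations)            # vertebrae in this phantom

pred <- segplane_extract(ph$masks, eps = 2, min_samples = 10)
rep  <- evaluate_predictions(pred, ph$annotations)
rep$detection
rep$orientation$summary
rep$localization$summary
```

```
[1] 5
  accuracy error_rate     recall  precision
         1          0          1          1
        metric      mean        sd
1    angle_asp 0.9196240 0.7319759
2    angle_csp 0.9341917 0.7851508
3    angle_ssp 1.1816851 0.8376006
4 angle_sp_bar 1.0118336 0.6806538
    metric       mean         sd
1     d_cc 0.05794234 0.04335649
2    d_asp 0.01467560 0.01142892
3    d_csp 0.02946573 0.03259190
4    d_ssp 0.04077374 0.03809135
5 d_sp_bar 0.03511974 0.03132993
```

All five vertebrae are recovered (detection accuracy 1), centers agree with
the ground truth to a few hundredths of a millimetre and plane normals to
about one degree — the post-processing chain is exact up to voxel
discretization.

The detection pipeline end to end, at a reduced scale that trains in
minutes on one CPU core (200 phantoms at 64³, width multiplier 0.25):

```r
res <- run_scaled_study(seed = 42)   # ~10 min on one core
res$report$detection["recall"]       # fraction of vertebrae found
mean(res$report$orientation$a_sp_bar)  # mean plane-normal error (degrees)
```

A shell front end for the full workflow (simulate / train-yolo / train-seg /
infer-yolo / infer-seg / evaluate) is installed at
`system.file("cli", "spineplane", package = "spineplane")`; volumes are
NIfTI or MetaImage, annotations a small JSON schema shared by ground truth
and both pipelines.

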