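Package: spineplane
Title: Vertebra Localization and Standard-Plane Regression in 3D CBCT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Localizes vertebral bodies and regresses their anatomical standard
    planes (axial, coronal, sagittal) in intra-operative cone-beam CT volumes.
    Implements two complementary pipelines: a single-shot volumetric detector in
    the YOLOv3 family that regresses, per vertebra, an axis-aligned bounding
    box, a spinal-region class and the spanning vectors of the three standard
    planes; and a segmentation-based reference pipeline that segments flat
    plane-aligned cylinder labels with a 3D U-Net and recovers plane parameters
    by DBSCAN clustering, cluster-size filtering, centroid averaging and
    principal component analysis. Ships a seeded synthetic spine-phantom
    generator with complete ground truth, the on-the-fly training augmentation
    suite, 3D box IoU and non-max suppression, and detection, classification,
    localization and orientation metrics. Neural networks run on a compact
    BLAS-backed 3D convolution engine with analytic gradients, so the whole
    system trains and infers on a CPU without external deep-learning runtimes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
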