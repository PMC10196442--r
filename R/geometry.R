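# Deterministic geometric core shared by both pipelines: plane triplets,
# axis-aligned 3D boxes, distances/angles, IoU and non-max suppression.

norm3 <- function(v) sqrt(sum(v * v))

unit3 <- function(v) {
  n <- norm3(v)
  if (!is.finite(n) || n < 1e-12) stop("cannot normalize a (near-)zero vector")
  v / n
}

#' Construct a standard-plane triplet from spanning vectors
#'
#' A vertebra's standard planes are stored as two spanning vectors \code{u},
#' \code{v} per plane; the plane normal is the cross product \code{u x v}.
#' By anatomical convention the axial normal points cranio-caudally, the
#' coronal normal antero-posteriorly and the sagittal normal left-right, and
#' the three normals form a right-handed orthonormal basis.
#'
#' @param axial,coronal,sagittal each a list with numeric length-3 elements
#'   \code{u} and \code{v}.
#' @return An object of class \code{plane_triplet}: a list with elements
#'   \code{axial}, \code{coronal}, \code{sagittal}, each holding \code{u},
#'   \code{v} and the derived normal \code{n}.
#' @export
plane_triplet <- function(axial, coronal, sagittal) {
  mk <- function(p) {
    u <- as.numeric(p$u); v <- as.numeric(p$v)
    stopifnot(length(u) == 3, length(v) == 3, all(is.finite(c(u, v))))
    list(u = u, v = v, n = cross3(u, v))
  }
  structure(list(axial = mk(axial), coronal = mk(coronal), sagittal = mk(sagittal)),
            class = "plane_triplet")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Plane normals of a triplet as a 3 x 3 matrix
#'
#' @param tp a \code{plane_triplet}.
#' @return Matrix with columns \code{axial}, \code{coronal}, \code{sagittal}
#'   holding the (not necessarily unit) plane normals.
#' @export
triplet_normals <- function(tp) {
  m <- cbind(axial = tp$axial$n, coronal = tp$coronal$n, sagittal = tp$sagittal$n)
  rownames(m) <- c("x", "y", "z")
  m
}

# Build a plane_triplet from a rotation matrix whose columns are the
# sagittal (x), coronal (y) and axial (z) normals. Spanning vectors follow
# the right-handed convention u x v = n for every plane.
triplet_from_axes <- function(R) {
  xs <- R[, 1]; yc <- R[, 2]; za <- R[, 3]
  plane_triplet(
    axial    = list(u = xs, v = yc), # x cross y = z
    coronal  = list(u = za, v = xs), # z cross x = y
    sagittal = list(u = yc, v = za)  # y cross z = x
  )
}

#' Orthonormalize a (possibly inexact) plane triplet
#'
#' Regressed spanning vectors are generally not exactly orthonormal. The
#' three raw plane normals are stacked into a 3 x 3 matrix (columns sagittal,
#' coronal, axial) and projected onto the rotation group via singular value
#' decomposition; the nearest rotation (in Frobenius norm) defines the
#' orthonormalized triplet, whose spanning vectors are rebuilt from the
#' rotated axes. The operation is idempotent.
#'
#' @param tp a \code{plane_triplet} (or a bare list with the same shape).
#' @return An orthonormal \code{plane_triplet}.
#' @export
orthonormalize_triplet <- function(tp) {
  if (!inherits(tp, "plane_triplet")) tp <- plane_triplet(tp$axial, tp$coronal, tp$sagittal)
  M <- cbind(unit_or_na(tp$sagittal$n), unit_or_na(tp$coronal$n), unit_or_na(tp$axial$n))
  if (anyNA(M)) stop("degenerate triplet: a plane's spanning vectors are collinear or zero")
  sv <- svd(M)
  if (sv$d[3] < 1e-8 * sv$d[1]) stop("degenerate triplet: normal matrix is rank deficient")
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) R <- sv$u %*% diag(c(1, 1, -1)) %*% t(sv$v)
  triplet_from_axes(R)
}

unit_or_na <- function(v) {
  n <- norm3(v)
  if (!is.finite(n) || n < 1e-12) rep(NA_real_, 3) else v / n
}

#' Check orthonormality of a plane triplet
#'
#' @param tp a \code{plane_triplet}.
#' @param tol tolerance on unit norms and pairwise dot products.
#' @return \code{TRUE} when the three normals form a right-handed
#'   orthonormal basis within \code{tol}.
#' @export
is_orthonormal_triplet <- function(tp, tol = 1e-6) {
  M <- triplet_normals(tp)
  M <- cbind(M[, "sagittal"], M[, "coronal"], M[, "axial"])
  ok <- all(abs(colSums(M^2) - 1) < tol) &&
    all(abs(crossprod(M)[upper.tri(diag(3))]) < tol)
  ok && det(M) > 0
}

#' Unoriented angle between two plane normals, in degrees
#'
#' Planes are unoriented, so the sign of a normal carries no information;
#' the error is \code{acos(|n1 . n2|)} for unit normals, in [0, 90] degrees.
#'
#' @param n_pred,n_gt nonzero numeric length-3 vectors.
#' @return Angle error in degrees.
#' @export
plane_angle_error <- function(n_pred, n_gt) {
  a <- unit3(as.numeric(n_pred)); b <- unit3(as.numeric(n_gt))
  d <- min(1, abs(sum(a * b)))
  acos(d) * 180 / pi
}

#' Unsigned point-to-plane distance
#'
#' @param p point (length-3 numeric, mm).
#' @param plane_point any point on the plane (mm).
#' @param n plane normal (nonzero).
#' @return Nonnegative distance in mm.
#' @export
point_to_plane_distance <- function(p, plane_point, n) {
  nh <- unit3(as.numeric(n))
  abs(sum((as.numeric(p) - as.numeric(plane_point)) * nh))
}

#' Axis-aligned 3D box
#'
#' @param center,extent length-3 numerics. Extents must be strictly positive.
#' @param frame either \code{"normalized"} (all six values in [0, 1],
#'   relative to the network patch) or \code{"world"} (mm).
#' @return An object of class \code{box3d}.
#' @export
box3d <- function(center, extent, frame = c("normalized", "world")) {
  frame <- match.arg(frame)
  center <- as.numeric(center); extent <- as.numeric(extent)
  stopifnot(length(center) == 3, length(extent) == 3, all(extent > 0),
            all(is.finite(c(center, extent))))
  if (frame == "normalized" && (any(center < 0) || any(center > 1) || any(extent > 1)))
    stop("normalized box values must lie in [0, 1]")
  structure(list(center = center, extent = extent, frame = frame), class = "box3d")
}

#' Intersection-over-union of two axis-aligned 3D boxes
#'
#' @param a,b \code{box3d} objects in the same frame.
#' @return IoU in [0, 1].
#' @export
box_iou3d <- function(a, b) {
  stopifnot(inherits(a, "box3d"), inherits(b, "box3d"))
  if (!identical(a$frame, b$frame)) stop("boxes are in different frames")
  iou3d_vec(a$center, a$extent, matrix(b$center, 1), matrix(b$extent, 1))
}

# IoU of one box against many (centers/extents as n x 3 matrices).
iou3d_vec <- function(c1, e1, C, E) {
  lo1 <- c1 - e1 / 2; hi1 <- c1 + e1 / 2
  LO <- sweep(C, 2, e1 * 0, "+") - E / 2  # C - E/2
  HI <- C + E / 2
  ix <- pmax(0, pmin(hi1[1], HI[, 1]) - pmax(lo1[1], LO[, 1]))
  iy <- pmax(0, pmin(hi1[2], HI[, 2]) - pmax(lo1[2], LO[, 2]))
  iz <- pmax(0, pmin(hi1[3], HI[, 3]) - pmax(lo1[3], LO[, 3]))
  inter <- ix * iy * iz
  v1 <- prod(e1); v2 <- E[, 1] * E[, 2] * E[, 3]
  inter / (v1 + v2 - inter)
}

#' Greedy per-class non-max suppression of 3D detections
#'
#' Detections are visited in descending score order (ties broken by
#' lexicographic center coordinates, so the result is deterministic); a
#' detection is suppressed when its IoU with an already kept detection of the
#' same class exceeds \code{iou_threshold}. Boxes of different classes never
#' suppress each other, mirroring the YOLOv3 convention: adjacent vertebrae
#' of different spinal regions must not cancel each other out.
#'
#' @param dets a detections data frame (see \code{\link{decode_yolo_output}})
#'   with box columns \code{cx,cy,cz,ex,ey,ez}, a \code{score} column and a
#'   \code{class_id} column.
#' @param iou_threshold suppress when pairwise IoU exceeds this value.
#' @return The surviving rows, sorted by decreasing score.
#' @export
nms3d <- function(dets, iou_threshold) {
  if (nrow(dets) == 0) return(dets)
  stopifnot(all(c("cx", "cy", "cz", "ex", "ey", "ez", "score", "class_id") %in% names(dets)))
  ord <- order(-dets$score, dets$cx, dets$cy, dets$cz)
  d <- dets[ord, , drop = FALSE]
  C <- as.matrix(d[, c("cx", "cy", "cz")])
  E <- as.matrix(d[, c("ex", "ey", "ez")])
  keep <- logical(nrow(d))
  alive <- rep(TRUE, nrow(d))
  for (i in seq_len(nrow(d))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    if (i == nrow(d)) break
    rest <- which(alive & seq_len(nrow(d)) > i & d$class_id == d$class_id[i])
    if (!length(rest)) next
    iou <- iou3d_vec(C[i, ], E[i, ], C[rest, , drop = FALSE], E[rest, , drop = FALSE])
    alive[rest[iou > iou_threshold]] <- FALSE
  }
  d[keep, , drop = FALSE]
}

#' Single vertebra annotation
#'
#' @param class_id spinal region: 1 cervical, 2 thoracic, 3 lumbar.
#' @param center_mm,extent_mm vertebra box center and extents in world mm.
#' @param planes a \code{plane_triplet} (orthonormalized on construction).
#' @return An object of class \code{vertebra_annotation}.
#' @export
vertebra_annotation <- function(class_id, center_mm, extent_mm, planes) {
  class_id <- as.integer(class_id)
  stopifnot(class_id %in% 1:3, length(center_mm) == 3, length(extent_mm) == 3,
            all(extent_mm > 0))
  structure(list(class_id = class_id,
                 center_mm = as.numeric(center_mm),
                 extent_mm = as.numeric(extent_mm),
                 planes = orthonormalize_triplet(planes)),
            class = "vertebra_annotation")
}

# --- coordinate conversions -------------------------------------------------
# Voxel indices are 0-based; world position = index * spacing + origin
# (voxel centers on the integer lattice). Patch-normalized coordinates map
# the continuous index t to (t + 0.5) / N, half-open in [0, 1).

#' Convert world mm to patch-normalized coordinates
#'
#' @param p world point(s), length-3 vector or n x 3 matrix (mm).
#' @param dim volume size in voxels per axis (length 1 or 3).
#' @param spacing isotropic voxel spacing (mm).
#' @param origin world position of voxel (0,0,0), mm.
#' @return Normalized coordinates in [0, 1), same shape as \code{p}.
#' @export
norm_from_world <- function(p, dim, spacing, origin = c(0, 0, 0)) {
  dim <- rep(dim, length.out = 3)
  if (is.matrix(p)) {
    t(apply(p, 1, function(r) ((r - origin) / spacing + 0.5) / dim))
  } else {
    ((as.numeric(p) - origin) / spacing + 0.5) / dim
  }
}

#' Convert patch-normalized coordinates to world mm
#'
#' @inheritParams norm_from_world
#' @param q normalized point, length-3.
#' @return World coordinates in mm.
#' @export
world_from_norm <- function(q, dim, spacing, origin = c(0, 0, 0)) {
  dim <- rep(dim, length.out = 3)
  (as.numeric(q) * dim - 0.5) * spacing + origin
}
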