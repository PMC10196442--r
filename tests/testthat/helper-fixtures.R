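# Shared fixtures: small phantoms and geometric helpers built in code.

# identity plane triplet (axial normal = +z)
identity_triplet <- function() {
  plane_triplet(axial = list(u = c(1, 0, 0), v = c(0, 1, 0)),
                coronal = list(u = c(0, 0, 1), v = c(1, 0, 0)),
                sagittal = list(u = c(0, 1, 0), v = c(0, 0, 1)))
}

# triplet rotated by R
rotated_triplet <- function(R, tp = identity_triplet()) {
  rot <- function(p) list(u = as.numeric(R %*% p$u), v = as.numeric(R %*% p$v))
  plane_triplet(axial = rot(tp$axial), coronal = rot(tp$coronal),
                sagittal = rot(tp$sagittal))
}

rot_axis <- function(axis, deg) spineplane:::rotation_about_axis(axis, deg * pi / 180)

# scaled-down study configuration: 64^3 patch over a 64 mm field of view
# (1 mm spacing), anchors at the full-scale mm sizes (24 / 17.6 / 11.2 mm)
scaled_yolo_config <- function(width = 0.25) {
  yolo_config(input_size = 64L, width_multiplier = width,
              anchors = c(0.15, 0.11, 0.07) * 2.5)
}

scaled_phantom_spec <- function(n_vertebrae = c(1L, 4L), ...) {
  phantom_spec(grid_size = 64L, spacing = 0.313 * 512 / 160,
               n_vertebrae = n_vertebrae, ...)
}

# independent voxel-counting IoU oracle: count voxel centers of a fixed
# n^3 grid over the unit cube inside each box. Exact for boxes whose faces
# lie on the grid lattice (see random_lattice_box).
voxel_iou_oracle <- function(c1, e1, c2, e2, n = 100L) {
  axes <- (seq_len(n) - 0.5) / n
  inbox <- function(ctr, ext) {
    outer(outer(axes > ctr[1] - ext[1] / 2 & axes < ctr[1] + ext[1] / 2,
                axes > ctr[2] - ext[2] / 2 & axes < ctr[2] + ext[2] / 2, "&"),
          axes > ctr[3] - ext[3] / 2 & axes < ctr[3] + ext[3] / 2, "&")
  }
  A <- inbox(c1, e1); B <- inbox(c2, e2)
  uni <- sum(A | B)
  if (uni == 0) 0 else sum(A & B) / uni
}

# random box inside [0,1] with all faces on the 1/n lattice
random_lattice_box <- function(min_ext = 4, max_ext = 40, n = 100) {
  e <- sample(seq(min_ext, max_ext, by = 2), 3, replace = TRUE)
  lo <- vapply(e, function(ei) sample(0:(n - ei), 1), 0)
  list(center = (lo + e / 2) / n, extent = e / n)
}

# scalar interval-overlap IoU written from scratch for the NMS oracle
# (kept independent of the package's vectorized implementation; its own
# correctness is pinned by the voxel-counting comparison above)
iou_plain <- function(c1, e1, c2, e2) {
  inter <- 1
  for (a in 1:3) {
    lo <- max(c1[a] - e1[a] / 2, c2[a] - e2[a] / 2)
    hi <- min(c1[a] + e1[a] / 2, c2[a] + e2[a] / 2)
    if (hi <= lo) return(0)
    inter <- inter * (hi - lo)
  }
  inter / (prod(e1) + prod(e2) - inter)
}

# independent greedy-NMS oracle (per class, score then lexicographic ties)
nms_oracle <- function(df, thr, iou_fun = iou_plain) {
  ord <- order(-df$score, df$cx, df$cy, df$cz)
  df <- df[ord, ]
  kept <- list()
  for (i in seq_len(nrow(df))) {
    ok <- TRUE
    for (k in kept) {
      if (k$class_id != df$class_id[i]) next
      iou <- iou_fun(c(k$cx, k$cy, k$cz), c(k$ex, k$ey, k$ez),
                     as.numeric(df[i, c("cx", "cy", "cz")]),
                     as.numeric(df[i, c("ex", "ey", "ez")]))
      if (iou > thr) { ok <- FALSE; break }
    }
    if (ok) kept[[length(kept) + 1]] <- as.list(df[i, ])
  }
  do.call(rbind, lapply(kept, as.data.frame))
}

random_boxes_df <- function(n) {
  rows <- lapply(seq_len(n), function(i) {
    b <- random_lattice_box(6, 40)
    data.frame(cx = b$center[1], cy = b$center[2], cz = b$center[3],
               ex = b$extent[1], ey = b$extent[2], ez = b$extent[3])
  })
  df <- do.call(rbind, rows)
  df$score <- round(runif(n), 3)
  df$class_id <- sample(1:3, n, replace = TRUE)
  df
}
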