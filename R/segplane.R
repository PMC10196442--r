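# Segmentation-based reference pipeline: flat cylinder labels aligned with
# the standard planes, a 3-channel segmentation network, the combined
# cross-entropy + Dice loss, and the DBSCAN -> cluster filter -> grouping ->
# centroid / PCA plane-parameter extraction.

#' Cylinder size for plane labels
#'
#' Each standard plane of a vertebra is represented by a flat cylinder whose
#' base normal equals the plane normal, with diameter d = 4 h. One (d, h)
#' pair is used for the whole volume and must keep cylinders of distinct
#' vertebrae disjoint, so d is chosen as
#' \code{min(0.9 * min pairwise center distance, 1.5 * median extent)}
#' (for a single vertebra: 1.5 times its extent).
#'
#' @param annotations list of \code{\link{vertebra_annotation}}.
#' @param min_gap additional separation (mm) guaranteed between cylinders of
#'   adjacent vertebrae. Disjointness alone is not enough when the masks are
#'   later clustered density-based: clusters closer than the DBSCAN radius
#'   merge, so mask generation for that pipeline should pass
#'   \code{(eps + 1) * spacing}.
#' @return List with \code{d} and \code{h} in mm (class \code{cylinder_spec}).
#' @export
choose_cylinder_size <- function(annotations, min_gap = 0) {
  stopifnot(length(annotations) >= 1)
  med_ext <- stats::median(vapply(annotations, function(a) mean(a$extent_mm), 0))
  if (length(annotations) == 1) {
    d <- 1.5 * med_ext
  } else {
    ctr <- t(vapply(annotations, function(a) a$center_mm, numeric(3)))
    dd <- as.matrix(stats::dist(ctr))
    mind <- min(dd[upper.tri(dd)])
    d <- min(0.9 * mind, mind - min_gap, 1.5 * med_ext)
  }
  structure(list(d = d, h = d / 4), class = "cylinder_spec")
}

#' Plane-channel mask container
#'
#' @param axial,coronal,sagittal 3D label arrays (0 background, otherwise the
#'   class value of the vertebra the voxel belongs to).
#' @param spacing,origin voxel geometry (mm).
#' @return A \code{plane_channel_masks} list.
#' @export
plane_channel_masks <- function(axial, coronal, sagittal, spacing = 1,
                                origin = c(0, 0, 0)) {
  stopifnot(identical(dim(axial), dim(coronal)), identical(dim(axial), dim(sagittal)))
  structure(list(axial = axial, coronal = coronal, sagittal = sagittal,
                 spacing = spacing, origin = origin),
            class = "plane_channel_masks")
}

#' Rasterize standard-plane cylinders into 3-channel voxel labels
#'
#' A voxel v belongs to vertebra i's plane-p cylinder when
#' \code{|(v - c_i) . n_p| <= h/2} and its radial distance from the cylinder
#' axis is at most d/2. Each channel holds one plane family; overlapping
#' cylinders of the same vertebra across channels are expected and allowed,
#' while the cylinder size guarantees disjointness across vertebrae.
#'
#' @param annotations list of \code{\link{vertebra_annotation}}.
#' @param spec a \code{\link{choose_cylinder_size}} result.
#' @param dim volume size (voxels, length 1 or 3).
#' @param spacing,origin voxel geometry (mm).
#' @return A \code{\link{plane_channel_masks}} object.
#' @export
rasterize_plane_cylinders <- function(annotations, spec, dim, spacing = 1,
                                      origin = c(0, 0, 0)) {
  dim <- rep(dim, length.out = 3)
  ch <- lapply(1:3, function(i) array(0, dim))
  names(ch) <- c("axial", "coronal", "sagittal")
  r <- spec$d / 2
  half_h <- spec$h / 2
  reach <- sqrt(r^2 + half_h^2)
  clipped <- FALSE
  for (a in annotations) {
    ci <- (a$center_mm - origin) / spacing  # continuous 0-based index
    rad <- reach / spacing
    lo <- floor(ci - rad); hi <- ceiling(ci + rad)
    if (any(lo < 0) || any(hi > dim - 1)) clipped <- TRUE
    lo <- pmax(lo, 0); hi <- pmin(hi, dim - 1)
    if (any(lo > hi)) next
    gx <- lo[1]:hi[1]; gy <- lo[2]:hi[2]; gz <- lo[3]:hi[3]
    g <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
    rel <- sweep(g * spacing, 2, a$center_mm - origin)  # voxel mm - center mm
    for (p in c("axial", "coronal", "sagittal")) {
      n <- unit3(a$planes[[p]]$n)
      axial_d <- as.numeric(rel %*% n)
      rad2 <- rowSums(rel^2) - axial_d^2
      inside <- abs(axial_d) <= half_h & rad2 <= r^2
      if (any(inside)) {
        idx <- g[inside, , drop = FALSE] + 1
        ch[[p]][cbind(idx[, 1], idx[, 2], idx[, 3])] <- a$class_id
      }
    }
  }
  if (clipped) warning("cylinder extends beyond the volume; clipped")
  plane_channel_masks(ch$axial, ch$coronal, ch$sagittal, spacing, origin)
}

# --- segmentation network ---------------------------------------------------

#' Build the 3-channel plane-segmentation U-Net
#'
#' An encoder-decoder with skip connections mapping a 1-channel patch to
#' three output channels (axial / coronal / sagittal) of 4 class logits each
#' (background + cervical/thoracic/lumbar). Downsampling uses stride-2
#' convolutions; upsampling is nearest-neighbor followed by convolution.
#'
#' @param patch_size input edge length; must be divisible by 2^depth.
#' @param depth number of resolution levels below the input level.
#' @param width channels at the first level (doubled per level).
#' @param n_classes label classes per channel including background.
#' @param seed RNG seed for weight initialization.
#' @return A network handle; its output array is
#'   (patch, patch, patch, 3 * n_classes), interpreted as 3 channels x
#'   n_classes logits.
#' @export
build_segnet <- function(patch_size = 64L, depth = 3L, width = 16L,
                         n_classes = 4L, seed = NULL) {
  patch_size <- as.integer(patch_size)
  if (patch_size %% (2L^depth) != 0L) stop("patch_size must be divisible by 2^depth")
  nodes <- list()
  add <- function(...) nodes[[length(nodes) + 1]] <<- nn_node(...)
  wd <- function(l) as.integer(width * 2^l)
  prev <- ".input"
  for (l in seq_len(depth) - 1L) {
    add(paste0("enc", l, "a"), "conv", prev, k = 3, cout = wd(l))
    add(paste0("enc", l, "b"), "conv", paste0("enc", l, "a"), k = 3, cout = wd(l))
    add(paste0("down", l), "conv", paste0("enc", l, "b"), k = 3, stride = 2, cout = wd(l + 1))
    prev <- paste0("down", l)
  }
  add("bota", "conv", prev, k = 3, cout = wd(depth))
  add("botb", "conv", "bota", k = 3, cout = wd(depth))
  prev <- "botb"
  for (l in rev(seq_len(depth) - 1L)) {
    add(paste0("up", l), "upsample", prev)
    add(paste0("upc", l), "conv", paste0("up", l), k = 3, cout = wd(l))
    add(paste0("cat", l), "concat", c(paste0("upc", l), paste0("enc", l, "b")))
    add(paste0("dec", l, "a"), "conv", paste0("cat", l), k = 3, cout = wd(l))
    add(paste0("dec", l, "b"), "conv", paste0("dec", l, "a"), k = 3, cout = wd(l))
    prev <- paste0("dec", l, "b")
  }
  add("seg_out", "head", prev, k = 1, cout = 3L * n_classes)
  net <- new_network(nodes, outputs = "seg_out",
                     input_dim = c(rep(patch_size, 3), 1L), seed = seed,
                     cfg = list(patch_size = patch_size, depth = depth,
                                width = width, n_classes = n_classes))
  class(net) <- c("segnet", class(net))
  net
}

#' Segmentation loss: cross-entropy plus Dice, summed over channels
#'
#' Per plane channel the loss is \code{w_CE * CE + w_DC * DC}, where CE is
#' the multi-class softmax cross-entropy (mean over voxels) and DC is the
#' Dice loss, 1 minus the soft Dice coefficient averaged over the three
#' foreground classes. The total is the sum over the axial, coronal and
#' sagittal channels. Defaults: \code{w_CE = w_DC = 1}.
#'
#' @param logits array (X, Y, Z, 3 * n_classes) from the segmentation net.
#' @param masks a \code{\link{plane_channel_masks}} ground truth.
#' @param w_CE,w_DC term weights.
#' @param n_classes classes per channel including background.
#' @param grad also return the gradient with respect to the logits.
#' @return List with per-channel \code{CE} and \code{DC}, \code{total}, and
#'   optionally \code{grad}.
#' @export
seg_loss <- function(logits, masks, w_CE = 1, w_DC = 1, n_classes = 4L,
                     grad = FALSE) {
  dm <- dim(logits)
  stopifnot(dm[4] == 3 * n_classes)
  nvox <- prod(dm[1:3])
  CE <- DC <- numeric(3)
  g <- if (grad) array(0, dm)
  smooth <- 1e-5
  for (c3 in 1:3) {
    lab <- as.integer(list(masks$axial, masks$coronal, masks$sagittal)[[c3]])
    sl <- (c3 - 1) * n_classes + seq_len(n_classes)
    lg <- matrix(logits[, , , sl], ncol = n_classes)
    lg <- lg - apply(lg, 1, max)
    p <- exp(lg); p <- p / rowSums(p)
    y <- matrix(0, nvox, n_classes)
    y[cbind(seq_len(nvox), lab + 1L)] <- 1
    CE[c3] <- -sum(log(pmax(p[cbind(seq_len(nvox), lab + 1L)], 1e-12))) / nvox
    # soft Dice over foreground classes
    dice <- dnum <- dden <- numeric(n_classes - 1)
    for (k in 2:n_classes) {
      dnum[k - 1] <- 2 * sum(p[, k] * y[, k]) + smooth
      dden[k - 1] <- sum(p[, k]) + sum(y[, k]) + smooth
      dice[k - 1] <- dnum[k - 1] / dden[k - 1]
    }
    DC[c3] <- 1 - mean(dice)
    if (grad) {
      dLdp <- (p - y) * 0  # gradient w.r.t. softmax probabilities (Dice part)
      nfg <- n_classes - 1
      for (k in 2:n_classes) {
        dLdp[, k] <- -(2 * y[, k] * dden[k - 1] - dnum[k - 1]) / dden[k - 1]^2 / nfg * w_DC
      }
      # chain through softmax: dL/dz_i = p_i * (dL/dp_i - sum_j p_j dL/dp_j)
      srow <- rowSums(dLdp * p)
      gz <- p * (dLdp - srow)
      gz <- gz + w_CE * (p - y) / nvox
      g[, , , sl] <- array(gz, c(dm[1:3], n_classes))
    }
  }
  names(CE) <- names(DC) <- c("axial", "coronal", "sagittal")
  res <- list(CE = CE, DC = DC, total = sum(w_CE * CE + w_DC * DC))
  if (grad) res$grad <- g
  res
}

# --- post-processing --------------------------------------------------------

#' DBSCAN clustering of plane-channel masks
#'
#' Foreground voxels (any nonzero label) of each channel are clustered with
#' DBSCAN on their integer voxel coordinates: a core point has at least
#' \code{min_samples} foreground voxels (itself included) within Euclidean
#' distance \code{eps}; noise voxels are discarded. Voxels are visited in
#' ascending linear-index order, making the labeling deterministic.
#'
#' @param masks a \code{\link{plane_channel_masks}} object.
#' @param eps neighborhood radius in voxels.
#' @param min_samples density threshold for core points.
#' @return List of clusters; each has \code{channel}, \code{voxels} (n x 3
#'   0-based indices), \code{n}, \code{centroid_mm}, \code{class_id}
#'   (majority label) and the voxel bounding box.
#' @export
cluster_masks <- function(masks, eps = 2, min_samples = 10) {
  out <- list()
  for (chn in c("axial", "coronal", "sagittal")) {
    m <- masks[[chn]]
    lab <- dbscan_voxels_cpp(as.numeric(m), dim(m), eps, as.integer(min_samples))
    ids <- sort(unique(lab[lab > 0]))
    for (id in ids) {
      w <- which(lab == id)
      vox <- cbind((w - 1) %% dim(m)[1],
                   ((w - 1) %/% dim(m)[1]) %% dim(m)[2],
                   (w - 1) %/% (dim(m)[1] * dim(m)[2]))
      cl <- list(channel = chn, voxels = vox, n = nrow(vox),
                 centroid_mm = colMeans(vox) * masks$spacing + masks$origin,
                 class_id = as.integer(names(which.max(table(m[w])))),
                 bbox_lo = apply(vox, 2, min), bbox_hi = apply(vox, 2, max))
      out[[length(out) + 1]] <- cl
    }
  }
  out
}

#' Filter clusters by half the largest cluster size
#'
#' Per channel, the threshold is half the voxel count of the largest cluster
#' in that channel; smaller clusters are discarded as likely false positives.
#'
#' @param clusters list from \code{\link{cluster_masks}}.
#' @return The surviving clusters.
#' @export
filter_clusters <- function(clusters) {
  if (!length(clusters)) return(clusters)
  keep <- logical(length(clusters))
  for (chn in unique(vapply(clusters, `[[`, "", "channel"))) {
    idx <- which(vapply(clusters, `[[`, "", "channel") == chn)
    sizes <- vapply(clusters[idx], function(cl) as.numeric(cl$n), 0)
    keep[idx] <- sizes >= max(sizes) / 2
  }
  clusters[keep]
}

#' Group axial/coronal/sagittal clusters into per-vertebra triples
#'
#' A triple is formed when the voxel bounding boxes of an axial, a coronal
#' and a sagittal cluster pairwise intersect; ambiguities are resolved by
#' nearest centroids. Vertebrae with fewer than three channel clusters are
#' dropped with a warning.
#'
#' @param clusters filtered clusters.
#' @return List of triples; each a named list with elements \code{axial},
#'   \code{coronal}, \code{sagittal}.
#' @export
group_clusters <- function(clusters) {
  chs <- vapply(clusters, `[[`, "", "channel")
  ax <- clusters[chs == "axial"]
  co <- clusters[chs == "coronal"]
  sa <- clusters[chs == "sagittal"]
  # deterministic order: by centroid, lexicographic
  ord <- function(cl) cl[order(vapply(cl, function(c) c$centroid_mm[3], 0),
                               vapply(cl, function(c) c$centroid_mm[2], 0),
                               vapply(cl, function(c) c$centroid_mm[1], 0))]
  ax <- ord(ax); co <- ord(co); sa <- ord(sa)
  bbox_isect <- function(a, b) all(a$bbox_lo <= b$bbox_hi) && all(b$bbox_lo <= a$bbox_hi)
  used_co <- logical(length(co)); used_sa <- logical(length(sa))
  triples <- list()
  dropped <- 0
  for (a in ax) {
    cand_co <- which(!used_co & vapply(co, bbox_isect, TRUE, b = a))
    cand_sa <- which(!used_sa & vapply(sa, bbox_isect, TRUE, b = a))
    if (!length(cand_co) || !length(cand_sa)) { dropped <- dropped + 1; next }
    pick <- function(cand, cl) cand[which.min(vapply(cl[cand], function(c)
      sum((c$centroid_mm - a$centroid_mm)^2), 0))]
    ic <- pick(cand_co, co); is <- pick(cand_sa, sa)
    if (!bbox_isect(co[[ic]], sa[[is]])) { dropped <- dropped + 1; next }
    used_co[ic] <- TRUE; used_sa[is] <- TRUE
    triples[[length(triples) + 1]] <- list(axial = a, coronal = co[[ic]], sagittal = sa[[is]])
  }
  if (dropped > 0 || any(!used_co) || any(!used_sa))
    warning("incomplete cluster groups discarded (", dropped + sum(!used_co) + sum(!used_sa),
            " clusters without a full axial/coronal/sagittal triple)")
  triples
}

#' Vertebra center from a cluster triple
#'
#' The approximated vertebra center is the component-wise mean of the three
#' cluster centroids.
#'
#' @param triple a triple from \code{\link{group_clusters}}.
#' @return Center in world mm.
#' @export
vertebra_center_from_clusters <- function(triple) {
  (triple$axial$centroid_mm + triple$coronal$centroid_mm + triple$sagittal$centroid_mm) / 3
}

#' Plane normal from a flat cylinder cluster via PCA
#'
#' The normal is the eigenvector of the voxel-coordinate covariance with the
#' smallest eigenvalue: for a flat cylinder with d = 4 h the extent along
#' the normal (variance h^2/12) is much smaller than the radial extent
#' (variance d^2/16). The sign is canonicalized to a positive dot product
#' with the volume axis it is most aligned with.
#'
#' @param cluster a cluster from \code{\link{cluster_masks}}.
#' @return Unit normal (length-3).
#' @export
plane_normals_from_cluster <- function(cluster) {
  if (cluster$n < 4) stop("cluster too small for PCA normal estimation")
  cv <- stats::cov(cluster$voxels)
  ev <- eigen(cv, symmetric = TRUE)
  if (ev$values[2] < 1e-9) stop("degenerate cluster: voxels are (nearly) collinear")
  n <- ev$vectors[, 3]
  ax <- which.max(abs(n))
  if (n[ax] < 0) n <- -n
  n
}

#' Extract vertebra annotations from plane-channel masks
#'
#' The full segmentation post-processing chain: DBSCAN clustering per
#' channel, half-max cluster filtering, triple grouping, centroid averaging
#' for the center and PCA for the plane normals. The three per-channel
#' normals are assembled into the nearest orthonormal triplet.
#'
#' @param masks a \code{\link{plane_channel_masks}} object (ground truth or
#'   network prediction).
#' @param eps,min_samples DBSCAN parameters (voxels / count).
#' @return List of \code{\link{vertebra_annotation}} objects, with a
#'   \code{stage_counts} attribute logging cluster counts per stage.
#' @export
segplane_extract <- function(masks, eps = 2, min_samples = 10) {
  cl <- cluster_masks(masks, eps, min_samples)
  counts <- c(clusters = length(cl))
  fl <- filter_clusters(cl)
  counts["after_filter"] <- length(fl)
  tr <- group_clusters(fl)
  counts["triples"] <- length(tr)
  anns <- lapply(tr, function(t3) {
    ctr <- vertebra_center_from_clusters(t3)
    n_ax <- plane_normals_from_cluster(t3$axial)
    n_co <- plane_normals_from_cluster(t3$coronal)
    n_sa <- plane_normals_from_cluster(t3$sagittal)
    tp <- orthonormalize_triplet(plane_triplet(
      axial = spanning_from_normal(n_ax),
      coronal = spanning_from_normal(n_co),
      sagittal = spanning_from_normal(n_sa)))
    cls <- c(t3$axial$class_id, t3$coronal$class_id, t3$sagittal$class_id)
    class_id <- as.integer(names(which.max(table(cls))))
    # radial variance of a solid disk of radius r is r^2 / 4
    r_est <- mean(vapply(list(t3$axial, t3$coronal, t3$sagittal), function(c3) {
      ev <- eigen(stats::cov(c3$voxels), symmetric = TRUE, only.values = TRUE)$values
      2 * sqrt(mean(ev[1:2])) * masks$spacing
    }, 0))
    vertebra_annotation(class_id, ctr, rep(max(2 * r_est, 1e-3), 3), tp)
  })
  attr(anns, "stage_counts") <- counts
  anns
}

# Any orthonormal (u, v) pair spanning the plane with normal n.
spanning_from_normal <- function(n) {
  n <- unit3(n)
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unit3(cross3(ref, n))
  v <- cross3(n, u)
  list(u = u, v = v)
}
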