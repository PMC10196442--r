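make_ann <- function(class_id, center, extent, tp = identity_triplet()) {
  vertebra_annotation(class_id, center, rep(extent, 3), tp)
}

test_that("cylinder size rule keeps cylinders disjoint", {
  # two vertebrae 20 mm apart with 24 mm extents
  a <- make_ann(3, c(30, 30, 20), 24)
  b <- make_ann(3, c(30, 30, 40), 24)
  spec <- choose_cylinder_size(list(a, b))
  expect_equal(spec$d, 18)
  expect_equal(spec$h, 4.5)
  expect_equal(spec$d, 4 * spec$h)

  # single vertebra fallback
  s1 <- choose_cylinder_size(list(make_ann(1, c(30, 30, 30), 10)))
  expect_equal(s1$d, 15)
  expect_equal(s1$h, 3.75)

  # rasterized cylinders of distinct vertebrae share no voxels
  for (seed in 1:5) {
    sp <- scaled_phantom_spec()
    anns <- suppressWarnings(sample_spine_geometry(sp, seed = seed))
    if (length(anns) < 2) next
    spec2 <- choose_cylinder_size(anns)
    per_vert <- lapply(anns, function(a)
      rasterize_plane_cylinders(list(a), spec2, 64, sp$spacing))
    for (chn in c("axial", "coronal", "sagittal")) {
      occ <- Reduce(`+`, lapply(per_vert, function(m) (m[[chn]] > 0) * 1))
      expect_lte(max(occ), 1)
    }
  }
})

test_that("rasterized cylinder voxel counts match the analytic volume", {
  spec <- structure(list(d = 16, h = 4), class = "cylinder_spec")
  # center off the voxel lattice so center-sampled voxelization is unbiased
  ann <- make_ann(2, c(32.35, 31.62, 32.41), 20)
  m <- rasterize_plane_cylinders(list(ann), spec, 64, 1)
  analytic <- pi * (spec$d / 2)^2 * spec$h  # voxel volume = 1
  expect_lt(abs(sum(m$axial > 0) - analytic) / analytic, 0.02)
  expect_true(all(m$axial %in% c(0, 2)))

  # rotation invariance of the count (within discretization tolerance)
  rot <- rotated_triplet(rot_axis(c(1, 0, 0), 90))
  m90 <- rasterize_plane_cylinders(list(make_ann(2, c(32.35, 31.62, 32.41), 20, rot)),
                                   spec, 64, 1)
  expect_lt(abs(sum(m90$axial > 0) - sum(m$axial > 0)) / sum(m$axial > 0), 0.02)

  # overlapping labels across channels of the same vertebra are allowed
  expect_gt(sum(m$axial > 0 & m$coronal > 0), 0)

  # empty annotations -> all-zero masks
  m0 <- rasterize_plane_cylinders(list(), spec, 16, 1)
  expect_equal(sum(m0$axial) + sum(m0$coronal) + sum(m0$sagittal), 0)
})

test_that("flat cylinder variances identify the normal direction", {
  # for a solid cylinder with d = 4h: axial variance h^2/12 < radial d^2/16
  h <- 4; d <- 4 * h
  expect_lt(h^2 / 12, (d / 2)^2 / 4)
})

test_that("segmentation network has the 3-channel x 4-logit shape contract", {
  net <- build_segnet(patch_size = 32L, depth = 3L, width = 4L, seed = 1)
  out <- spineplane:::net_forward(net, array(0, rep(32, 3)))$outputs$seg_out
  expect_equal(dim(out), c(32L, 32L, 32L, 12L))
  # deterministic under a fixed seed
  net2 <- build_segnet(patch_size = 32L, depth = 3L, width = 4L, seed = 1)
  x <- array(runif(32^3), rep(32, 3))
  expect_identical(spineplane:::net_forward(net, x)$outputs$seg_out,
                   spineplane:::net_forward(net2, x)$outputs$seg_out)
  expect_error(build_segnet(patch_size = 30L, depth = 3L), "divisible")
})

test_that("segmentation loss: cross-entropy and Dice behave as specified", {
  dims <- c(8, 8, 8)
  lab <- array(0L, dims); lab[1:4, , ] <- 2L
  masks <- plane_channel_masks(lab, lab, lab)
  # one-hot logits exactly matching the masks -> Dice component ~0
  logits <- array(0, c(dims, 12))
  for (c3 in 1:3) for (k in 0:3) {
    logits[, , , (c3 - 1) * 4 + k + 1] <- ifelse(lab == k, 50, -50)
  }
  ls <- seg_loss(logits, masks)
  expect_lt(max(ls$DC), 1e-4)
  expect_lt(max(ls$CE), 1e-10)

  # uniform logits on a half/half two-class patch: CE = log(4) per voxel
  lu <- array(0, c(dims, 12))
  lsu <- seg_loss(lu, masks)
  expect_equal(unname(lsu$CE["axial"]), log(4), tolerance = 1e-12)

  # total sums the three channels: three identical channels -> 3x one channel
  expect_equal(ls$total, sum(1 * ls$CE + 1 * ls$DC))
  expect_equal(lsu$total, unname(3 * (1 * lsu$CE[1] + 1 * lsu$DC[1])), tolerance = 1e-12)

  # gradient check against finite differences
  set.seed(8)
  small <- array(rnorm(4 * 4 * 4 * 12), c(4, 4, 4, 12))
  labs <- array(sample(0:3, 64, replace = TRUE), c(4, 4, 4))
  msk <- plane_channel_masks(labs, labs, labs)
  g <- seg_loss(small, msk, grad = TRUE)$grad
  for (i in c(1, 100, 500)) {
    p <- small; p[i] <- p[i] + 1e-6
    m2 <- small; m2[i] <- m2[i] - 1e-6
    fd <- (seg_loss(p, msk)$total - seg_loss(m2, msk)$total) / 2e-6
    expect_equal(g[i], fd, tolerance = 1e-5)
  }
})

test_that("DBSCAN clustering finds blobs, discards noise, matches flood fill", {
  dims <- c(40, 40, 40)
  m <- array(0, dims)
  m[3:7, 3:7, 3:7] <- 1      # solid 5^3 blob
  m[28:32, 28:32, 28:32] <- 2 # second blob, > 20 voxels away
  masks <- plane_channel_masks(m, array(0, dims), array(0, dims))
  cl <- cluster_masks(masks, eps = 2, min_samples = 5)
  expect_equal(length(cl), 2)
  expect_setequal(vapply(cl, `[[`, 0L, "class_id"), c(1L, 2L))
  expect_equal(sort(vapply(cl, `[[`, 0L, "n")), c(125L, 125L))
  # centroid = mean of member voxel coordinates
  c1 <- cl[[1]]
  expect_equal(c1$centroid_mm, colMeans(c1$voxels), tolerance = 1e-12)

  # isolated voxels are noise under min_samples = 5
  iso <- array(0, dims)
  iso[cbind(c(5, 20, 35), c(5, 20, 35), c(5, 20, 35))] <- 1
  cl0 <- cluster_masks(plane_channel_masks(iso, iso * 0, iso * 0),
                       eps = 2, min_samples = 5)
  expect_equal(length(cl0), 0)

  # eps = 1 (6-neighborhood): same partition as an R flood-fill oracle
  flood_components <- function(arr) {
    lab <- array(0L, dim(arr)); nxt <- 0L
    idx <- which(arr > 0)
    for (st in idx) {
      if (lab[st] > 0) next
      nxt <- nxt + 1L
      queue <- st
      lab[st] <- nxt
      while (length(queue)) {
        v <- queue[[1]]; queue <- queue[-1]
        co <- arrayInd(v, dim(arr))
        for (d in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))) {
          nb <- co + d
          if (any(nb < 1) || any(nb > dim(arr))) next
          li <- nb[1] + dim(arr)[1] * (nb[2] - 1) + prod(dim(arr)[1:2]) * (nb[3] - 1)
          if (arr[li] > 0 && lab[li] == 0L) { lab[li] <- nxt; queue <- c(queue, li) }
        }
      }
    }
    lab
  }
  set.seed(12)
  blob <- array(0, c(24, 24, 24))
  for (k in 1:6) {
    c0 <- sample(4:20, 3, replace = TRUE)
    blob[(c0[1]-2):(c0[1]+2), (c0[2]-2):(c0[2]+2), (c0[3]-2):(c0[3]+2)] <- 1
  }
  labs <- flood_components(blob)
  cl1 <- cluster_masks(plane_channel_masks(blob, blob * 0, blob * 0),
                       eps = 1, min_samples = 1)
  expect_equal(length(cl1), max(labs))
  # identical partition: every cluster maps to exactly one flood-fill label
  for (c2 in cl1) {
    li <- c2$voxels[, 1] + 1 + 24 * c2$voxels[, 2] + 24^2 * c2$voxels[, 3]
    expect_equal(length(unique(labs[li])), 1)
    expect_equal(sum(labs == labs[li[1]]), c2$n)
  }
})

test_that("cluster filtering keeps clusters above half the channel maximum", {
  mk <- function(n, chn = "axial") list(channel = chn, n = n, voxels = matrix(0, n, 3),
                                        centroid_mm = c(0, 0, 0), class_id = 1L,
                                        bbox_lo = c(0, 0, 0), bbox_hi = c(1, 1, 1))
  out <- filter_clusters(list(mk(1000), mk(600), mk(499)))
  expect_equal(vapply(out, `[[`, 0, "n"), c(1000, 600))
  expect_equal(length(filter_clusters(list(mk(7)))), 1)
  allsame <- filter_clusters(list(mk(50), mk(50), mk(50)))
  expect_equal(length(allsame), 3)
  # threshold is per channel
  mixed <- filter_clusters(list(mk(1000), mk(400), mk(10, "coronal"), mk(9, "coronal")))
  expect_equal(vapply(mixed, `[[`, 0, "n"), c(1000, 10, 9))
  # never removes the largest cluster; monotone in input size
  expect_equal(length(filter_clusters(list())), 0)
})

test_that("cluster grouping, centroid averaging and PCA normals recover phantoms", {
  # Eq.-style centroid average
  triple <- list(axial = list(centroid_mm = c(1, 2, 3)),
                 coronal = list(centroid_mm = c(3, 2, 1)),
                 sagittal = list(centroid_mm = c(2, 2, 2)))
  expect_equal(vertebra_center_from_clusters(triple), c(2, 2, 2))

  # PCA normal of a rasterized flat cylinder
  spec <- structure(list(d = 16, h = 4), class = "cylinder_spec")
  m <- rasterize_plane_cylinders(list(make_ann(2, c(32, 32, 32), 20)), spec, 64, 1)
  cl <- cluster_masks(m, eps = 2, min_samples = 10)
  axial_cl <- cl[[which(vapply(cl, `[[`, "", "channel") == "axial")]]
  n <- plane_normals_from_cluster(axial_cl)
  expect_lt(plane_angle_error(n, c(0, 0, 1)), 1)

  # 30-degree rotated cylinder
  rot <- rotated_triplet(rot_axis(c(1, 0, 0), 30))
  m30 <- rasterize_plane_cylinders(list(make_ann(2, c(32, 32, 32), 20, rot)), spec, 64, 1)
  cl30 <- cluster_masks(m30, eps = 2, min_samples = 10)
  ax30 <- cl30[[which(vapply(cl30, `[[`, "", "channel") == "axial")]]
  n30 <- plane_normals_from_cluster(ax30)
  expect_lt(plane_angle_error(n30, c(0, -sin(pi / 6), cos(pi / 6))), 1)

  # full grouping on clean phantom masks: one triple per vertebra, classes and
  # correspondence correct by nearest-center matching
  for (seed in c(3, 7, 11)) {
    sp <- scaled_phantom_spec()
    s <- suppressWarnings(phantom_sample(sp, seed = seed))
    anns <- segplane_extract(s$masks, eps = 2, min_samples = 10)
    expect_equal(length(anns), length(s$annotations))
    rep <- evaluate_predictions(anns, s$annotations)
    expect_equal(unname(rep$detection["recall"]), 1)
    expect_equal(unname(rep$classification$metrics["accuracy"]), 1)
  }

  # a vertebra missing one channel is dropped with a warning
  sp <- scaled_phantom_spec()
  s <- suppressWarnings(phantom_sample(sp, seed = 3))
  if (length(s$annotations) >= 2) {
    broken <- s$masks
    cl <- cluster_masks(broken, 2, 10)
    sag <- which(vapply(cl, `[[`, "", "channel") == "sagittal")
    drop_vox <- cl[[sag[1]]]$voxels + 1
    broken$sagittal[drop_vox] <- 0  # erase one sagittal cylinder
    broken$sagittal <- array(broken$sagittal, dim(s$masks$sagittal))
    ix <- cbind(drop_vox)
    broken$sagittal[ix] <- 0
    expect_warning(out <- segplane_extract(broken, 2, 10), "incomplete")
    expect_equal(length(out), length(s$annotations) - 1)
  }
})
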