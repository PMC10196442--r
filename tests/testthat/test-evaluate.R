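ann_at <- function(center, class_id = 2L, extent = 20,
                   tp = identity_triplet()) {
  vertebra_annotation(class_id, center, rep(extent, 3), tp)
}

test_that("matching is one-to-one, validity-gated and order-invariant", {
  gts <- list(ann_at(c(30, 30, 30)), ann_at(c(30, 30, 60)), ann_at(c(30, 30, 90)))
  m <- match_predictions(gts, gts)
  expect_equal(nrow(m$pairs), 3)
  expect_equal(length(m$fp), 0)
  expect_equal(length(m$fn), 0)

  # a far-away prediction is a false positive
  preds <- c(gts, list(ann_at(c(100, 100, 100))))
  m2 <- match_predictions(preds, gts)
  expect_equal(nrow(m2$pairs), 3)
  expect_equal(m2$fp, 4L)

  # prediction outside every ground-truth box never matches, even if nearest
  off <- list(ann_at(c(30, 30, 42)))  # 12 mm from gt1, outside its 20 mm box
  m3 <- match_predictions(off, gts[1])
  expect_equal(nrow(m3$pairs), 0)

  # order invariance: permuting predictions yields the same pair set
  set.seed(31)
  preds4 <- list(ann_at(c(31, 30, 29)), ann_at(c(29, 31, 61)), ann_at(c(30, 29, 91)))
  m4 <- match_predictions(preds4, gts)
  perm <- c(3, 1, 2)
  m5 <- match_predictions(preds4[perm], gts)
  got4 <- m4$pairs[order(m4$pairs[, "gt"]), "pred"]
  got5 <- perm[m5$pairs[order(m5$pairs[, "gt"]), "pred"]]  # back to original ids
  expect_equal(unname(got5), unname(got4))

  # one-to-one: each index appears at most once
  expect_equal(anyDuplicated(m4$pairs[, 1]), 0)
  expect_equal(anyDuplicated(m4$pairs[, 2]), 0)
})

test_that("detection metrics follow the TP/FP/FN conventions", {
  m <- list(pairs = matrix(seq_len(18), 9, 2), fp = 10L, fn = integer(0))
  dm <- detection_metrics(m)
  expect_equal(unname(dm["recall"]), 1.0)
  expect_equal(unname(dm["precision"]), 0.9)
  expect_equal(unname(dm["accuracy"]), 0.9)
  expect_equal(unname(dm["error_rate"]), 0.1)

  m0 <- list(pairs = matrix(integer(0), 0, 2), fp = integer(0), fn = 1:5)
  d0 <- detection_metrics(m0)
  expect_equal(unname(d0["recall"]), 0)
  expect_equal(unname(d0["accuracy"]), 0)

  expect_message(de <- detection_metrics(list(pairs = matrix(integer(0), 0, 2),
                                              fp = integer(0), fn = integer(0))),
                 "empty")
  expect_equal(unname(de["accuracy"]), 1)
  # accuracy + error rate = 1 on random confusion counts
  set.seed(17)
  for (i in 1:20) {
    tp <- sample(0:30, 1); fp <- sample(0:10, 1); fn <- sample(0:10, 1)
    if (tp + fp + fn == 0) next
    mm <- list(pairs = matrix(seq_len(2 * tp), ncol = 2),
               fp = seq_len(fp), fn = seq_len(fn))
    dmm <- detection_metrics(mm)
    expect_equal(unname(dmm["accuracy"] + dmm["error_rate"]), 1)
    expect_equal(unname(dmm["recall"]), if (tp + fn > 0) tp / (tp + fn) else 1)
    expect_equal(unname(dmm["precision"]), if (tp + fp > 0) tp / (tp + fp) else 1)
  }
})

test_that("classification metrics use matched pairs only, macro-averaged", {
  gts <- list(ann_at(c(30, 30, 30), 1L), ann_at(c(30, 30, 60), 2L),
              ann_at(c(30, 30, 90), 2L), ann_at(c(30, 30, 120), 3L))
  preds <- list(ann_at(c(30, 30, 30), 1L), ann_at(c(30, 30, 60), 2L),
                ann_at(c(30, 30, 90), 3L),  # thoracic predicted as lumbar
                ann_at(c(30, 30, 120), 3L))
  m <- match_predictions(preds, gts)
  cm <- classification_metrics(m, preds, gts)
  expect_equal(sum(cm$confusion), 4)
  expect_equal(unname(cm$metrics["accuracy"]), 0.75)
  expect_equal(cm$confusion["L", "T"], 1L)
  # macro recall by hand: C 1/1, T 1/2, L 1/1
  expect_equal(unname(cm$metrics["recall"]), mean(c(1, 0.5, 1)))
  # macro precision by hand: C 1/1, T 1/1, L 1/2
  expect_equal(unname(cm$metrics["precision"]), mean(c(1, 1, 0.5)))

  perfect <- classification_metrics(m, gts, gts)
  expect_equal(unname(perfect$metrics["accuracy"]), 1)
  expect_true(all(perfect$confusion[upper.tri(perfect$confusion)] == 0))
})

test_that("localization errors decompose along the ground-truth planes", {
  g <- ann_at(c(30, 30, 30))
  # prediction shifted 2 mm along the gt axial normal
  p <- ann_at(c(30, 30, 32))
  m <- match_predictions(list(p), list(g))
  le <- localization_errors(m, list(p), list(g))
  expect_equal(le$d_cc, 2)
  expect_equal(le$d_asp, 2)
  expect_equal(le$d_csp, 0)
  expect_equal(le$d_ssp, 0)
  expect_equal(le$d_sp_bar, 0)

  # identical annotations -> all zeros
  m0 <- match_predictions(list(g), list(g))
  l0 <- localization_errors(m0, list(g), list(g))
  expect_true(all(c(l0$d_cc, l0$d_asp, l0$d_csp, l0$d_ssp) == 0))

  # Pythagoras: d_cc^2 = d_asp^2 + d_csp^2 + d_ssp^2 for orthonormal triplets
  set.seed(23)
  for (i in 1:20) {
    R <- rot_axis(rnorm(3), runif(1, 0, 40))
    gt <- ann_at(c(30, 30, 30), tp = rotated_triplet(R))
    pr <- ann_at(c(30, 30, 30) + runif(3, -5, 5), tp = rotated_triplet(R))
    mm <- match_predictions(list(pr), list(gt))
    ll <- localization_errors(mm, list(pr), list(gt))
    expect_equal(ll$d_cc^2, ll$d_asp^2 + ll$d_csp^2 + ll$d_ssp^2, tolerance = 1e-9)
  }
})

test_that("orientation errors match an independent quaternion recomputation", {
  g <- ann_at(c(30, 30, 30))
  # prediction rotated 5 degrees about the gt axial normal: axial unchanged
  p <- ann_at(c(30, 30, 30), tp = rotated_triplet(rot_axis(c(0, 0, 1), 5)))
  m <- match_predictions(list(p), list(g))
  oe <- orientation_errors(m, list(p), list(g))
  expect_equal(oe$a_asp, 0, tolerance = 1e-9)
  expect_equal(oe$a_csp, 5, tolerance = 1e-9)
  expect_equal(oe$a_ssp, 5, tolerance = 1e-9)

  o0 <- orientation_errors(m, list(g), list(g))
  expect_equal(o0$a_sp_bar, 0)

  # random rotations: compare with a quaternion-based recomputation
  quat_rotate <- function(q, v) {
    # rotate v by unit quaternion q = (w, x, y, z)
    w <- q[1]; u <- q[2:4]
    v + 2 * spineplane:::cross3(u, spineplane:::cross3(u, v) + w * v)
  }
  set.seed(29)
  for (i in 1:100) {
    ax <- spineplane:::unit3(rnorm(3)); th <- runif(1, 0, pi / 2)
    q <- c(cos(th / 2), sin(th / 2) * ax)
    tp <- identity_triplet()
    pr <- ann_at(c(30, 30, 30), tp = plane_triplet(
      axial = list(u = quat_rotate(q, tp$axial$u), v = quat_rotate(q, tp$axial$v)),
      coronal = list(u = quat_rotate(q, tp$coronal$u), v = quat_rotate(q, tp$coronal$v)),
      sagittal = list(u = quat_rotate(q, tp$sagittal$u), v = quat_rotate(q, tp$sagittal$v))))
    mm <- match_predictions(list(pr), list(g))
    oo <- orientation_errors(mm, list(pr), list(g))
    # independent: angle between rotated and original axes from the quaternion
    for (pl in c("axial", "coronal", "sagittal")) {
      nref <- list(axial = c(0, 0, 1), coronal = c(0, 1, 0), sagittal = c(1, 0, 0))[[pl]]
      nrot <- quat_rotate(q, nref)
      expected <- acos(min(1, abs(sum(nrot * nref)))) * 180 / pi
      got <- switch(pl, axial = oo$a_asp, coronal = oo$a_csp, sagittal = oo$a_ssp)
      expect_equal(got, expected, tolerance = 1e-9)
    }
  }
})

test_that("pooled evaluation over volumes matches per-volume counting", {
  set.seed(41)
  gt_vols <- lapply(1:5, function(v)
    lapply(1:3, function(i) ann_at(c(30, 30, 25 * i), sample(1:3, 1))))
  pred_vols <- lapply(gt_vols, function(g) g[-1])  # drop one per volume -> FNs
  rep <- evaluate_predictions(pred_vols, gt_vols)
  expect_equal(unname(rep$counts["tp"]), 10)
  expect_equal(unname(rep$counts["fn"]), 5)
  expect_equal(unname(rep$detection["recall"]), 10 / 15)
  expect_equal(unname(rep$detection["precision"]), 1)
  expect_equal(unname(rep$classification$metrics["accuracy"]), 1)
  expect_equal(mean(rep$localization$d_cc), 0)
})
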