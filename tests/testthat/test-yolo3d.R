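test_that("network shape contract follows the three-scale grid pattern", {
  # full-size configuration: grids 5/10/20 and 9125 candidates, checked
  # symbolically from the architecture trace
  cfg160 <- yolo_config(input_size = 160L)
  expect_equal(cfg160$grids, c(5L, 10L, 20L))
  expect_equal(yolo_candidates(cfg160)$n_candidates, 9125)
  net160 <- build_yolo3d(cfg160, seed = 1)
  expect_equal(net160$shapes$spd1, c(5L, 5L, 5L, 28L))
  expect_equal(net160$shapes$spd2, c(10L, 10L, 10L, 28L))
  expect_equal(net160$shapes$spd3, c(20L, 20L, 20L, 28L))

  # real forward pass at a reduced size
  cfg <- yolo_config(input_size = 64L, width_multiplier = 0.25)
  net <- build_yolo3d(cfg, seed = 1)
  out <- yolo_forward(net, array(0, rep(64, 3)))
  expect_equal(dim(out$spd1), c(2L, 2L, 2L, 28L))
  expect_equal(dim(out$spd2), c(4L, 4L, 4L, 28L))
  expect_equal(dim(out$spd3), c(8L, 8L, 8L, 28L))

  expect_error(yolo_config(input_size = 100L), "divisible by 32")
})

test_that("normalized anchor sizes follow from the stated vertebra extents", {
  # largest lumbar extent over the 160 mm patch -> the scale-1 anchor;
  # smallest cervical -> 0.05
  expect_equal(24 / 160, 0.15)
  expect_equal(8 / 160, 0.05)
  cfg <- yolo_config()
  expect_equal(cfg$anchors[1], 24 / 160)
})

test_that("target encoding assigns scales by anchor size-IoU and cells by center", {
  cfg <- yolo_config(input_size = 160L)
  mk <- function(extent_mm, center = c(80, 80, 80)) {
    vertebra_annotation(2, center, rep(extent_mm, 3), identity_triplet())
  }
  # 0.15-normalized box at the patch center -> scale 1, cell (2,2,2)
  tg <- encode_yolo_targets(list(mk(0.15 * 160)), cfg, dim = 160, spacing = 1)
  cells <- attr(tg, "obj_cells")
  expect_equal(unname(cells[1, ]), c(1, 2, 2, 2))
  # independently: size-IoU against each cubic anchor
  sIoU <- vapply(cfg$anchors, function(a) {
    inter <- min(0.15, a)^3; inter / (0.15^3 + a^3 - inter)
  }, 0)
  expect_equal(which.max(sIoU), 1L)

  # 0.07-normalized box -> finest scale
  tg3 <- encode_yolo_targets(list(mk(0.07 * 160)), cfg, dim = 160, spacing = 1)
  expect_equal(unname(attr(tg3, "obj_cells")[1, 1]), 3)
  sIoU3 <- vapply(cfg$anchors, function(a) {
    inter <- min(0.07, a)^3; inter / (0.07^3 + a^3 - inter)
  }, 0)
  expect_equal(which.max(sIoU3), 3L)

  # empty annotation list -> all-zero objectness
  tg0 <- encode_yolo_targets(list(), cfg, dim = 160, spacing = 1)
  expect_true(all(vapply(tg0, function(t) all(t[, , , 7] == 0), TRUE)))

  # cell collision keeps the larger vertebra
  a1 <- mk(22, c(80, 80, 80)); a2 <- mk(24, c(80, 80, 82))
  expect_warning(tgc <- encode_yolo_targets(list(a1, a2), cfg, dim = 160, spacing = 1),
                 "larger")
  expect_equal(sum(vapply(tgc, function(t) sum(t[, , , 7]), 0)), 1)
  cell <- attr(tgc, "obj_cells")[1, 2:4] + 1
  expect_equal(exp(tgc[[1]][cell[1], cell[2], cell[3], 4]) * cfg$anchors[1] * 160,
               24, tolerance = 1e-9)
})

test_that("decoding inverts encoding up to half a cell", {
  cfg <- yolo_config(input_size = 160L)
  # all-zero raw activations: center at (sigmoid(0) + 0)/G, extents = anchor
  raw <- lapply(cfg$grids, function(G) array(0, c(G, G, G, 28)))
  dets <- decode_yolo_output(raw, cfg, orthonormalize = FALSE)
  first <- dets[dets$scale == 1 & dets$cell_x == 0 & dets$cell_y == 0 & dets$cell_z == 0, ]
  expect_equal(as.numeric(first[1, c("cx", "cy", "cz")]), rep(0.1, 3))
  expect_equal(as.numeric(first[1, c("ex", "ey", "ez")]), rep(0.15, 3))
  expect_equal(first$objectness, 0.5)
  # objectness logit -> extreme values saturate to 0/1
  raw[[1]][1, 1, 1, 7] <- -50
  d2 <- decode_yolo_output(raw, cfg, orthonormalize = FALSE)
  expect_equal(d2$objectness[d2$scale == 1][1], 0, tolerance = 1e-12)

  # encode -> decode round trip on phantom annotations
  sp <- scaled_phantom_spec()
  cfgs <- scaled_yolo_config()
  for (seed in 1:5) {
    anns <- suppressWarnings(sample_spine_geometry(sp, seed = seed))
    tg <- suppressWarnings(encode_yolo_targets(anns, cfgs, dim = 64, spacing = sp$spacing))
    dets <- decode_yolo_output(tg, cfgs, orthonormalize = FALSE)
    cells <- attr(tg, "obj_cells")
    for (r in seq_len(nrow(cells))) {
      sc <- cells[r, 1]; G <- cfgs$grids[sc]
      row <- dets[dets$scale == sc & dets$cell_x == cells[r, 2] &
                  dets$cell_y == cells[r, 3] & dets$cell_z == cells[r, 4], ]
      # find the annotation encoded in this cell
      matched <- FALSE
      for (a in anns) {
        cn <- norm_from_world(a$center_mm, 64, sp$spacing)
        if (!all(floor(cn * G) == cells[r, 2:4])) next
        sc_a <- which.max(vapply(cfgs$anchors, function(an)
          spineplane:::size_iou(a$extent_mm / (64 * sp$spacing), an), 0))
        if (sc_a != sc) next
        matched <- TRUE
        expect_lt(max(abs(as.numeric(row[1, c("cx", "cy", "cz")]) - cn)), 1 / (2 * G))
        expect_equal(as.numeric(row[1, c("ex", "ey", "ez")]),
                     a$extent_mm / (64 * sp$spacing), tolerance = 1e-9)
        expect_equal(row$class_id[1], a$class_id)
        expect_equal(as.numeric(row[1, paste0("pl", 1:18)]),
                     spineplane:::triplet_components(a$planes), tolerance = 1e-9)
      }
      expect_true(matched)
    }
  }

  # shape mismatch is an error
  bad <- lapply(c(5, 10, 19), function(G) array(0, c(G, G, G, 28)))
  expect_error(decode_yolo_output(bad, cfg), "shape")
})

test_that("decoded plane triplets are orthonormalized", {
  cfg <- yolo_config(input_size = 160L)
  set.seed(4)
  raw <- lapply(cfg$grids, function(G) array(rnorm(G^3 * 28, 0, 0.5), c(G, G, G, 28)))
  dets <- decode_yolo_output(raw, cfg)
  i <- sample(nrow(dets), 20)
  for (r in i) {
    tp <- spineplane:::triplet_from_components(as.numeric(dets[r, paste0("pl", 1:18)]))
    expect_true(is_orthonormal_triplet(tp, tol = 1e-6))
  }
})

test_that("loss terms are zero for perfect predictions and respond to weights", {
  cfg <- scaled_yolo_config()
  sp <- scaled_phantom_spec()
  anns <- suppressWarnings(sample_spine_geometry(sp, seed = 9))
  tg <- suppressWarnings(encode_yolo_targets(anns, cfg, dim = 64, spacing = sp$spacing))
  # logit-space raw outputs that decode exactly to the targets
  raw <- lapply(seq_len(3), function(s) {
    t <- tg[[s]]
    r <- array(0, dim(t))
    m <- matrix(t, ncol = 28); rm <- matrix(r, ncol = 28)
    obj <- m[, 7] == 1
    rm[, 7] <- -50
    rm[obj, 7] <- 50
    eps <- 1e-12
    rm[obj, 1:3] <- log(pmax(m[obj, 1:3, drop = FALSE], eps) /
                        pmax(1 - m[obj, 1:3, drop = FALSE], eps))
    rm[obj, 4:6] <- m[obj, 4:6, drop = FALSE]
    rm[obj, 8:10] <- ifelse(m[obj, 8:10, drop = FALSE] == 1, 50, -50)
    rm[obj, 11:28] <- m[obj, 11:28, drop = FALSE]
    array(rm, dim(t))
  })
  ls <- yolo_loss(raw, tg, cfg)
  expect_equal(ls$BL, 0, tolerance = 1e-10)
  expect_equal(ls$CL, 0, tolerance = 1e-10)
  expect_equal(ls$APL, 0, tolerance = 1e-12)
  expect_equal(ls$CPL, 0, tolerance = 1e-12)
  expect_equal(ls$SPL, 0, tolerance = 1e-12)
  expect_lt(ls$OL, 1e-10)
  expect_lt(ls$NOL, 1e-10)

  # weighted total: perturbing one background logit moves total by 10 x dNOL
  raw2 <- raw
  raw2[[3]][1, 1, 1, 7] <- 0  # a non-object cell
  ls2 <- yolo_loss(raw2, tg, cfg)
  expect_equal(ls2$total - ls$total, 10 * (ls2$NOL - ls$NOL), tolerance = 1e-9)
  # and the default weights are w_NOL = w_BL = 10, others 1
  expect_equal(cfg$loss_weights$NOL, 10)
  expect_equal(cfg$loss_weights$BL, 10)
  expect_equal(cfg$loss_weights$OL, 1)

  # single object cell, one plane component off by eps: APL = eps^2 / 18
  one <- suppressWarnings(encode_yolo_targets(
    list(vertebra_annotation(3, rep(32, 3), rep(22, 3), identity_triplet())),
    cfg, dim = 64, spacing = sp$spacing))
  rawp <- lapply(seq_len(3), function(s) {
    t <- one[[s]]; r <- array(0, dim(t))
    m <- matrix(t, ncol = 28); rm <- matrix(r, ncol = 28)
    obj <- m[, 7] == 1
    rm[, 7] <- -50; rm[obj, 7] <- 50
    rm[obj, 1:3] <- log(m[obj, 1:3] / (1 - m[obj, 1:3]))
    rm[obj, 4:6] <- m[obj, 4:6]
    rm[obj, 8:10] <- ifelse(m[obj, 8:10] == 1, 50, -50)
    rm[obj, 11:28] <- m[obj, 11:28]
    array(rm, dim(t))
  })
  cells <- attr(one, "obj_cells")
  sc <- cells[1, 1]; ci <- cells[1, 2:4] + 1
  rawp[[sc]][ci[1], ci[2], ci[3], 12] <- rawp[[sc]][ci[1], ci[2], ci[3], 12] + 0.3
  lsp <- yolo_loss(rawp, one, cfg)
  expect_equal(lsp$APL, 0.3^2 / 18, tolerance = 1e-10)
  expect_equal(lsp$CPL, 0)
  # hand-checked total
  expect_equal(lsp$total, 1 * 0.3^2 / 18 + lsp$OL + 10 * lsp$NOL, tolerance = 1e-9)

  # no object cells: object-conditioned terms are zero by definition
  empty <- encode_yolo_targets(list(), cfg, dim = 64, spacing = sp$spacing)
  raw0 <- lapply(cfg$grids, function(G) array(0, c(G, G, G, 28)))
  ls0 <- yolo_loss(raw0, empty, cfg)
  expect_equal(ls0$OL, 0)
  expect_equal(ls0$BL, 0)
  expect_equal(ls0$CL, 0)
  expect_equal(ls0$APL + ls0$CPL + ls0$SPL, 0)
  expect_gt(ls0$NOL, 0)
})

test_that("loss gradients match finite differences through the network", {
  cfg <- yolo_config(input_size = 32L, width_multiplier = 0.1)
  net <- build_yolo3d(cfg, seed = 2)
  sp <- phantom_spec(grid_size = 32L, spacing = 1, n_vertebrae = c(1L, 1L),
                     size_ranges = list(cervical = c(8, 10), thoracic = c(10, 12),
                                        lumbar = c(10, 12)))
  anns <- suppressWarnings(sample_spine_geometry(sp, seed = 1))
  tg <- suppressWarnings(encode_yolo_targets(anns, cfg, dim = 32, spacing = 1))
  set.seed(3)
  vol <- array(runif(32^3), rep(32, 3))
  fwd <- spineplane:::net_forward(net, vol, cache = TRUE)
  ls <- yolo_loss(fwd$outputs, tg, cfg, grad = TRUE)
  gr <- spineplane:::net_backward(net, fwd, ls$grads)
  loss_of <- function(n2) yolo_loss(spineplane:::net_forward(n2, vol)$outputs, tg, cfg)$total
  # wide central-difference step: the convolution path is single precision
  for (probe in list(c("c1", "w"), c("c1", "beta"), c("spd3", "b"), c("c14", "gamma"))) {
    nm <- probe[1]; pn <- probe[2]
    i <- min(5, length(net$params[[nm]][[pn]]))
    np <- net; np$params[[nm]][[pn]][i] <- np$params[[nm]][[pn]][i] + 1e-3
    nmn <- net; nmn$params[[nm]][[pn]][i] <- nmn$params[[nm]][[pn]][i] - 1e-3
    fd <- (loss_of(np) - loss_of(nmn)) / 2e-3
    expect_equal(gr[[nm]][[pn]][i], fd, tolerance = 1e-2)
  }
})

test_that("select_detections applies confidence, per-class NMS and class threshold", {
  base <- data.frame(cx = 0.5, cy = 0.5, cz = 0.5, ex = 0.3, ey = 0.3, ez = 0.3,
                     objectness = 0.9, p1 = 0.9, p2 = 0.1, p3 = 0.1,
                     class_id = 1L, score = 0.9, scale = 1L,
                     cell_x = 0L, cell_y = 0L, cell_z = 0L)
  for (k in 1:18) base[[paste0("pl", k)]] <- 0

  # all below confidence -> empty
  low <- base; low$objectness <- 0.05
  expect_equal(nrow(select_detections(low, 0.10, 0.15, 0.25)), 0)

  # two overlapping detections of the same vertebra -> one survivor
  two <- rbind(base, base)
  two$cx <- c(0.5, 0.56); two$objectness <- c(0.9, 0.8); two$score <- two$objectness
  ov <- spineplane:::iou3d_vec(c(0.5, 0.5, 0.5), c(0.3, 0.3, 0.3),
                               matrix(c(0.56, 0.5, 0.5), 1), matrix(0.3, 1, 3))
  expect_gt(ov, 0.15)
  out <- select_detections(two, 0.10, 0.15, 0.25)
  expect_equal(nrow(out), 1)
  expect_equal(out$objectness, 0.9)

  # class-probability threshold drops low-probability survivors
  weak <- base; weak$p1 <- 0.2; weak$p2 <- 0.1; weak$p3 <- 0.15
  expect_equal(nrow(select_detections(weak, 0.10, 0.15, 0.25)), 0)

  # different classes do not suppress each other
  twoc <- rbind(base, base)
  twoc$cx <- c(0.5, 0.56); twoc$class_id <- c(1L, 2L)
  twoc$p1 <- c(0.9, 0.1); twoc$p2 <- c(0.1, 0.9)
  out2 <- select_detections(twoc, 0.10, 0.15, 0.25)
  expect_equal(nrow(out2), 2)

  # stage counts are logged
  expect_named(attr(out, "stage_counts"),
               c("candidates", "after_confidence", "after_nms", "after_classprob"))
})
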