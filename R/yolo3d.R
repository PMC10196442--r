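# Detection pipeline: volumetric YOLOv3-style network, grid target encoding,
# multi-term detection loss, decoding, and thresholded detection selection.
#
# Per grid cell the detector predicts 25 + n_classes channels:
#   3 center offsets, 3 log extent ratios, 1 objectness logit,
#   n_classes class logits, and 18 plane spanning-vector components
#   (u and v for each of axial / coronal / sagittal).
# With 3 classes this is 28 channels per (single-anchor) cell.

#' Detector configuration
#'
#' The three detection scales use one cubic anchor each: 0.15, 0.11 and 0.07
#' of the patch size, matching the typical normalized extents of lumbar
#' (21--24 mm), thoracic (17--24 mm) and cervical (8--13 mm) vertebrae in a
#' 160 mm patch. Grids have \code{input_size}/32, /16 and /8 cells per axis.
#'
#' @param input_size patch edge length in voxels; must be divisible by 32.
#' @param width_multiplier scales every channel count of the backbone.
#' @param n_classes number of vertebra classes (cervical, thoracic, lumbar).
#' @param anchors normalized cubic anchor extents, coarse to fine scale.
#' @param conf_threshold minimum objectness kept during selection.
#' @param iou_threshold non-max suppression IoU threshold.
#' @param classprob_threshold minimum max class probability after NMS.
#' @param loss_weights named list of the seven loss-term weights.
#' @param lr,weight_decay Adam defaults for training.
#' @return A \code{yolo_config} list.
#' @export
yolo_config <- function(input_size = 160L, width_multiplier = 1,
                        n_classes = 3L,
                        anchors = c(0.15, 0.11, 0.07),
                        conf_threshold = 0.10, iou_threshold = 0.15,
                        classprob_threshold = 0.25,
                        loss_weights = list(OL = 1, NOL = 10, BL = 10, CL = 1,
                                            APL = 1, CPL = 1, SPL = 1),
                        lr = 1e-5, weight_decay = 1e-4) {
  input_size <- as.integer(input_size)
  if (input_size %% 32L != 0L) stop("input_size must be divisible by 32")
  stopifnot(length(anchors) == 3, all(anchors > 0), all(anchors < 1),
            all(diff(anchors) < 0))
  cfg <- list(input_size = input_size, width_multiplier = width_multiplier,
              n_classes = as.integer(n_classes), anchors = anchors,
              conf_threshold = conf_threshold, iou_threshold = iou_threshold,
              classprob_threshold = classprob_threshold,
              loss_weights = loss_weights, lr = lr, weight_decay = weight_decay)
  cfg$grids <- input_size %/% c(32L, 16L, 8L)
  cfg$out_channels <- 25L + cfg$n_classes
  class(cfg) <- "yolo_config"
  cfg
}

yolo_nodes <- function(cfg) {
  w <- cfg$width_multiplier
  ch <- function(n) max(2L, as.integer(round(n * w)))
  oc <- cfg$out_channels
  res <- function(tag, from, cmid, cfull) {
    list(nn_node(paste0(tag, "a"), "conv", from, k = 1, cout = ch(cmid)),
         nn_node(paste0(tag, "b"), "conv", paste0(tag, "a"), k = 3, cout = ch(cfull)),
         nn_node(paste0(tag, "add"), "add", c(from, paste0(tag, "b"))))
  }
  c(
    list(nn_node("c1", "conv", ".input", k = 3, cout = ch(32)),
         nn_node("c2", "conv", "c1", k = 3, stride = 2, cout = ch(64))),
    res("r1", "c2", 32, 64),
    list(nn_node("c3", "conv", "r1add", k = 3, stride = 2, cout = ch(128))),
    res("r2", "c3", 64, 128),
    list(nn_node("c4", "conv", "r2add", k = 3, stride = 2, cout = ch(256))),
    res("r3", "c4", 128, 256),
    list(nn_node("c5", "conv", "r3add", k = 3, stride = 2, cout = ch(512))),
    res("r4", "c5", 256, 512),
    list(nn_node("c6", "conv", "r4add", k = 3, stride = 2, cout = ch(1024))),
    res("r5", "c6", 512, 1024),
    list(
      nn_node("c7", "conv", "r5add", k = 1, cout = ch(512)),
      nn_node("c8", "conv", "c7", k = 3, cout = ch(1024)),
      nn_node("spd1a", "conv", "c8", k = 3, cout = ch(512)),
      nn_node("spd1", "head", "spd1a", k = 1, cout = oc),
      nn_node("c9", "conv", "c7", k = 1, cout = ch(256)),
      nn_node("u1", "upsample", "c9"),
      nn_node("cat1", "concat", c("u1", "r4add")),
      nn_node("c10", "conv", "cat1", k = 1, cout = ch(256)),
      nn_node("c11", "conv", "c10", k = 3, cout = ch(512)),
      nn_node("spd2a", "conv", "c11", k = 3, cout = ch(512)),
      nn_node("spd2", "head", "spd2a", k = 1, cout = oc),
      nn_node("c12", "conv", "c11", k = 1, cout = ch(128)),
      nn_node("u2", "upsample", "c12"),
      nn_node("cat2", "concat", c("u2", "r3add")),
      nn_node("c13", "conv", "cat2", k = 1, cout = ch(128)),
      nn_node("c14", "conv", "c13", k = 3, cout = ch(256)),
      nn_node("spd3", "head", "c14", k = 1, cout = oc)
    )
  )
}

#' Build the volumetric YOLOv3-style detection network
#'
#' A 3D scaling of the YOLOv3 layout: convolutional blocks with five stride-2
#' stages and one residual block per stage for feature learning, detection
#' heads at three scales, and two upsample-and-concatenate paths feeding the
#' finer scales. At the default input of 160^3 voxels the heads produce grids
#' of 5^3, 10^3 and 20^3 cells (input/32, /16, /8).
#'
#' @param cfg a \code{\link{yolo_config}}.
#' @param seed RNG seed for the Kaiming-style weight initialization.
#' @return A network handle usable with \code{\link{yolo_forward}},
#'   \code{\link{train_yolo3d}} and \code{\link{infer_yolo}}.
#' @export
build_yolo3d <- function(cfg = yolo_config(), seed = NULL) {
  nodes <- yolo_nodes(cfg)
  net <- new_network(nodes, outputs = c("spd1", "spd2", "spd3"),
                     input_dim = c(rep(cfg$input_size, 3), 1L),
                     seed = seed, cfg = cfg)
  # head bias priors: objectness starts at a low prior probability (objects
  # are rare among cells) and the plane components at the canonical
  # anatomical frame (axial normal cranio-caudal), so the regression learns
  # deviations from the standard orientation
  for (h in c("spd1", "spd2", "spd3")) {
    b <- net$params[[h]]$b
    b[7] <- log(0.01 / 0.99)
    b[(8 + cfg$n_classes):cfg$out_channels] <-
      c(1, 0, 0, 0, 1, 0, 0, 0, 1, 1, 0, 0, 0, 1, 0, 0, 0, 1)
    net$params[[h]]$b <- b
  }
  class(net) <- c("yolo3d_net", class(net))
  net
}

#' Per-scale grid sizes and candidate count of a detector configuration
#'
#' @param cfg a \code{\link{yolo_config}}.
#' @return List with \code{grids} (cells per axis at the three heads) and
#'   \code{n_candidates} (total single-anchor predictions, e.g. 9125 at
#'   160^3: 5^3 + 10^3 + 20^3).
#' @export
yolo_candidates <- function(cfg) {
  list(grids = cfg$grids, n_candidates = sum(cfg$grids^3))
}

#' Run the detector forward
#'
#' @param net a \code{\link{build_yolo3d}} network.
#' @param volume numeric 3D array of \code{input_size}^3 intensities.
#' @return List of three raw output arrays (G, G, G, 25 + n_classes).
#' @export
yolo_forward <- function(net, volume) {
  net_forward(net, volume, cache = FALSE)$outputs
}

# --- target encoding --------------------------------------------------------

# IoU between co-centered cubes: used to pick the responsible scale.
size_iou <- function(extent, anchor) {
  inter <- prod(pmin(extent, anchor))
  inter / (prod(extent) + anchor^3 - inter)
}

#' Encode annotations into per-scale grid targets
#'
#' Each vertebra is assigned to the scale whose cubic anchor has the largest
#' size-IoU with its (normalized) box, and within that scale to the cell
#' containing its center. The responsible cell stores objectness 1, the
#' center offset within the cell, log extent ratios relative to the anchor,
#' a class one-hot and the 18 plane spanning-vector components; all other
#' cells are zero. If two vertebrae land in the same cell the larger one is
#' kept with a warning.
#'
#' @param annotations list of \code{\link{vertebra_annotation}} objects.
#' @param cfg a \code{\link{yolo_config}}.
#' @param dim,spacing,origin geometry of the patch the annotations live in
#'   (used to normalize world-mm centers/extents).
#' @return List of three target arrays (G, G, G, 25 + n_classes) with an
#'   \code{obj_cells} attribute listing responsible cells.
#' @export
encode_yolo_targets <- function(annotations, cfg, dim = cfg$input_size,
                                spacing = 1, origin = c(0, 0, 0)) {
  dim <- rep(dim, length.out = 3)
  oc <- cfg$out_channels
  tg <- lapply(cfg$grids, function(G) array(0, c(G, G, G, oc)))
  occupied <- lapply(seq_len(3), function(i) list())  # key -> volume
  cells <- NULL
  for (a in annotations) {
    cn <- norm_from_world(a$center_mm, dim, spacing, origin)
    en <- a$extent_mm / (dim * spacing)
    if (any(cn < 0) || any(cn >= 1)) stop("annotation center outside the patch")
    sc <- which.max(vapply(cfg$anchors, function(an) size_iou(en, an), 0))
    G <- cfg$grids[sc]
    cell <- pmin(floor(cn * G), G - 1)  # 0-based
    key <- paste(cell, collapse = ",")
    vol <- prod(a$extent_mm)
    prev <- occupied[[sc]][[key]]
    if (!is.null(prev)) {
      if (prev >= vol) { warning("two vertebrae map to one cell; keeping the larger"); next }
      warning("two vertebrae map to one cell; keeping the larger")
    }
    occupied[[sc]][[key]] <- vol
    i <- cell + 1
    tg[[sc]][i[1], i[2], i[3], ] <- c(
      cn * G - cell,                       # offset within cell, in [0,1)
      log(en / cfg$anchors[sc]),           # extents relative to anchor
      1,                                   # objectness
      as.numeric(seq_len(cfg$n_classes) == a$class_id),
      triplet_components(a$planes))
    cells <- rbind(cells, c(scale = sc, cell))
  }
  attr(tg, "obj_cells") <- cells
  tg
}

triplet_components <- function(tp) {
  c(tp$axial$u, tp$axial$v, tp$coronal$u, tp$coronal$v, tp$sagittal$u, tp$sagittal$v)
}

triplet_from_components <- function(v) {
  plane_triplet(axial = list(u = v[1:3], v = v[4:6]),
                coronal = list(u = v[7:9], v = v[10:12]),
                sagittal = list(u = v[13:15], v = v[16:18]))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# --- decoding ---------------------------------------------------------------

#' Decode raw detector outputs into candidate detections
#'
#' Per cell: center = (sigmoid(t_xyz) + cell) / G, extents =
#' anchor * exp(t_whd), objectness and class probabilities through the
#' logistic function. Plane spanning vectors are taken linearly and
#' orthonormalized (\code{\link{orthonormalize_triplet}}).
#'
#' @param raw list of three raw output arrays from \code{\link{yolo_forward}}.
#' @param cfg a \code{\link{yolo_config}}.
#' @param orthonormalize orthonormalize the decoded triplets (disable only
#'   for round-trip diagnostics).
#' @return A data frame of candidate detections, one row per grid cell, with
#'   normalized box columns \code{cx,cy,cz,ex,ey,ez}, \code{objectness},
#'   class probability columns \code{p1..pK}, \code{class_id}, \code{score},
#'   scale/cell bookkeeping and 18 plane component columns \code{pl1..pl18}.
#' @export
decode_yolo_output <- function(raw, cfg, orthonormalize = TRUE) {
  stopifnot(length(raw) == 3)
  out <- vector("list", 3)
  for (s in 1:3) {
    x <- raw[[s]]
    G <- cfg$grids[s]
    if (!identical(as.integer(dim(x)), as.integer(c(G, G, G, cfg$out_channels))))
      stop("raw output shape does not match the configured grid at scale ", s)
    cells <- as.matrix(expand.grid(cx = 0:(G - 1), cy = 0:(G - 1), cz = 0:(G - 1)))
    m <- matrix(x, ncol = cfg$out_channels)  # rows ordered like expand.grid
    ctr <- (sigmoid(m[, 1:3]) + cells) / G
    ext <- cfg$anchors[s] * exp(pmin(m[, 4:6], 8))
    obj <- sigmoid(m[, 7])
    cls <- sigmoid(m[, 8:(7 + cfg$n_classes), drop = FALSE])
    pl <- m[, (8 + cfg$n_classes):cfg$out_channels, drop = FALSE]
    df <- data.frame(cx = ctr[, 1], cy = ctr[, 2], cz = ctr[, 3],
                     ex = ext[, 1], ey = ext[, 2], ez = ext[, 3],
                     objectness = obj)
    colnames(cls) <- paste0("p", seq_len(cfg$n_classes))
    df <- cbind(df, cls)
    df$class_id <- max.col(cls, ties.method = "first")
    df$score <- obj
    df$scale <- s
    df$cell_x <- cells[, 1]; df$cell_y <- cells[, 2]; df$cell_z <- cells[, 3]
    colnames(pl) <- paste0("pl", 1:18)
    out[[s]] <- cbind(df, pl)
  }
  dets <- do.call(rbind, out)
  rownames(dets) <- NULL
  if (orthonormalize) dets <- orthonormalize_rows(dets)
  class(dets) <- c("spine_detections", class(dets))
  dets
}

orthonormalize_rows <- function(dets) {
  if (!nrow(dets)) return(dets)
  pl <- as.matrix(dets[, paste0("pl", 1:18)])
  for (i in seq_len(nrow(pl))) {
    tp <- orthonormalize_triplet(triplet_from_components(pl[i, ]))
    pl[i, ] <- triplet_components(tp)
  }
  dets[, paste0("pl", 1:18)] <- pl
  dets
}

# --- loss -------------------------------------------------------------------

bce_logit <- function(t, y) {
  # numerically stable binary cross-entropy with logits
  pmax(t, 0) - t * y + log1p(exp(-abs(t)))
}

#' Detection loss with per-term breakdown
#'
#' The total loss is the weighted sum of seven terms: objectness at object
#' cells (OL) and non-object cells (NOL), both binary cross-entropy; mean
#' squared error on the decoded box parameters (BL); class cross-entropy
#' (CL); and the mean squared error of each plane's spanning vectors at
#' object cells (APL, CPL, SPL; each plane's 6 squared component errors are
#' divided by the 18 total spanning components). Default weights follow the
#' YOLOv3 convention: OL = CL = APL = CPL = SPL = 1 and NOL = BL = 10.
#'
#' @param raw list of three raw output arrays.
#' @param targets targets from \code{\link{encode_yolo_targets}}.
#' @param cfg a \code{\link{yolo_config}}.
#' @param weights loss weights (defaults from \code{cfg}).
#' @param grad also return gradients with respect to the raw outputs.
#' @return List with the seven terms, \code{total}, and (when
#'   \code{grad = TRUE}) a \code{grads} list of per-scale arrays.
#' @export
yolo_loss <- function(raw, targets, cfg, weights = cfg$loss_weights, grad = FALSE) {
  terms <- c(OL = 0, NOL = 0, BL = 0, CL = 0, APL = 0, CPL = 0, SPL = 0)
  grads <- if (grad) vector("list", 3)
  n_obj_total <- 0
  # accumulators: term sums over scales; object terms averaged over all
  # object cells of the whole volume, NOL over all non-object cells
  acc <- list(OL = 0, NOL = 0, nno = 0, BL = 0, CL = 0, APL = 0, CPL = 0, SPL = 0)
  per_scale <- list()
  for (s in 1:3) {
    x <- raw[[s]]; t <- targets[[s]]
    stopifnot(identical(dim(x), dim(t)))
    G <- cfg$grids[s]
    nc <- cfg$n_classes
    m <- matrix(x, ncol = cfg$out_channels)
    tm <- matrix(t, ncol = cfg$out_channels)
    objmask <- tm[, 7] == 1
    nobj <- sum(objmask)
    n_obj_total <- n_obj_total + nobj
    gm <- if (grad) matrix(0, nrow(m), ncol(m))
    # objectness
    acc$OL <- acc$OL + sum(bce_logit(m[objmask, 7], 1))
    acc$NOL <- acc$NOL + sum(bce_logit(m[!objmask, 7], 0))
    acc$nno <- acc$nno + sum(!objmask)
    if (grad) {
      p <- sigmoid(m[, 7])
      gm[objmask, 7] <- (p[objmask] - 1)   # d OL sum / d t
      gm[!objmask, 7] <- p[!objmask]       # d NOL sum / d t
    }
    if (nobj > 0) {
      idx <- which(objmask)
      cells <- as.matrix(expand.grid(0:(G - 1), 0:(G - 1), 0:(G - 1)))[idx, , drop = FALSE]
      # decoded box vs target box (normalized patch coordinates)
      so <- sigmoid(m[idx, 1:3, drop = FALSE])
      cpred <- (so + cells) / G
      ctgt <- (tm[idx, 1:3, drop = FALSE] + cells) / G
      lw <- pmin(m[idx, 4:6, drop = FALSE], 8)
      epred <- cfg$anchors[s] * exp(lw)
      etgt <- cfg$anchors[s] * exp(tm[idx, 4:6, drop = FALSE])
      acc$BL <- acc$BL + sum((cpred - ctgt)^2 + (epred - etgt)^2) / 6
      # class
      tcl <- tm[idx, 8:(7 + nc), drop = FALSE]
      acc$CL <- acc$CL + sum(bce_logit(m[idx, 8:(7 + nc), drop = FALSE], tcl)) / nc
      # planes
      pidx <- (8 + nc):cfg$out_channels
      dpl <- m[idx, pidx, drop = FALSE] - tm[idx, pidx, drop = FALSE]
      acc$APL <- acc$APL + sum(dpl[, 1:6]^2) / 18
      acc$CPL <- acc$CPL + sum(dpl[, 7:12]^2) / 18
      acc$SPL <- acc$SPL + sum(dpl[, 13:18]^2) / 18
      if (grad) {
        gm[idx, 1:3] <- (2 / 6) * (cpred - ctgt) * so * (1 - so) / G
        gm[idx, 4:6] <- (2 / 6) * (epred - etgt) * epred * (lw < 8)
        pcl <- sigmoid(m[idx, 8:(7 + nc), drop = FALSE])
        gm[idx, 8:(7 + nc)] <- (pcl - tcl) / nc
        gm[idx, pidx] <- (2 / 18) * dpl
      }
    }
    per_scale[[s]] <- list(gm = gm, dims = dim(x), nobj = nobj)
  }
  w <- weights
  n_obj <- max(n_obj_total, 1)
  n_no <- max(acc$nno, 1)
  terms["OL"] <- acc$OL / n_obj
  terms["NOL"] <- acc$NOL / n_no
  terms["BL"] <- acc$BL / n_obj
  terms["CL"] <- acc$CL / n_obj
  terms["APL"] <- acc$APL / n_obj
  terms["CPL"] <- acc$CPL / n_obj
  terms["SPL"] <- acc$SPL / n_obj
  total <- sum(unlist(w[names(terms)]) * terms)
  res <- as.list(terms)
  res$total <- total
  if (grad) {
    for (s in 1:3) {
      gm <- per_scale[[s]]$gm
      tmm <- matrix(targets[[s]], ncol = cfg$out_channels)
      objmask <- tmm[, 7] == 1
      # scale object-cell gradients by their weights / n_obj, NOL by w/ n_no
      gm[objmask, 7] <- gm[objmask, 7] * w$OL / n_obj
      gm[!objmask, 7] <- gm[!objmask, 7] * w$NOL / n_no
      if (any(objmask)) {
        idx <- which(objmask)
        nc <- cfg$n_classes
        gm[idx, 1:6] <- gm[idx, 1:6] * w$BL / n_obj
        gm[idx, 8:(7 + nc)] <- gm[idx, 8:(7 + nc)] * w$CL / n_obj
        pidx <- (8 + nc):cfg$out_channels
        gm[idx, pidx[1:6]] <- gm[idx, pidx[1:6]] * w$APL / n_obj
        gm[idx, pidx[7:12]] <- gm[idx, pidx[7:12]] * w$CPL / n_obj
        gm[idx, pidx[13:18]] <- gm[idx, pidx[13:18]] * w$SPL / n_obj
      }
      dim(gm) <- per_scale[[s]]$dims
      grads[[s]] <- gm
    }
    names(grads) <- c("spd1", "spd2", "spd3")
    res$grads <- grads
  }
  res
}

# --- selection --------------------------------------------------------------

#' Select final detections by confidence, NMS and class probability
#'
#' Keeps candidates with objectness at or above \code{conf_thr}, applies
#' per-class greedy non-max suppression with objectness as the score, then
#' drops survivors whose maximum class probability falls below
#' \code{classprob_thr}. The defaults (0.10, 0.15, 0.25) are the operating
#' point found by hyperparameter search.
#'
#' @param dets candidate detections from \code{\link{decode_yolo_output}}.
#' @param conf_thr objectness threshold.
#' @param iou_thr NMS IoU threshold.
#' @param classprob_thr class-probability threshold applied after NMS.
#' @param cfg optional \code{\link{yolo_config}} supplying the defaults.
#' @return The surviving detections, sorted by decreasing objectness, with a
#'   \code{counts} attribute logging the size after each stage.
#' @export
select_detections <- function(dets, conf_thr = NULL, iou_thr = NULL,
                              classprob_thr = NULL, cfg = NULL) {
  conf_thr <- conf_thr %||% cfg$conf_threshold %||% 0.10
  iou_thr <- iou_thr %||% cfg$iou_threshold %||% 0.15
  classprob_thr <- classprob_thr %||% cfg$classprob_threshold %||% 0.25
  counts <- c(candidates = nrow(dets))
  kept <- dets[dets$objectness >= conf_thr, , drop = FALSE]
  counts["after_confidence"] <- nrow(kept)
  kept$score <- kept$objectness
  kept <- nms3d(kept, iou_thr)
  counts["after_nms"] <- nrow(kept)
  pcols <- grep("^p[0-9]+$", names(kept))
  if (nrow(kept)) {
    pmaxv <- do.call(pmax, kept[pcols])
    kept <- kept[pmaxv >= classprob_thr, , drop = FALSE]
  }
  counts["after_classprob"] <- nrow(kept)
  attr(kept, "stage_counts") <- counts
  kept
}

#' Convert selected detections to world-frame annotations
#'
#' @param dets selected detections (normalized patch frame).
#' @param dim,spacing,origin patch geometry used to map back to world mm.
#' @return List of \code{\link{vertebra_annotation}} objects.
#' @export
detections_to_annotations <- function(dets, dim, spacing, origin = c(0, 0, 0)) {
  dim <- rep(dim, length.out = 3)
  lapply(seq_len(nrow(dets)), function(i) {
    r <- dets[i, ]
    vertebra_annotation(
      class_id = r$class_id,
      center_mm = world_from_norm(c(r$cx, r$cy, r$cz), dim, spacing, origin),
      extent_mm = c(r$ex, r$ey, r$ez) * dim * spacing,
      planes = triplet_from_components(as.numeric(r[paste0("pl", 1:18)])))
  })
}
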