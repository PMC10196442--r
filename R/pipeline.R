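# Training loops and end-to-end inference for both pipelines.

#' Train the volumetric detector
#'
#' Adam on the seven-term detection loss, one sample at a time with
#' gradients accumulated over a mini-batch. Volumes are min-max normalized
#' to [0, 1] before the forward pass; the same normalization is applied at
#' inference.
#'
#' @param samples list of training samples; each needs \code{volume} (array
#'   of \code{cfg$input_size}^3 voxels), \code{annotations}, \code{spacing}
#'   (phantom samples qualify directly).
#' @param cfg a \code{\link{yolo_config}}.
#' @param net optionally continue training an existing network.
#' @param steps number of optimizer steps.
#' @param batch_size samples per step (cycled deterministically when
#'   \code{shuffle = FALSE}).
#' @param lr,weight_decay Adam settings (defaults from \code{cfg}).
#' @param augment optional \code{\link{augment_config}} applied on the fly.
#' @param shuffle draw batches at random instead of cycling.
#' @param seed RNG seed covering initialization, shuffling and augmentation.
#' @param verbose print the loss breakdown every \code{verbose} steps (0 =
#'   silent).
#' @param clip_norm global gradient-norm clip (guards the box-extent
#'   exponential against transient explosions; \code{Inf} disables).
#' @return List with \code{net} and \code{history} (one row per step with
#'   all loss terms).
#' @export
train_yolo3d <- function(samples, cfg = yolo_config(), net = NULL,
                         steps = 100L, batch_size = 2L, lr = cfg$lr,
                         weight_decay = cfg$weight_decay, augment = NULL,
                         shuffle = TRUE, seed = NULL, verbose = 0L,
                         clip_norm = 10) {
  with_seed(seed, {
    if (is.null(net)) net <- build_yolo3d(cfg, seed = NULL)
    state <- adam_init(net)
    hist <- vector("list", steps)
    targets_cache <- vector("list", length(samples))
    order_idx <- 0L
    for (step in seq_len(steps)) {
      idx <- if (shuffle) sample.int(length(samples), min(batch_size, length(samples)))
             else (order_idx + seq_len(batch_size) - 1L) %% length(samples) + 1L
      order_idx <- (order_idx + batch_size) %% length(samples)
      agg <- NULL
      terms <- NULL
      for (i in idx) {
        s <- samples[[i]]
        vol <- s$volume
        anns <- s$annotations
        if (!is.null(augment)) {
          au <- augment_sample(vol, anns, cfg = augment, spacing = s$spacing)
          vol <- au$volume; anns <- au$annotations
        }
        vol <- normalize01(vol)
        tg <- if (is.null(augment) && !is.null(targets_cache[[i]])) {
          targets_cache[[i]]
        } else {
          t0 <- encode_yolo_targets(anns, cfg, dim = dim(vol), spacing = s$spacing)
          if (is.null(augment)) targets_cache[[i]] <- t0
          t0
        }
        fwd <- net_forward(net, vol, cache = TRUE)
        ls <- yolo_loss(fwd$outputs, tg, cfg, grad = TRUE)
        g <- net_backward(net, fwd, ls$grads)
        agg <- if (is.null(agg)) g else add_grads(agg, g)
        tvec <- unlist(ls[c("OL", "NOL", "BL", "CL", "APL", "CPL", "SPL", "total")])
        terms <- if (is.null(terms)) tvec else terms + tvec
      }
      agg <- scale_grads(agg, 1 / length(idx))
      if (is.finite(clip_norm) && clip_norm > 0) {
        gn <- sqrt(sum(vapply(agg, function(p)
          sum(vapply(p, function(g) sum(g * g), 0)), 0)))
        if (gn > clip_norm) agg <- scale_grads(agg, clip_norm / gn)
      }
      st <- adam_step(net, agg, state, lr = lr, weight_decay = weight_decay)
      net <- st$net; state <- st$state
      hist[[step]] <- terms / length(idx)
      if (verbose > 0 && step %% verbose == 0)
        message(sprintf("step %d  total %.4f  (OL %.3f NOL %.3f BL %.3f CL %.3f pl %.3f)",
                        step, hist[[step]]["total"], hist[[step]]["OL"],
                        hist[[step]]["NOL"], hist[[step]]["BL"], hist[[step]]["CL"],
                        hist[[step]]["APL"] + hist[[step]]["CPL"] + hist[[step]]["SPL"]))
    }
    history <- as.data.frame(do.call(rbind, hist))
    history$step <- seq_len(steps)
    list(net = net, history = history)
  })
}

normalize01 <- function(v) {
  r <- range(v)
  if (r[2] - r[1] < 1e-12) return(v * 0)
  out <- (v - r[1]) / (r[2] - r[1])
  dim(out) <- dim(v)
  out
}

add_grads <- function(a, b) {
  for (nm in names(b)) for (pn in names(b[[nm]]))
    a[[nm]][[pn]] <- a[[nm]][[pn]] + b[[nm]][[pn]]
  a
}

scale_grads <- function(a, f) {
  for (nm in names(a)) for (pn in names(a[[nm]]))
    a[[nm]][[pn]] <- a[[nm]][[pn]] * f
  a
}

#' Detect vertebrae and standard planes in a volume
#'
#' Resamples the volume to the detector input size (trilinear), normalizes
#' intensities, runs the network, decodes all candidate cells, applies
#' confidence filtering, per-class NMS and the class-probability threshold,
#' and maps the survivors back to world millimetres.
#'
#' @param net a trained \code{\link{build_yolo3d}} network.
#' @param vh a \code{\link{volume_handle}} (or bare array with unit
#'   spacing).
#' @param cfg the \code{\link{yolo_config}} (defaults to the one stored in
#'   the network).
#' @return List of predicted \code{\link{vertebra_annotation}}; attribute
#'   \code{stage_counts} logs candidate counts through the filter stages,
#'   attribute \code{detections} keeps the selected rows.
#' @export
infer_yolo <- function(net, vh, cfg = net$cfg) {
  if (!inherits(vh, "volume_handle")) vh <- volume_handle(vh)
  rs <- if (!all(dim(vh$data) == cfg$input_size)) resample_volume(vh, cfg$input_size) else vh
  raw <- yolo_forward(net, normalize01(rs$data))
  dets <- decode_yolo_output(raw, cfg)
  sel <- select_detections(dets, cfg = cfg)
  anns <- detections_to_annotations(sel, dim = dim(vh$data),
                                    spacing = vh$spacing[1], origin = vh$origin)
  attr(anns, "stage_counts") <- attr(sel, "stage_counts")
  attr(anns, "detections") <- sel
  anns
}

#' Train the plane-segmentation network
#'
#' Mini-batch gradient descent with momentum on the summed per-channel
#' cross-entropy + Dice loss.
#'
#' @param samples list of samples with \code{volume} and \code{masks}
#'   (phantom samples qualify).
#' @param net a \code{\link{build_segnet}} network (built when \code{NULL}).
#' @param steps,batch_size,lr,momentum optimizer settings.
#' @param patch_size,depth,width network settings when building.
#' @param seed RNG seed.
#' @param verbose print loss every \code{verbose} steps.
#' @return List with \code{net} and \code{history}.
#' @export
train_segnet <- function(samples, net = NULL, steps = 100L, batch_size = 2L,
                         lr = 1e-3, momentum = 0.99, patch_size = 64L,
                         depth = 3L, width = 16L, seed = NULL, verbose = 0L) {
  with_seed(seed, {
    if (is.null(net)) net <- build_segnet(patch_size, depth, width, seed = NULL)
    state <- sgd_init(net)
    hist <- numeric(steps)
    for (step in seq_len(steps)) {
      idx <- sample.int(length(samples), min(batch_size, length(samples)))
      agg <- NULL; tot <- 0
      for (i in idx) {
        s <- samples[[i]]
        fwd <- net_forward(net, normalize01(s$volume), cache = TRUE)
        ls <- seg_loss(fwd$outputs$seg_out, s$masks, grad = TRUE)
        g <- net_backward(net, fwd, list(seg_out = ls$grad))
        agg <- if (is.null(agg)) g else add_grads(agg, g)
        tot <- tot + ls$total
      }
      agg <- scale_grads(agg, 1 / length(idx))
      st <- sgd_step(net, agg, state, lr = lr, momentum = momentum)
      net <- st$net; state <- st$state
      hist[step] <- tot / length(idx)
      if (verbose > 0 && step %% verbose == 0)
        message(sprintf("seg step %d  loss %.4f", step, hist[step]))
    }
    list(net = net, history = data.frame(step = seq_len(steps), total = hist))
  })
}

#' Segment a volume and extract vertebra plane parameters
#'
#' Sliding-window inference with 50 percent window overlap and averaged
#' logits, per-channel argmax to label masks, then the clustering /
#' filtering / grouping / centroid / PCA chain.
#'
#' @param net a trained \code{\link{build_segnet}}.
#' @param vh a \code{\link{volume_handle}} or bare array.
#' @param eps,min_samples DBSCAN parameters.
#' @return Predicted annotations as in \code{\link{segplane_extract}}; the
#'   predicted \code{\link{plane_channel_masks}} are attached as an
#'   attribute.
#' @export
infer_seg <- function(net, vh, eps = 2, min_samples = 10) {
  if (!inherits(vh, "volume_handle")) vh <- volume_handle(vh)
  ps <- net$cfg$patch_size
  nc <- net$cfg$n_classes
  dm <- dim(vh$data)
  if (any(dm < ps)) stop("volume smaller than the segmentation patch size")
  vol <- normalize01(vh$data)
  logits <- array(0, c(dm, 3L * nc))
  wsum <- array(0, dm)
  starts <- lapply(dm, function(n) {
    s <- unique(pmin(seq(1L, n, by = ps %/% 2L), n - ps + 1L))
    s[s >= 1]
  })
  for (sx in starts[[1]]) for (sy in starts[[2]]) for (sz in starts[[3]]) {
    px <- sx:(sx + ps - 1); py <- sy:(sy + ps - 1); pz <- sz:(sz + ps - 1)
    out <- net_forward(net, vol[px, py, pz], cache = FALSE)$outputs$seg_out
    logits[px, py, pz, ] <- logits[px, py, pz, ] + out
    wsum[px, py, pz] <- wsum[px, py, pz] + 1
  }
  logits <- logits / as.numeric(wsum)
  masks <- logits_to_masks(logits, nc, vh$spacing[1], vh$origin)
  anns <- segplane_extract(masks, eps = eps, min_samples = min_samples)
  attr(anns, "masks") <- masks
  anns
}

# Per-channel argmax over class logits -> label masks (0..n_classes-1).
logits_to_masks <- function(logits, n_classes, spacing, origin) {
  dm <- dim(logits)[1:3]
  ch <- lapply(1:3, function(c3) {
    sl <- (c3 - 1) * n_classes + seq_len(n_classes)
    m <- matrix(logits[, , , sl], ncol = n_classes)
    lab <- max.col(m, ties.method = "first") - 1L
    array(lab, dm)
  })
  plane_channel_masks(ch[[1]], ch[[2]], ch[[3]], spacing, origin)
}

#' Save / load a trained network
#'
#' Networks are plain R lists; they serialize with \code{saveRDS}.
#'
#' @param net a network handle.
#' @param path an \code{.rds} path.
#' @export
save_model <- function(net, path) {
  saveRDS(net, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)

#' File-based detector inference
#'
#' Loads a volume, runs \code{\link{infer_yolo}} and writes the shared
#' annotation JSON; per-stage candidate counts are logged.
#'
#' @param volume_path input volume file.
#' @param net trained network (or path to an \code{.rds}).
#' @param out_path output JSON path.
#' @param cfg optional \code{\link{yolo_config}} override.
#' @return The predicted annotations, invisibly.
#' @export
run_infer_yolo <- function(volume_path, net, out_path, cfg = NULL) {
  if (is.character(net)) {
    if (!file.exists(net)) stop("model file not found: ", net)
    net <- load_model(net)
  }
  vh <- load_volume(volume_path)
  anns <- infer_yolo(net, vh, cfg = cfg %||% net$cfg)
  counts <- attr(anns, "stage_counts")
  message("detector candidates: ", paste(names(counts), counts, sep = "=", collapse = ", "))
  write_annotations(anns, out_path, spacing = vh$spacing[1], origin = vh$origin)
  invisible(anns)
}

#' File-based segmentation inference
#'
#' @inheritParams run_infer_yolo
#' @param eps,min_samples DBSCAN parameters.
#' @return The predicted annotations, invisibly.
#' @export
run_infer_seg <- function(volume_path, net, out_path, eps = 2, min_samples = 10) {
  if (is.character(net)) {
    if (!file.exists(net)) stop("model file not found: ", net)
    net <- load_model(net)
  }
  vh <- load_volume(volume_path)
  anns <- infer_seg(net, vh, eps = eps, min_samples = min_samples)
  counts <- attr(anns, "stage_counts")
  message("cluster stages: ", paste(names(counts), counts, sep = "=", collapse = ", "))
  write_annotations(anns, out_path, spacing = vh$spacing[1], origin = vh$origin)
  invisible(anns)
}

#' Run the scaled-down end-to-end detection study
#'
#' Generates seeded training and held-out phantom suites at 64^3 over a
#' 64 mm field of view, trains the detector (width multiplier 0.25, anchors
#' at the full-scale millimetre sizes) with a three-phase Adam schedule, and
#' evaluates detection, localization and orientation on the held-out suite.
#' See the methods vignette for why the scale-down preserves millimetre
#' rather than normalized geometry.
#'
#' @param n_train,n_test phantom suite sizes (default 200 / 50).
#' @param seed master seed; training-suite seeds are \code{seed + 0:(n_train-1)}
#'   and test-suite seeds follow after them.
#' @param steps,lrs per-phase step counts and Adam learning rates.
#' @param batch_size samples per optimizer step.
#' @param width_multiplier backbone width scale.
#' @param verbose print loss every this many steps (0 = silent).
#' @return List with the trained \code{net}, the \code{report} from
#'   \code{\link{evaluate_predictions}}, the final training \code{history}
#'   and the configuration used.
#' @export
run_scaled_study <- function(n_train = 200L, n_test = 50L, seed = 42L,
                             steps = c(250L, 150L, 150L, 50L),
                             lrs = c(2e-3, 5e-4, 1e-4, 2e-5), batch_size = 2L,
                             width_multiplier = 0.25, verbose = 0L) {
  cfg <- yolo_config(input_size = 64L, width_multiplier = width_multiplier,
                     anchors = c(0.15, 0.11, 0.07) * 2.5)
  sp <- phantom_spec(grid_size = 64L, spacing = 0.313 * 512 / 160,
                     n_vertebrae = c(1L, 4L))
  train <- suppressWarnings(phantom_suite(n_train, sp, base_seed = seed))
  test <- suppressWarnings(phantom_suite(n_test, sp, base_seed = seed + n_train))
  net <- with_seed(seed, build_yolo3d(cfg))
  history <- NULL
  for (ph in seq_along(steps)) {
    fit <- suppressWarnings(train_yolo3d(train, cfg, net = net,
                                         steps = steps[ph],
                                         batch_size = batch_size,
                                         lr = lrs[ph], seed = seed + 900 + ph,
                                         verbose = verbose))
    net <- fit$net
    history <- rbind(history, fit$history)
  }
  preds <- lapply(test, function(s)
    suppressWarnings(infer_yolo(net, volume_handle(s$volume, s$spacing))))
  report <- evaluate_predictions(preds, lapply(test, `[[`, "annotations"))
  list(net = net, report = report, history = history, cfg = cfg,
       phantom_spec = sp)
}
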