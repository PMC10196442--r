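# Study metrics: detection, classification, localization and orientation
# errors between predicted and ground-truth vertebrae.

#' Match predicted to ground-truth vertebrae
#'
#' Greedy one-to-one matching by ascending center-to-center distance; a pair
#' is only valid when the predicted center lies inside the ground-truth box.
#' Unmatched predictions are false positives, unmatched ground truths false
#' negatives. The criterion is parameter-free and agnostic to which pipeline
#' produced the predictions.
#'
#' @param preds,gts lists of \code{\link{vertebra_annotation}} (world mm).
#' @return List with \code{pairs} (two-column matrix of prediction / ground
#'   truth indices), \code{fp} and \code{fn} index vectors.
#' @export
match_predictions <- function(preds, gts) {
  np <- length(preds); ng <- length(gts)
  if (np == 0 || ng == 0)
    return(list(pairs = matrix(integer(0), 0, 2,
                               dimnames = list(NULL, c("pred", "gt"))),
                fp = seq_len(np), fn = seq_len(ng)))
  D <- matrix(Inf, np, ng)
  for (i in seq_len(np)) for (j in seq_len(ng)) {
    d <- preds[[i]]$center_mm - gts[[j]]$center_mm
    inside <- all(abs(d) <= gts[[j]]$extent_mm / 2)
    if (inside) D[i, j] <- sqrt(sum(d * d))
  }
  pairs <- NULL
  while (any(is.finite(D))) {
    k <- arrayInd(which.min(D), dim(D))
    pairs <- rbind(pairs, k)
    D[k[1], ] <- Inf
    D[, k[2]] <- Inf
  }
  if (is.null(pairs)) pairs <- matrix(integer(0), 0, 2)
  colnames(pairs) <- c("pred", "gt")
  list(pairs = pairs,
       fp = setdiff(seq_len(np), pairs[, 1]),
       fn = setdiff(seq_len(ng), pairs[, 2]))
}

#' Detection metrics from a match result
#'
#' Detection has no true negatives, so accuracy is defined as
#' TP / (TP + FP + FN); recall = TP / (TP + FN), precision = TP / (TP + FP),
#' error rate = 1 - accuracy. With no predictions and no ground truth all
#' metrics are 1 by convention.
#'
#' @param m a \code{\link{match_predictions}} result.
#' @return Named numeric vector: accuracy, error_rate, recall, precision.
#' @export
detection_metrics <- function(m) {
  tp <- nrow(m$pairs); fp <- length(m$fp); fn <- length(m$fn)
  if (tp + fp + fn == 0) {
    message("empty evaluation: no predictions and no ground truth; metrics set to 1")
    return(c(accuracy = 1, error_rate = 0, recall = 1, precision = 1))
  }
  acc <- tp / (tp + fp + fn)
  rec <- if (tp + fn > 0) tp / (tp + fn) else 1
  prec <- if (tp + fp > 0) tp / (tp + fp) else 1
  c(accuracy = acc, error_rate = 1 - acc, recall = rec, precision = prec)
}

#' Classification metrics over correctly detected vertebrae
#'
#' Builds the 3 x 3 confusion matrix over matched pairs only, then computes
#' accuracy (trace / total), error rate, and macro-averaged recall and
#' precision.
#'
#' @param m a match result.
#' @param preds,gts the annotation lists used for matching.
#' @return List with \code{confusion} and named \code{metrics}.
#' @export
classification_metrics <- function(m, preds, gts) {
  cm <- matrix(0L, 3, 3, dimnames = list(pred = c("C", "T", "L"), gt = c("C", "T", "L")))
  if (nrow(m$pairs) == 0) {
    message("no matched vertebrae: classification metrics undefined, reported as 0")
    return(list(confusion = cm,
                metrics = c(accuracy = 0, error_rate = 0, recall = 0, precision = 0)))
  }
  for (r in seq_len(nrow(m$pairs))) {
    pc <- preds[[m$pairs[r, 1]]]$class_id
    gc <- gts[[m$pairs[r, 2]]]$class_id
    cm[pc, gc] <- cm[pc, gc] + 1L
  }
  tot <- sum(cm)
  acc <- sum(diag(cm)) / tot
  rec <- prec <- numeric(0)
  for (k in 1:3) {
    if (sum(cm[, k]) > 0) rec <- c(rec, cm[k, k] / sum(cm[, k]))
    if (sum(cm[k, ]) > 0) prec <- c(prec, cm[k, k] / sum(cm[k, ]))
  }
  list(confusion = cm,
       metrics = c(accuracy = acc, error_rate = 1 - acc,
                   recall = if (length(rec)) mean(rec) else 0,
                   precision = if (length(prec)) mean(prec) else 0))
}

#' Localization errors of matched vertebrae
#'
#' Per matched pair: the center-to-center distance d_cc and the distances of
#' the predicted center to the ground-truth axial, coronal and sagittal
#' standard planes (d_asp, d_csp, d_ssp). The summary distance d_sp_bar
#' averages the coronal and sagittal distances; by default per pair
#' (\code{(d_csp + d_ssp) / 2}, then summarized), alternatively per plane
#' (mean of the two plane-level means).
#'
#' @param m a match result.
#' @param preds,gts annotation lists.
#' @param sp_aggregation \code{"pair"} or \code{"plane"}.
#' @return List with per-pair vectors (\code{d_cc}, \code{d_asp},
#'   \code{d_csp}, \code{d_ssp}, \code{d_sp_bar}) and a mean/sd
#'   \code{summary} data frame.
#' @export
localization_errors <- function(m, preds, gts, sp_aggregation = c("pair", "plane")) {
  sp_aggregation <- match.arg(sp_aggregation)
  n <- nrow(m$pairs)
  d_cc <- d_asp <- d_csp <- d_ssp <- numeric(n)
  for (r in seq_len(n)) {
    p <- preds[[m$pairs[r, 1]]]; g <- gts[[m$pairs[r, 2]]]
    d_cc[r] <- sqrt(sum((p$center_mm - g$center_mm)^2))
    d_asp[r] <- point_to_plane_distance(p$center_mm, g$center_mm, g$planes$axial$n)
    d_csp[r] <- point_to_plane_distance(p$center_mm, g$center_mm, g$planes$coronal$n)
    d_ssp[r] <- point_to_plane_distance(p$center_mm, g$center_mm, g$planes$sagittal$n)
  }
  d_sp_bar <- (d_csp + d_ssp) / 2
  sm <- data.frame(
    metric = c("d_cc", "d_asp", "d_csp", "d_ssp", "d_sp_bar"),
    mean = c(mean(d_cc), mean(d_asp), mean(d_csp), mean(d_ssp),
             if (sp_aggregation == "pair") mean(d_sp_bar)
             else mean(c(mean(d_csp), mean(d_ssp)))),
    sd = c(sd(d_cc), sd(d_asp), sd(d_csp), sd(d_ssp), sd(d_sp_bar)))
  list(d_cc = d_cc, d_asp = d_asp, d_csp = d_csp, d_ssp = d_ssp,
       d_sp_bar = d_sp_bar, summary = sm)
}

#' Orientation errors of matched vertebrae
#'
#' Unoriented angle error between predicted and ground-truth plane normals
#' for each standard plane, plus their per-pair mean.
#'
#' @param m a match result.
#' @param preds,gts annotation lists.
#' @return List with per-pair vectors (\code{a_asp}, \code{a_csp},
#'   \code{a_ssp}, \code{a_sp_bar}, degrees) and a \code{summary} frame.
#' @export
orientation_errors <- function(m, preds, gts) {
  n <- nrow(m$pairs)
  a_asp <- a_csp <- a_ssp <- numeric(n)
  for (r in seq_len(n)) {
    p <- preds[[m$pairs[r, 1]]]; g <- gts[[m$pairs[r, 2]]]
    a_asp[r] <- plane_angle_error(p$planes$axial$n, g$planes$axial$n)
    a_csp[r] <- plane_angle_error(p$planes$coronal$n, g$planes$coronal$n)
    a_ssp[r] <- plane_angle_error(p$planes$sagittal$n, g$planes$sagittal$n)
  }
  a_sp_bar <- (a_asp + a_csp + a_ssp) / 3
  sm <- data.frame(metric = c("angle_asp", "angle_csp", "angle_ssp", "angle_sp_bar"),
                   mean = c(mean(a_asp), mean(a_csp), mean(a_ssp), mean(a_sp_bar)),
                   sd = c(sd(a_asp), sd(a_csp), sd(a_ssp), sd(a_sp_bar)))
  list(a_asp = a_asp, a_csp = a_csp, a_ssp = a_ssp, a_sp_bar = a_sp_bar,
       summary = sm)
}

#' Full evaluation report for one or many volumes
#'
#' Pools matched pairs over volumes and reports the detection,
#' classification, localization and orientation metrics.
#'
#' @param preds,gts either annotation lists (single volume) or lists of
#'   annotation lists (one element per volume, same length).
#' @return List with \code{detection}, \code{classification},
#'   \code{localization}, \code{orientation} and the pooled match counts.
#' @export
evaluate_predictions <- function(preds, gts) {
  single <- length(preds) == 0 || inherits(preds[[1]], "vertebra_annotation")
  if (single) { preds <- list(preds); gts <- list(gts) }
  stopifnot(length(preds) == length(gts))
  all_p <- list(); all_g <- list(); pairs <- NULL; fp <- 0L; fn <- 0L
  for (v in seq_along(preds)) {
    m <- match_predictions(preds[[v]], gts[[v]])
    off_p <- length(all_p); off_g <- length(all_g)
    if (nrow(m$pairs)) pairs <- rbind(pairs, m$pairs + cbind(rep(off_p, nrow(m$pairs)), off_g))
    fp <- fp + length(m$fp); fn <- fn + length(m$fn)
    all_p <- c(all_p, preds[[v]]); all_g <- c(all_g, gts[[v]])
  }
  if (is.null(pairs)) pairs <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("pred", "gt")))
  colnames(pairs) <- c("pred", "gt")
  m <- list(pairs = pairs,
            fp = seq_len(fp),  # identities are irrelevant for the counts
            fn = seq_len(fn))
  list(detection = detection_metrics(m),
       classification = classification_metrics(m, all_p, all_g),
       localization = if (nrow(pairs)) localization_errors(m, all_p, all_g),
       orientation = if (nrow(pairs)) orientation_errors(m, all_p, all_g),
       counts = c(tp = nrow(pairs), fp = fp, fn = fn))
}
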