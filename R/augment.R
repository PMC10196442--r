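# On-the-fly training augmentation. Seven transforms fire independently at
# configured probabilities, applied in a fixed order:
#   rotation/scaling -> noise -> blur -> brightness -> contrast ->
#   low-resolution simulation -> gamma.
# Geometric transforms update the volume (trilinear), the masks (nearest)
# and the annotations (centers, axis-aligned extents, spanning vectors)
# consistently; intensity transforms leave labels untouched.

#' Augmentation configuration
#'
#' Probabilities and parameter distributions of the training augmentation
#' suite. Rotation and scaling are composed into a single resampling: with
#' probability \code{p_rot_only} only rotation fires, with \code{p_scale_only}
#' only scaling, with \code{p_rot_scale} both.
#'
#' @param p_rot_only,p_scale_only,p_rot_scale geometric transform
#'   probabilities (defaults 0.16 / 0.16 / 0.08).
#' @param rot_range rotation angle range per axis, degrees.
#' @param scale_range isotropic scale factor range.
#' @param p_noise,noise_var_range additive zero-mean Gaussian noise on
#'   intensities normalized to [0, 1]; the variance is uniform in the range.
#' @param p_blur,blur_sigma_range Gaussian blur, kernel width in voxels.
#' @param p_brightness,brightness_range multiplicative intensity factor.
#' @param p_contrast,contrast_range multiplicative factor followed by
#'   clipping to the original value range.
#' @param p_lowres,lowres_range nearest-neighbor downsampling by the factor,
#'   then cubic upsampling back to the original size.
#' @param p_gamma,gamma_range per-voxel i^gamma on intensities rescaled to
#'   [0, 1] (rescaled back afterwards).
#' @return An \code{augment_config} list.
#' @export
augment_config <- function(p_rot_only = 0.16, p_scale_only = 0.16, p_rot_scale = 0.08,
                           rot_range = c(-30, 30), scale_range = c(0.7, 1.4),
                           p_noise = 0.15, noise_var_range = c(0, 0.1),
                           p_blur = 0.2, blur_sigma_range = c(0.5, 1.5),
                           p_brightness = 0.15, brightness_range = c(0.7, 1.3),
                           p_contrast = 0.15, contrast_range = c(0.65, 1.5),
                           p_lowres = 0.25, lowres_range = c(1, 2),
                           p_gamma = 0.15, gamma_range = c(0.7, 1.5)) {
  cfg <- as.list(environment())
  probs <- unlist(cfg[startsWith(names(cfg), "p_")])
  stopifnot(all(probs >= 0), all(probs <= 1),
            p_rot_only + p_scale_only + p_rot_scale <= 1)
  class(cfg) <- "augment_config"
  cfg
}

#' Draw an augmentation plan
#'
#' Separates the random draws from the application so firing statistics can
#' be audited and a plan can be replayed. Each transform fires independently
#' at its configured probability; rotation/scaling use a single partitioned
#' draw.
#'
#' @param cfg an \code{\link{augment_config}}.
#' @return A named list with per-transform \code{fire} flags and sampled
#'   parameters.
#' @export
augment_plan <- function(cfg = augment_config()) {
  u <- runif(1)
  geo <- if (u < cfg$p_rot_only) "rot"
         else if (u < cfg$p_rot_only + cfg$p_scale_only) "scale"
         else if (u < cfg$p_rot_only + cfg$p_scale_only + cfg$p_rot_scale) "both"
         else "none"
  list(
    rotate = geo %in% c("rot", "both"),
    scale = geo %in% c("scale", "both"),
    angles = runif(3, cfg$rot_range[1], cfg$rot_range[2]),
    scale_factor = runif(1, cfg$scale_range[1], cfg$scale_range[2]),
    noise = runif(1) < cfg$p_noise,
    noise_var = runif(1, cfg$noise_var_range[1], cfg$noise_var_range[2]),
    blur = runif(1) < cfg$p_blur,
    blur_sigma = runif(1, cfg$blur_sigma_range[1], cfg$blur_sigma_range[2]),
    brightness = runif(1) < cfg$p_brightness,
    brightness_factor = runif(1, cfg$brightness_range[1], cfg$brightness_range[2]),
    contrast = runif(1) < cfg$p_contrast,
    contrast_factor = runif(1, cfg$contrast_range[1], cfg$contrast_range[2]),
    lowres = runif(1) < cfg$p_lowres,
    lowres_factor = runif(1, cfg$lowres_range[1], cfg$lowres_range[2]),
    gamma = runif(1) < cfg$p_gamma,
    gamma_value = runif(1, cfg$gamma_range[1], cfg$gamma_range[2])
  )
}

#' Augment a volume with consistent labels
#'
#' @param volume 3D intensity array.
#' @param annotations list of \code{\link{vertebra_annotation}} (world mm).
#' @param masks optional \code{\link{plane_channel_masks}}.
#' @param cfg an \code{\link{augment_config}}.
#' @param spacing,origin voxel geometry of \code{volume} (mm).
#' @param seed optional RNG seed for the plan.
#' @param plan replay a previous \code{\link{augment_plan}} instead of
#'   drawing a new one.
#' @return List with \code{volume}, \code{annotations}, \code{masks} (if
#'   given) and the \code{plan} that was applied.
#' @export
augment_sample <- function(volume, annotations, masks = NULL,
                           cfg = augment_config(), spacing = 1,
                           origin = c(0, 0, 0), seed = NULL, plan = NULL) {
  if (is.null(plan)) plan <- with_seed(seed, augment_plan(cfg))
  N <- dim(volume)
  if (plan$rotate || plan$scale) {
    R <- diag(3)
    if (plan$rotate) {
      ang <- plan$angles * pi / 180
      R <- rotation_about_axis(c(0, 0, 1), ang[3]) %*%
           rotation_about_axis(c(0, 1, 0), ang[2]) %*%
           rotation_about_axis(c(1, 0, 0), ang[1])
    }
    s <- if (plan$scale) plan$scale_factor else 1
    ctr_vox <- (N - 1) / 2
    ctr_mm <- ctr_vox * spacing + origin
    # output voxel p maps to input q = A p + t with A = R^T / s (objects are
    # rotated by R and scaled by s in the output)
    A <- t(R) / s
    tv <- ctr_vox - A %*% ctr_vox
    fill <- min(volume)
    volume <- affine_resample3d_cpp(volume, dim(volume), A, as.numeric(tv),
                                    dim(volume), 1L, fill)
    if (!is.null(masks)) {
      for (chn in c("axial", "coronal", "sagittal")) {
        masks[[chn]] <- affine_resample3d_cpp(masks[[chn]], dim(masks[[chn]]),
                                              A, as.numeric(tv),
                                              dim(masks[[chn]]), 0L, 0)
      }
    }
    annotations <- lapply(annotations, function(a) {
      ctr <- s * as.numeric(R %*% (a$center_mm - ctr_mm)) + ctr_mm
      ext <- s * as.numeric(abs(R) %*% a$extent_mm)  # AABB of the rotated box
      rot_tp <- plane_triplet(
        axial = list(u = as.numeric(R %*% a$planes$axial$u),
                     v = as.numeric(R %*% a$planes$axial$v)),
        coronal = list(u = as.numeric(R %*% a$planes$coronal$u),
                       v = as.numeric(R %*% a$planes$coronal$v)),
        sagittal = list(u = as.numeric(R %*% a$planes$sagittal$u),
                        v = as.numeric(R %*% a$planes$sagittal$v)))
      vertebra_annotation(a$class_id, ctr, ext, rot_tp)
    })
  }
  rng <- range(volume)
  span <- max(rng[2] - rng[1], 1e-8)
  if (plan$noise)
    volume <- volume + array(rnorm(length(volume), 0, sqrt(plan$noise_var) * span),
                             dim(volume))
  if (plan$blur)
    volume <- gauss_blur3d_cpp(volume, dim(volume), plan$blur_sigma)
  if (plan$brightness)
    volume <- volume * plan$brightness_factor
  if (plan$contrast) {
    rng2 <- range(volume)  # pre-transform value range
    volume <- pmin(pmax(volume * plan$contrast_factor, rng2[1]), rng2[2])
    dim(volume) <- N
  }
  if (plan$lowres && plan$lowres_factor > 1) {
    small <- pmax(round(N / plan$lowres_factor), 4)
    v <- volume
    for (ax in 0:2) v <- resize_axis_cpp(v, dim(v), ax, small[ax + 1], 0L)
    for (ax in 0:2) v <- resize_axis_cpp(v, dim(v), ax, N[ax + 1], 3L)
    volume <- v
  }
  if (plan$gamma) {
    rng3 <- range(volume)
    span3 <- max(rng3[2] - rng3[1], 1e-8)
    volume <- ((volume - rng3[1]) / span3)^plan$gamma_value * span3 + rng3[1]
    dim(volume) <- N
  }
  out <- list(volume = volume, annotations = annotations, plan = plan)
  if (!is.null(masks)) out$masks <- masks
  out
}
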