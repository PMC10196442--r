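# Seeded synthetic spine-phantom generator. Produces CBCT-like gray-value
# volumes with complete ground truth (annotations + plane cylinder masks)
# matching the data statistics the pipelines were designed for: 1-10
# vertebrae per volume, class-dependent extents (cervical 8-13 mm, thoracic
# 17-24 mm, lumbar 21-24 mm), roughly collinear stacking with per-vertebra
# tilts, optional noise and implant-like streak artifacts.
#
# Vertebra shapes are deliberately simple (bright ellipsoid body plus a
# posterior arc) - the generator's purpose is algorithmic correctness, not
# anatomical realism.

#' Phantom specification
#'
#' @param grid_size volume edge length in voxels.
#' @param spacing voxel spacing in mm; the default scales the native CBCT
#'   geometry (512 voxels at 0.313 mm, a 160 mm field of view) to
#'   \code{grid_size} so phantoms keep a realistic physical extent.
#' @param n_vertebrae range (or single value) of vertebra counts; counts are
#'   capped automatically when a chain does not fit the field of view.
#' @param region \code{"cervical"}, \code{"thoracic"}, \code{"lumbar"} or
#'   \code{"mixed"} (a contiguous stretch of the spine that may span
#'   region boundaries).
#' @param size_ranges named list of per-class extent ranges in mm.
#' @param gap_range range of inter-vertebra gaps (face to face, mm).
#' @param max_tilt maximum per-vertebra tilt of the plane triplet (degrees).
#' @param noise Gaussian noise standard deviation (intensity units; volumes
#'   are rendered in [0, 1]).
#' @param artifact artifact severity in [0, 1]: expected number of bright
#'   implant-like streaks is \code{5 * artifact}.
#' @return A \code{phantom_spec} list.
#' @export
phantom_spec <- function(grid_size = 160L,
                         spacing = 0.313 * 512 / grid_size,
                         n_vertebrae = c(1L, 10L),
                         region = c("mixed", "cervical", "thoracic", "lumbar"),
                         size_ranges = list(cervical = c(8, 13),
                                            thoracic = c(17, 24),
                                            lumbar = c(21, 24)),
                         gap_range = c(2, 5),
                         max_tilt = 15,
                         noise = 0.03,
                         artifact = 0) {
  region <- match.arg(region)
  n_vertebrae <- as.integer(rep(n_vertebrae, length.out = 2))
  stopifnot(n_vertebrae[1] >= 1, n_vertebrae[2] <= 10,
            n_vertebrae[1] <= n_vertebrae[2],
            grid_size >= 16, spacing > 0, max_tilt >= 0, noise >= 0,
            artifact >= 0, artifact <= 1)
  structure(list(grid_size = as.integer(grid_size), spacing = spacing,
                 n_vertebrae = n_vertebrae, region = region,
                 size_ranges = size_ranges, gap_range = gap_range,
                 max_tilt = max_tilt, noise = noise, artifact = artifact),
            class = "phantom_spec")
}

# class ids along the whole spine: C1-C7, T1-T12, L1-L5
spine_classes <- rep(1:3, c(7L, 12L, 5L))

# Random unit vector and random rotation with angle <= max_deg about a
# random axis.
rand_rotation <- function(max_deg) {
  ax <- unit3(rnorm(3))
  ang <- runif(1, 0, max_deg) * pi / 180
  rotation_about_axis(ax, ang)
}

rotation_about_axis <- function(axis, angle) {
  a <- unit3(axis); c1 <- cos(angle); s1 <- sin(angle)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + s1 * K + (1 - c1) * (K %*% K)
}

#' Sample the geometric layout of a phantom spine
#'
#' Vertebra centers are stacked along a smoothly curving axis (small random
#' bends per step); each vertebra gets a cubic box with a class-dependent
#' extent and a plane triplet equal to the local stacking frame perturbed by
#' a random tilt. Boxes are guaranteed pairwise disjoint; if a chain cannot
#' fit inside the field of view the vertebra count is reduced with a
#' warning.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @param seed RNG seed (optional; caller may also manage the RNG).
#' @return List of \code{\link{vertebra_annotation}} objects (world mm,
#'   origin at 0).
#' @export
sample_spine_geometry <- function(spec, seed = NULL) {
  with_seed(seed, {
    n <- if (spec$n_vertebrae[1] == spec$n_vertebrae[2]) spec$n_vertebrae[1]
         else sample(spec$n_vertebrae[1]:spec$n_vertebrae[2], 1)
    classes <- sample_region_classes(spec$region, n)
    n <- length(classes)
    rngs <- spec$size_ranges[c("cervical", "thoracic", "lumbar")]
    ext <- vapply(classes, function(k) runif(1, rngs[[k]][1], rngs[[k]][2]), 0)
    fov <- spec$grid_size * spec$spacing
    # stacking directions: near +z, slowly curving
    dir <- unit3(c(rnorm(2, 0, 0.08), 1))
    dirs <- matrix(0, n, 3)
    dirs[1, ] <- dir
    for (i in seq_len(n - 1)) {
      dir <- unit3(dir + rnorm(3, 0, 0.03))
      dirs[i + 1, ] <- dir
    }
    centers <- matrix(0, n, 3)
    for (i in seq_len(n - 1)) {
      gap <- runif(1, spec$gap_range[1], spec$gap_range[2])
      step <- (ext[i] + ext[i + 1]) / 2 + gap
      # enlarge the step until the axis-aligned boxes are disjoint (tilted
      # stacking shrinks the along-axis separation)
      repeat {
        cand <- centers[i, ] + dirs[i, ] * step
        if (any(abs(cand - centers[i, ]) >= (ext[i] + ext[i + 1]) / 2)) break
        step <- step * 1.05
      }
      centers[i + 1, ] <- cand
    }
    # drop vertebrae that cannot fit in the field of view
    margin <- ext / 2 + 1.5 * spec$spacing
    prefix_fits <- function(k) {
      all(vapply(1:3, function(ax2) {
        v <- centers[1:k, ax2]
        (max(v + margin[1:k]) - min(v - margin[1:k])) < fov
      }, TRUE))
    }
    keep <- 1L
    while (keep < n && prefix_fits(keep + 1L)) keep <- keep + 1L
    if (keep < n) {
      warning("phantom chain of ", n, " vertebrae does not fit the field of view; reduced to ", keep)
      n <- keep
      centers <- centers[1:n, , drop = FALSE]
      classes <- classes[1:n]; ext <- ext[1:n]; dirs <- dirs[1:n, , drop = FALSE]
    }
    # place the chain: center it, then jitter
    lo <- apply(centers - margin[1:n], 2, min)
    hi <- apply(centers + margin[1:n], 2, max)
    slack <- fov - (hi - lo)
    offset <- -lo + slack / 2 + runif(3, -1, 1) * pmax(slack / 2 - 1, 0) * 0.5
    centers <- sweep(centers, 2, offset, "+")
    lapply(seq_len(n), function(i) {
      Rbase <- frame_from_axis(dirs[i, ])
      R <- rand_rotation(spec$max_tilt) %*% Rbase
      vertebra_annotation(match(classes[i], c("cervical", "thoracic", "lumbar")),
                          centers[i, ], rep(ext[i], 3), triplet_from_axes(R))
    })
  })
}

# Right-handed frame with z = axis: columns (sagittal x, coronal y, axial z).
frame_from_axis <- function(z) {
  z <- unit3(z)
  x <- unit3(cross3(c(0, 1, 0), z))
  y <- cross3(z, x)
  cbind(x, y, z)
}

# Contiguous stretch of the spine for a phantom: a class-balanced mix for
# region = "mixed", otherwise vertebrae of the requested region only.
sample_region_classes <- function(region, n) {
  cls <- c("cervical", "thoracic", "lumbar")
  if (region != "mixed") return(rep(region, n))
  # anchor-class probabilities compensate for the thoracic segment being
  # half the spine (windows crossing region boundaries would otherwise
  # over-represent it); keeps the three class frequencies near 1/3
  k <- sample(1:3, 1, prob = c(0.35, 0.25, 0.40))
  pos <- which(spine_classes == k)
  anchor <- sample(pos, 1)
  # window centered on the anchor vertebra, clamped to the spine
  start <- anchor - (n - 1L) %/% 2L
  start <- max(1L, min(start, length(spine_classes) - n + 1L))
  cls[spine_classes[start:(start + n - 1L)]]
}

#' Render a phantom volume with complete ground truth
#'
#' Each vertebra is drawn as a bright ellipsoidal body with a posterior
#' arc, oriented by its plane triplet, over a soft-tissue background with a
#' gentle intensity gradient; Gaussian noise and optional bright streak
#' artifacts (emulating metal implants) are added on top. Plane cylinder
#' masks are rasterized from the same annotations, so masks and annotations
#' are mutually consistent by construction.
#'
#' @param annotations vertebra annotations from
#'   \code{\link{sample_spine_geometry}}.
#' @param spec the \code{\link{phantom_spec}} used.
#' @param seed RNG seed (optional).
#' @return A \code{phantom_sample}: list with \code{volume} (3D array in
#'   roughly [0, 1]), \code{annotations}, \code{masks}, \code{spacing},
#'   \code{origin} and the \code{spec}.
#' @export
render_volume <- function(annotations, spec, seed = NULL) {
  with_seed(seed, {
    N <- spec$grid_size
    sp <- spec$spacing
    vol <- array(0.15, c(N, N, N))
    grad <- rnorm(3, 0, 0.015)
    ax <- (0:(N - 1)) / N - 0.5
    vol <- vol + outer(outer(ax * grad[1], ax * grad[2], "+"), ax * grad[3], "+")
    for (a in annotations) {
      body <- 0.75 + runif(1, -0.05, 0.05)
      e <- a$extent_mm
      ci <- a$center_mm / sp
      rad <- ceiling(max(e) / 2 / sp) + 1
      lo <- pmax(floor(ci - rad), 0); hi <- pmin(ceiling(ci + rad), N - 1)
      g <- as.matrix(expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3]))
      rel <- sweep(g * sp, 2, a$center_mm)  # mm offsets
      R <- cbind(unit3(a$planes$sagittal$n), unit3(a$planes$coronal$n),
                 unit3(a$planes$axial$n))
      l <- rel %*% R  # local coordinates (x right, y anterior->posterior, z axial)
      # vertebral bodies are oblate: the axial height of the body is smaller
      # than its transverse width, which makes the orientation observable
      semi <- c(0.48, 0.42, 0.33) * e
      inside <- (l[, 1] / semi[1])^2 + (l[, 2] / semi[2])^2 + (l[, 3] / semi[3])^2 <= 1
      # posterior arc: half-ring in the axial plane behind the body
      rho <- sqrt(l[, 1]^2 + l[, 2]^2)
      ring <- abs(rho - 0.42 * e[2]) <= 0.10 * e[2] &
        abs(l[, 3]) <= 0.14 * e[3] & l[, 2] > 0
      idx <- g + 1
      sel <- inside | ring
      if (any(sel)) {
        lin <- idx[sel, 1] + N * (idx[sel, 2] - 1) + N * N * (idx[sel, 3] - 1)
        val <- ifelse(inside[sel], body, 0.62)
        vol[lin] <- pmax(vol[lin], val)
      }
    }
    n_art <- if (spec$artifact > 0) stats::rpois(1, 5 * spec$artifact) else 0
    for (k in seq_len(n_art)) {
      p0 <- runif(3, 0.2, 0.8) * N * sp
      d <- unit3(rnorm(3))
      tt <- seq(-0.6 * N * sp, 0.6 * N * sp, by = sp / 2)
      pts <- sweep(outer(tt, d), 2, p0, "+") / sp
      pts <- round(pts[apply(pts, 1, function(p) all(p >= 0 & p <= N - 1)), , drop = FALSE])
      if (nrow(pts)) {
        lin <- unique(pts[, 1] + 1 + N * pts[, 2] + N * N * pts[, 3])
        vol[lin] <- 1.0
      }
    }
    if (spec$noise > 0) vol <- vol + array(rnorm(length(vol), 0, spec$noise), dim(vol))
    masks <- if (length(annotations)) {
      # 3-voxel cylinder separation so ground-truth masks stay separable
      # under the default DBSCAN radius of 2 voxels
      rasterize_plane_cylinders(annotations,
                                choose_cylinder_size(annotations, min_gap = 3 * sp),
                                N, sp, c(0, 0, 0))
    } else {
      plane_channel_masks(array(0, c(N, N, N)), array(0, c(N, N, N)),
                          array(0, c(N, N, N)), sp, c(0, 0, 0))
    }
    structure(list(volume = vol, annotations = annotations, masks = masks,
                   spacing = sp, origin = c(0, 0, 0), spec = spec),
              class = "phantom_sample")
  })
}

#' Generate one phantom sample
#'
#' Convenience wrapper: samples the geometry and renders the volume under a
#' single seed, so a sample is fully reproducible from \code{(spec, seed)}.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @param seed integer seed.
#' @return A \code{phantom_sample} (see \code{\link{render_volume}}).
#' @export
phantom_sample <- function(spec = phantom_spec(), seed = NULL) {
  with_seed(seed, {
    anns <- sample_spine_geometry(spec)
    render_volume(anns, spec)
  })
}

#' Generate a suite of phantom samples
#'
#' @param n number of samples.
#' @param spec a \code{\link{phantom_spec}}.
#' @param seeds integer seeds, default \code{base_seed + 0:(n-1)}.
#' @param base_seed first seed.
#' @return List of \code{phantom_sample} objects.
#' @export
phantom_suite <- function(n, spec = phantom_spec(), base_seed = 0L,
                          seeds = base_seed + seq_len(n) - 1L) {
  lapply(seeds, function(s) phantom_sample(spec, seed = s))
}
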