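# Volume and annotation I/O plus run configuration.
#
# Volumes: NIfTI (.nii / .nii.gz) through RNifti, MetaImage (.mha / .mhd,
# uncompressed) through a minimal reader/writer for the simple key = value
# header format. Annotations: one JSON file per volume with the shared
# schema used for ground truth and both pipelines' outputs.

#' Load a 3D volume with geometry metadata
#'
#' @param path a \code{.nii}, \code{.nii.gz}, \code{.mha} or \code{.mhd}
#'   file.
#' @return A \code{volume_handle}: list with \code{data} (3D numeric array),
#'   \code{spacing} (mm per axis), \code{origin} (mm). Intensities are
#'   passed through unchanged.
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    if (length(dim(arr)) != 3) stop("expected a 3D volume in ", path,
                                    " but found ", length(dim(arr)), " dimensions")
    sp <- RNifti::pixdim(img)[1:3]
    org <- as.numeric(RNifti::voxelToWorld(c(1, 1, 1), img))
    vh <- volume_handle(arr, sp, origin = org)
  } else if (grepl("\\.(mha|mhd)$", lower)) {
    vh <- read_metaimage(path)
  } else stop("unsupported volume format: ", path, " (use .nii, .nii.gz, .mha or .mhd)")
  if (diff(range(vh$spacing)) > 1e-6 * mean(vh$spacing))
    warning("anisotropic voxel spacing in ", path,
            "; resample isotropic before detection (see resample_volume)")
  vh
}

#' Construct a volume handle
#'
#' @param data 3D numeric array.
#' @param spacing voxel spacing, mm (length 1 or 3).
#' @param origin world position of voxel (0,0,0), mm.
#' @return A \code{volume_handle} list.
#' @export
volume_handle <- function(data, spacing = 1, origin = c(0, 0, 0)) {
  stopifnot(length(dim(data)) == 3, all(spacing > 0))
  structure(list(data = data, spacing = rep(as.numeric(spacing), length.out = 3),
                 origin = as.numeric(origin)), class = "volume_handle")
}

#' Save a volume
#'
#' @param vh a \code{\link{volume_handle}} (or bare array).
#' @param path output path (\code{.nii}, \code{.nii.gz}, \code{.mha}).
#' @param spacing,origin geometry when \code{vh} is a bare array.
#' @export
save_volume <- function(vh, path, spacing = 1, origin = c(0, 0, 0)) {
  if (!inherits(vh, "volume_handle")) vh <- volume_handle(vh, spacing, origin)
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    img <- RNifti::asNifti(vh$data)
    aff <- diag(c(vh$spacing, 1))
    aff[1:3, 4] <- vh$origin
    img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
    RNifti::pixdim(img) <- vh$spacing
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.mha$", lower)) {
    write_metaimage(vh, path)
  } else stop("unsupported output format: ", path)
  invisible(path)
}

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (!length(line)) stop("corrupted MetaImage header in ", path,
                            ": no ElementDataFile entry")
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("corrupted MetaImage header in ", path, ": '", line, "'")
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (identical(hdr$CompressedData, "True"))
    stop("compressed MetaImage not supported: ", path)
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  if (length(dims) != 3) stop("expected a 3D volume in ", path)
  sp <- if (!is.null(hdr$ElementSpacing)) as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]]) else rep(1, 3)
  org <- if (!is.null(hdr$Offset)) as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else rep(0, 3)
  n <- prod(dims)
  sz <- switch(hdr$ElementType,
               MET_DOUBLE = 8L, MET_FLOAT = 4L, MET_SHORT = 2L, MET_USHORT = 2L,
               MET_UCHAR = 1L, MET_CHAR = 1L,
               stop("unsupported ElementType ", hdr$ElementType, " in ", path))
  if (hdr$ElementDataFile != "LOCAL") {
    con2 <- file(file.path(dirname(path), hdr$ElementDataFile), "rb")
    on.exit(close(con2), add = TRUE)
    raw <- con2
  } else raw <- con
  what <- if (hdr$ElementType %in% c("MET_DOUBLE", "MET_FLOAT")) "double" else "integer"
  vals <- readBin(raw, what, n = n, size = sz,
                  signed = !hdr$ElementType %in% c("MET_UCHAR", "MET_USHORT"),
                  endian = "little")
  if (length(vals) != n) stop("corrupted MetaImage data in ", path)
  volume_handle(array(as.numeric(vals), dims), sp, org)
}

write_metaimage <- function(vh, path) {
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False", "CompressedData = False",
           paste("DimSize =", paste(dim(vh$data), collapse = " ")),
           paste("ElementSpacing =", paste(vh$spacing, collapse = " ")),
           paste("Offset =", paste(vh$origin, collapse = " ")),
           "ElementType = MET_DOUBLE", "ElementDataFile = LOCAL")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  writeBin(as.numeric(vh$data), con, size = 8, endian = "little")
  invisible(path)
}

#' Resample a volume to an isotropic cubic grid
#'
#' Trilinear interpolation onto \code{n}^3 voxels covering the same field of
#' view (used to bring whole volumes to the detector input size).
#'
#' @param vh a \code{\link{volume_handle}}.
#' @param n output voxels per axis.
#' @return A \code{volume_handle} of size \code{n}^3.
#' @export
resample_volume <- function(vh, n) {
  v <- vh$data
  for (ax in 0:2) v <- resize_axis_cpp(v, dim(v), ax, as.integer(n), 1L)
  sp <- vh$spacing * dim(vh$data) / n
  # voxel centers shift when the grid is rescaled: index 0 of the new grid
  # sits at (0.5 * scale - 0.5) old-index units
  org <- vh$origin + (0.5 * dim(vh$data) / n - 0.5) * vh$spacing
  volume_handle(v, sp, org)
}

# --- annotations ------------------------------------------------------------

#' Write vertebra annotations to JSON
#'
#' Schema (one file per volume):
#' \code{{"spacing_mm": s, "origin_mm": [x,y,z], "vertebrae": [{"class_id":
#' 1|2|3, "center_mm": [...], "extent_mm": [...], "planes": {"axial":
#' {"u": [...], "v": [...]}, "coronal": ..., "sagittal": ...}}]}}
#'
#' @param annotations list of \code{\link{vertebra_annotation}}.
#' @param path output file.
#' @param spacing,origin geometry of the volume the annotations refer to.
#' @param meta optional named list merged into the JSON root (e.g. seeds).
#' @export
write_annotations <- function(annotations, path, spacing = 1,
                              origin = c(0, 0, 0), meta = NULL) {
  obj <- list(spacing_mm = spacing[1], origin_mm = as.numeric(origin),
              vertebrae = lapply(annotations, function(a) list(
                class_id = a$class_id,
                center_mm = a$center_mm,
                extent_mm = a$extent_mm,
                planes = list(axial = list(u = a$planes$axial$u, v = a$planes$axial$v),
                              coronal = list(u = a$planes$coronal$u, v = a$planes$coronal$v),
                              sagittal = list(u = a$planes$sagittal$u, v = a$planes$sagittal$v)))))
  if (!is.null(meta)) obj <- c(obj, meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read vertebra annotations from JSON
#'
#' @param path an annotation JSON file (see \code{\link{write_annotations}}).
#' @return List with \code{annotations}, \code{spacing}, \code{origin}.
#' @export
read_annotations <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  anns <- lapply(obj$vertebrae, function(v)
    vertebra_annotation(v$class_id, v$center_mm, v$extent_mm,
                        plane_triplet(axial = v$planes$axial,
                                      coronal = v$planes$coronal,
                                      sagittal = v$planes$sagittal)))
  list(annotations = anns, spacing = obj$spacing_mm,
       origin = as.numeric(obj$origin_mm))
}

# --- run configuration ------------------------------------------------------

#' Default run configuration
#'
#' All tunable constants of both pipelines with their defaults: detector
#' thresholds and anchors, loss weights, optimizer settings, DBSCAN
#' parameters, cylinder rule coefficients, augmentation probabilities and
#' phantom settings. \code{load_run_config} merges a YAML file over these
#' defaults, rejecting unknown keys.
#'
#' @return Nested named list.
#' @export
default_run_config <- function() {
  list(
    seed = 0L,
    yolo = list(input_size = 160L, width_multiplier = 1.0,
                anchors = c(0.15, 0.11, 0.07),
                conf_threshold = 0.10, iou_threshold = 0.15,
                classprob_threshold = 0.25,
                loss_weights = list(OL = 1, NOL = 10, BL = 10, CL = 1,
                                    APL = 1, CPL = 1, SPL = 1),
                optimizer = list(name = "adam", lr = 1e-5, weight_decay = 1e-4),
                epochs = 1000L, batch_size = 2L),
    seg = list(patch_size = 64L, depth = 3L, width = 16L,
               w_CE = 1, w_DC = 1,
               optimizer = list(name = "sgd", lr = 1e-3, momentum = 0.99),
               dbscan = list(eps = 2, min_samples = 10L)),
    augment = list(enabled = TRUE),
    phantom = list(grid_size = 160L, n_vertebrae = c(1L, 10L),
                   region = "mixed", max_tilt = 15, noise = 0.03,
                   artifact = 0)
  )
}

#' Load and validate a YAML run configuration
#'
#' @param path YAML file; keys must be a subset of
#'   \code{\link{default_run_config}}.
#' @return The merged configuration.
#' @export
load_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_validate(default_run_config(), user, "")
}

merge_validate <- function(base, user, prefix) {
  for (k in names(user)) {
    if (!k %in% names(base))
      stop("unknown configuration key: ", paste0(prefix, k))
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      if (!is.list(user[[k]])) stop("configuration key ", paste0(prefix, k),
                                    " must be a mapping")
      base[[k]] <- merge_validate(base[[k]], user[[k]], paste0(prefix, k, "."))
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}
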