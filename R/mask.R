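#' Binary ROI mask on a shared template grid
#'
#' A 3D binary voxel grid with a fixed axis convention — sagittal = x (first
#' dimension), coronal = y, axial = z on an RAS+ grid — plus the 4x4 template
#' affine. All masks entering one analysis must share grid shape and affine
#' (template space).
#'
#' @param voxels 3D array of 0/1.
#' @param subject_id,roi Identifiers.
#' @param affine 4x4 voxel-to-world transform; default centres the grid.
#' @return A `mask_volume`.
#' @export
mask_volume <- function(voxels, subject_id, roi, affine = NULL) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L) {
    ts_abort("mask voxels must be a 3D array", "geometry_error")
  }
  if (!all(voxels %in% c(0, 1))) {
    ts_abort("mask voxels must be binary", "geometry_error")
  }
  if (sum(voxels) == 0) {
    ts_abort("mask has no nonzero voxel", "empty_mask")
  }
  if (is.null(affine)) {
    affine <- rbind(cbind(diag(3), -dim(voxels) / 2), c(0, 0, 0, 1))
  }
  structure(list(voxels = voxels, affine = affine,
                 subject_id = subject_id, roi = canonical_roi(roi),
                 axes = c(sagittal = 1L, coronal = 2L, axial = 3L)),
            class = "mask_volume")
}

#' @export
print.mask_volume <- function(x, ...) {
  cat(sprintf("<mask_volume> %s / %s, grid %s, %d voxels set\n",
              x$subject_id, x$roi, paste(dim(x$voxels), collapse = "x"),
              sum(x$voxels)))
  invisible(x)
}

#' Ellipsoid slab mask with exact per-axis nonzero slice counts
#'
#' Builds a connected, ellipsoid-shaped binary slab whose number of nonzero
#' slices along each grid axis equals `counts` exactly (the ellipsoid
#' semi-axes are set just under the half-extent of the requested slice
#' window, so the boundary slices are occupied but no slice outside the
#' window is).
#'
#' @param grid_shape 3 positive integers.
#' @param counts Integer vector of 3 per-axis nonzero slice counts.
#' @param center Optional ellipsoid centre (defaults to the grid centre,
#'   shifted to half-integers as needed for even counts).
#' @return 3D 0/1 array.
#' @export
ellipsoid_mask <- function(grid_shape, counts, center = NULL) {
  grid_shape <- as.integer(grid_shape); counts <- as.integer(counts)
  if (any(counts < 1L) || any(counts > grid_shape)) {
    ts_abort("requested slab exceeds the grid", "geometry_error")
  }
  if (is.null(center)) center <- (grid_shape + 1) / 2
  # snap centre so the occupied window [center - (c-1)/2, center + (c-1)/2]
  # holds exactly `counts` integers and stays inside the grid
  center <- ifelse(counts %% 2L == 1L, round(center),
                   floor(center) + 0.5)
  lo <- center - (counts - 1) / 2
  shift <- pmax(0, 1 - lo) - pmax(0, (lo + counts - 1) - grid_shape)
  center <- center + shift
  if (any(center - (counts - 1) / 2 < 1) ||
      any(center + (counts - 1) / 2 > grid_shape)) {
    ts_abort("requested slab exceeds the grid", "geometry_error")
  }
  semi <- (counts - 1) / 2 + 0.49
  dx <- ((seq_len(grid_shape[1]) - center[1]) / semi[1])^2
  dy <- ((seq_len(grid_shape[2]) - center[2]) / semi[2])^2
  dz <- ((seq_len(grid_shape[3]) - center[3]) / semi[3])^2
  vox <- outer(outer(dx, dy, `+`), dz, `+`) <= 1
  storage.mode(vox) <- "integer"
  vox
}

#' Simulate per-subject, per-ROI template-space masks
#'
#' For each ROI a base per-axis slice count is drawn from
#' `cfg$mask_slices_per_axis`; each sibling's counts are the base counts
#' scaled by `1 + offset + jitter`, where `offset` comes from
#' `cfg$mask_profile` (planted shape similarity: subjects with close offsets
#' get close masks) and `jitter ~ N(0, cfg$mask_jitter)`, then clamped to the
#' configured range so every exported stack size stays within it. All masks
#' share one grid and affine.
#'
#' @param cohort A [family_cohort()].
#' @param roi_set Character vector of ROI names.
#' @param cfg A [sim_config()].
#' @param seed_offset Added to `cfg$seed` (default 0).
#' @return Nested list: `masks[[roi]][[subject_id]]` of [mask_volume()]s.
#' @export
simulate_masks <- function(cohort, roi_set, cfg, seed_offset = 0L) {
  stopifnot(inherits(cohort, "family_cohort"), inherits(cfg, "sim_config"))
  roi_set <- unique(canonical_roi(roi_set))
  rng <- cfg$mask_slices_per_axis
  if (any(rng[2] > cfg$grid_shape)) {
    ts_abort("slice range exceeds the grid", "geometry_error")
  }
  sibs <- sibling_ids(cohort)
  affine <- rbind(cbind(diag(3), -cfg$grid_shape / 2), c(0, 0, 0, 1))
  prof <- cfg$mask_profile
  with_seed(cfg$seed + 202L + seed_offset, {
    out <- lapply(roi_set, function(roi) {
      offs <- vapply(sibs, function(s) {
        if (is.null(prof)) return(0)
        hit <- prof$roi == roi & prof$subject_id == s
        if (any(hit)) prof$scale[which(hit)[1]] else 0
      }, numeric(1))
      # draw base counts with enough headroom that every subject's scaled
      # count stays inside the range (clamping would erase planted structure)
      fmin <- 1 + min(offs) - 3 * cfg$mask_jitter
      fmax <- 1 + max(offs) + 3 * cfg$mask_jitter
      lo <- min(max(rng[1], ceiling(rng[1] / max(fmin, 0.01))), rng[2])
      hi <- max(min(rng[2], floor(rng[2] / max(fmax, 0.01))), lo)
      base <- sample(seq(lo, hi), 3L, replace = TRUE)
      center <- (cfg$grid_shape + 1) / 2 +
        stats::runif(3, -2, 2)
      subj_masks <- lapply(sibs, function(s) {
        f <- 1 + offs[[s]] + stats::rnorm(1L, 0, cfg$mask_jitter)
        counts <- pmin(pmax(round(base * f), rng[1]), rng[2])
        mask_volume(ellipsoid_mask(cfg$grid_shape, counts, center),
                    subject_id = s, roi = roi, affine = affine)
      })
      stats::setNames(subj_masks, sibs)
    })
    stats::setNames(out, roi_set)
  })
}

#' Write / read a mask as NIfTI-1
#'
#' Masks are stored as uint8 0/1 volumes with the template affine in the
#' sform/qform.
#'
#' @param mask A [mask_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path` invisibly; `read_mask()` returns a [mask_volume()].
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "mask_volume"))
  img <- RNifti::asNifti(mask$voxels)
  img <- RNifti::`sform<-`(img, structure(mask$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname write_mask
#' @param subject_id,roi Identifiers to attach (`read_mask` cannot recover
#'   them from the voxel data alone; defaults parse `subject__roi.nii[.gz]`
#'   file names as written by the pipeline).
#' @export
read_mask <- function(path, subject_id = NULL, roi = NULL) {
  img <- RNifti::readNifti(path)
  stem <- sub("\\.nii(\\.gz)?$", "", basename(path))
  parts <- strsplit(stem, "__", fixed = TRUE)[[1]]
  if (is.null(subject_id)) subject_id <- parts[1]
  if (is.null(roi)) roi <- ifelse(length(parts) > 1L, parts[2], stem)
  aff <- structure(RNifti::xform(img), dimnames = NULL)
  mask_volume(array(as.integer(img > 0), dim = dim(img)),
              subject_id = subject_id, roi = roi, affine = aff)
}
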