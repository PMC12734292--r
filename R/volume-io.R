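## Volume/mask containers, NIfTI I/O, slice-stack construction along the
## muscle's segmentation plane, and the two slice exclusion rules.

#' CT volume container
#'
#' @param voxels 3D numeric array of HU values.
#' @param spacing Voxel spacing in mm per array axis.
#' @param axis_roles Named integer vector mapping stacking planes to array
#'   axes; default axial = 3, coronal = 2.
#' @return A `ct_volume` object.
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1), axis_roles = c(axial = 3L, coronal = 2L)) {
  assert_that(is.array(voxels) && length(dim(voxels)) == 3L, "voxels must be a 3D array")
  assert_that(all(is.finite(voxels)), "voxels must be finite")
  assert_that(length(spacing) == 3L && all(spacing > 0), "spacing must be three positive values")
  structure(list(voxels = voxels, spacing = as.numeric(spacing), axis_roles = axis_roles),
            class = "ct_volume")
}

#' Binary muscle mask container
#'
#' @param voxels 3D logical (or 0/1) array, same grid as its volume.
#' @param label Muscle label.
#' @param plane Segmentation plane, `"axial"` or `"coronal"`.
#' @return A `muscle_mask` object.
#' @export
muscle_mask <- function(voxels, label = "PM", plane = c("axial", "coronal")) {
  plane <- match.arg(plane)
  assert_that(is.array(voxels) && length(dim(voxels)) == 3L, "mask voxels must be a 3D array")
  voxels <- array(as.logical(voxels), dim = dim(voxels))
  if (!any(voxels)) stop_respiromics("mask has no foreground voxels", "respiromics_mask_error")
  structure(list(voxels = voxels, label = label, plane = plane), class = "muscle_mask")
}

write_nifti_volume <- function(voxels, spacing, path) {
  img <- RNifti::asNifti(voxels)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Load and validate a volume/mask NIfTI pair
#'
#' Grids must match exactly and spacings to 1e-3 mm; an empty mask is refused.
#'
#' @param volume_path,mask_path Paths to NIfTI files.
#' @param label Muscle label attached to the mask.
#' @param plane Segmentation plane of the mask.
#' @return List with elements `volume` and `mask`.
#' @export
load_pair <- function(volume_path, mask_path, label = "PM", plane = c("axial", "coronal")) {
  plane <- match.arg(plane)
  assert_that(file.exists(volume_path), sprintf("volume file not found: %s", volume_path))
  assert_that(file.exists(mask_path), sprintf("mask file not found: %s", mask_path))
  v <- RNifti::readNifti(volume_path)
  m <- RNifti::readNifti(mask_path)
  if (!identical(dim(v), dim(m)))
    stop_respiromics(sprintf("volume/mask grid mismatch: %s vs %s",
                             paste(dim(v), collapse = "x"), paste(dim(m), collapse = "x")),
                     "respiromics_alignment_error")
  sv <- RNifti::pixdim(v)[seq_len(3)]
  sm <- RNifti::pixdim(m)[seq_len(3)]
  if (any(abs(sv - sm) > 1e-3))
    stop_respiromics("volume/mask spacing mismatch beyond 1e-3 mm", "respiromics_alignment_error")
  mv <- array(as.numeric(m) != 0, dim = dim(m))
  if (!any(mv)) stop_respiromics("mask has no foreground voxels", "respiromics_mask_error")
  list(volume = ct_volume(array(as.numeric(v), dim = dim(v)), spacing = sv),
       mask = muscle_mask(mv, label = label, plane = plane))
}

#' Build a per-slice stack along the mask's segmentation plane
#'
#' One entry per plane-axis slice intersecting the mask, with pixel count,
#' mean and SD (sample, n-1) of the masked HU values in that slice. Slice
#' indices are 0-based along the plane axis of the full volume.
#'
#' @param volume A [ct_volume()].
#' @param mask A [muscle_mask()] on the same grid.
#' @return A `slice_stack`: data frame with columns `index`, `pixel_count`,
#'   `mean_hu`, `sd_hu`, `retained`, carrying the per-slice masked HU values
#'   and spacing metadata as attributes.
#' @export
build_stack <- function(volume, mask) {
  assert_that(inherits(volume, "ct_volume"), "volume must be a ct_volume")
  assert_that(inherits(mask, "muscle_mask"), "mask must be a muscle_mask")
  assert_that(identical(dim(volume$voxels), dim(mask$voxels)), "volume and mask grids differ")
  axis <- volume$axis_roles[[mask$plane]]
  perm <- c(setdiff(1:3, axis), axis)
  vox <- aperm(volume$voxels, perm)
  mv <- aperm(mask$voxels, perm)
  n <- dim(vox)[3]
  npix <- prod(dim(vox)[1:2])
  vox <- matrix(vox, npix, n)
  mv <- matrix(mv, npix, n)
  counts <- colSums(mv)
  idx <- which(counts > 0L)
  values <- lapply(idx, function(j) vox[mv[, j], j])
  df <- data.frame(index = idx - 1L,
                   pixel_count = counts[idx],
                   mean_hu = vapply(values, mean, 0),
                   sd_hu = vapply(values, function(x) if (length(x) > 1) stats::sd(x) else 0, 0),
                   retained = TRUE)
  names(values) <- as.character(df$index)
  in_plane <- volume$spacing[perm[1:2]]
  structure(df, values = values, plane = mask$plane, label = mask$label,
            pixel_area = prod(in_plane), in_plane_spacing = in_plane,
            slice_spacing = volume$spacing[axis],
            class = c("slice_stack", "data.frame"))
}

#' Retained slice values from a stack
#'
#' @param stack A `slice_stack`.
#' @param retained_only Restrict to retained slices (default `TRUE`).
#' @return Named list (by 0-based slice index) of masked HU vectors.
#' @export
slice_values <- function(stack, retained_only = TRUE) {
  vals <- attr(stack, "values")
  if (retained_only) vals <- vals[as.character(stack$index[stack$retained])]
  vals
}

#' Apply the slice exclusion rules
#'
#' Step 1 removes slices whose pixel count is strictly lower than
#' `pixel_fraction` times the maximum slice pixel count of the muscle. Step 2
#' computes z-scores of per-slice mean HU over the step-1 survivors (sample
#' SD) and removes slices with |z| > `z_threshold`. Order is preserved;
#' `retained` flags are updated.
#'
#' @param stack A `slice_stack`.
#' @param pixel_fraction Pixel-count threshold as a fraction of the maximum.
#' @param z_threshold Mean-density z-score cut-off.
#' @return The filtered `slice_stack`.
#' @export
filter_slices <- function(stack, pixel_fraction = 0.20, z_threshold = 3.0) {
  assert_that(inherits(stack, "slice_stack"), "stack must be a slice_stack")
  assert_that(nrow(stack) > 0, "empty stack")
  keep <- stack$retained
  thr <- pixel_fraction * max(stack$pixel_count[keep])
  keep <- keep & stack$pixel_count >= thr
  if (sum(keep) >= 2L) {
    m <- stack$mean_hu[keep]
    z <- (m - mean(m)) / stats::sd(m)
    if (any(is.finite(z))) {
      drop <- abs(z) > z_threshold
      drop[!is.finite(z)] <- FALSE # zero-SD stack: nothing is an outlier
      keep[keep] <- !drop
    }
  }
  if (!any(keep))
    stop_respiromics("all slices removed: degenerate segmentation", "respiromics_filter_error")
  stack$retained <- keep
  stack
}
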