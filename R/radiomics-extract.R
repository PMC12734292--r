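## Feature-extraction front-end: whole-volume 3D vectors and per-slice 2D
## vectors (averaged), with pooled mean density always computed over the
## included masked voxels.

FEATURE_CLASSES <- c("firstorder", "shape", "glcm", "glrlm", "glszm", "gldm", "ngtdm", "density")
VARIABILITY_CLASSES <- c("glcm", "glrlm", "glszm", "gldm", "ngtdm")

#' Feature class and category of feature names
#'
#' Class is the matrix family or `firstorder`/`shape`/`density`; category is
#' the variability (texture-matrix) vs structural (first-order, shape,
#' density) partition used by the biomarker clustering.
#'
#' @param names Character vector of feature names.
#' @return Character vector.
#' @export
feature_class <- function(names) {
  cls <- sub("_.*$", "", names)
  ifelse(cls %in% FEATURE_CLASSES, cls, "unknown")
}

#' @rdname feature_class
#' @export
feature_category <- function(names) {
  ifelse(feature_class(names) %in% VARIABILITY_CLASSES, "variability", "structural")
}

slice_index_matrix <- function(arr, axis, i) {
  switch(axis, arr[i, , ], arr[, i, ], arr[, , i])
}

make_feature_vector <- function(x, flagged = character(0)) {
  structure(x, class = "feature_vector",
            feature_class = feature_class(names(x)),
            feature_category = feature_category(names(x)),
            flagged = intersect(flagged, names(x)))
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector: %d features, %d flagged>\n",
              length(x), length(attr(x, "flagged"))))
  print(utils::head(unclass(x), 10))
  invisible(x)
}

region_features <- function(values, gray_arr, mask_arr, spacing, settings) {
  fo <- firstorder_features(values, spacing = spacing, settings = settings)
  tm <- texture_matrices(gray_arr)
  tx <- texture_features(tm)
  sh <- shape_features(mask_arr, spacing)
  flagged <- c(attr(tx, "flagged"), attr(sh, "flagged"))
  vec <- c(fo, as.numeric(tx), as.numeric(sh))
  names(vec) <- c(names(fo), names(tx), names(sh))
  list(vec = vec, flagged = flagged)
}

#' Extract a radiomic feature vector
#'
#' `whole_3d` computes one vector over the full retained masked volume.
#' `per_slice_2d` computes per-slice 2D vectors (used for non-adjacent slice
#' sets, where 3D texture across sampled slices is physically meaningless)
#' and averages them; pooled mean/SD density is always computed over all
#' included masked voxels. Slice filtering is applied unless a pre-filtered
#' stack is supplied.
#'
#' @param volume A [ct_volume()].
#' @param mask A [muscle_mask()].
#' @param mode `"whole_3d"` or `"per_slice_2d"`.
#' @param settings [discretization_settings()].
#' @param slices Optional integer vector of 0-based slice indices (along the
#'   plane axis) to include; defaults to all retained slices.
#' @param stack Optional pre-filtered `slice_stack` (avoids recomputation).
#' @return A `feature_vector`: named numeric vector with `feature_class`,
#'   `feature_category` and `flagged` attributes.
#' @export
extract_features <- function(volume, mask, mode = c("whole_3d", "per_slice_2d"),
                             settings = discretization_settings(), slices = NULL,
                             stack = NULL) {
  mode <- match.arg(mode)
  if (is.null(stack)) stack <- filter_slices(build_stack(volume, mask))
  retained <- stack$index[stack$retained]
  if (is.null(slices)) slices <- retained
  bad <- setdiff(slices, retained)
  if (length(bad))
    stop_respiromics(sprintf("requested slices not in retained set: %s",
                             paste(bad, collapse = ", ")), "respiromics_protocol_error")
  axis <- volume$axis_roles[[mask$plane]]
  in_plane <- volume$spacing[setdiff(1:3, axis)]
  vvol <- prod(volume$spacing)
  vals_by_slice <- slice_values(stack)[as.character(slices)]
  pooled <- unlist(vals_by_slice, use.names = FALSE)
  density <- c(density_mean = mean(pooled),
               density_sd = if (length(pooled) > 1) stats::sd(pooled) else 0)

  if (mode == "whole_3d") {
    sl1 <- slices + 1L
    keep <- rep(FALSE, dim(volume$voxels)[axis])
    keep[sl1] <- TRUE
    sub_vox <- switch(axis, volume$voxels[keep, , , drop = FALSE],
                      volume$voxels[, keep, , drop = FALSE],
                      volume$voxels[, , keep, drop = FALSE])
    sub_msk <- switch(axis, mask$voxels[keep, , , drop = FALSE],
                      mask$voxels[, keep, , drop = FALSE],
                      mask$voxels[, , keep, drop = FALSE])
    mvals <- sub_vox[sub_msk]
    gray <- array(NA_integer_, dim = dim(sub_vox))
    gray[sub_msk] <- discretize(mvals, settings)
    rf <- region_features(mvals, gray, sub_msk, volume$spacing, settings)
    out <- c(density, rf$vec)
    return(make_feature_vector(out, rf$flagged))
  }

  per <- lapply(slices, function(s) {
    vox2 <- slice_index_matrix(volume$voxels, axis, s + 1L)
    msk2 <- slice_index_matrix(mask$voxels, axis, s + 1L)
    vals <- vox2[msk2]
    gray <- matrix(NA_integer_, nrow(vox2), ncol(vox2))
    gray[msk2] <- discretize(vals, settings)
    region_features(vals, gray, msk2, in_plane, settings)
  })
  mat <- do.call(rbind, lapply(per, `[[`, "vec"))
  avg <- colMeans(mat, na.rm = TRUE)
  avg[colSums(!is.na(mat)) == 0L] <- NA_real_
  flagged <- unique(unlist(lapply(per, `[[`, "flagged")))
  flagged <- union(flagged, names(avg)[is.na(avg)])
  make_feature_vector(c(density, avg), flagged)
}
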