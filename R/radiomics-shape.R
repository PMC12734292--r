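## Shape descriptors of binary masks in physical (mm) units.

## Count exposed voxel faces (3D) or pixel edges (2D) of a binary array.
exposed_faces <- function(mask, spacing) {
  d <- dim(mask)
  ndim <- length(d)
  total <- 0
  for (ax in seq_len(ndim)) {
    face_area <- prod(spacing[-ax])
    ## a face is exposed when a foreground voxel meets background (or the
    ## array edge) along this axis, on either side
    fg <- matrix(aperm(mask, c(ax, seq_len(ndim)[-ax])), nrow = d[ax])
    before <- rbind(FALSE, fg[-nrow(fg), , drop = FALSE])
    after <- rbind(fg[-1, , drop = FALSE], FALSE)
    total <- total + (sum(fg & !before) + sum(fg & !after)) * face_area
  }
  total
}

## Principal-axis eigenvalues of the voxel-centre point cloud (physical
## coordinates), as used for elongation/flatness.
shape_eigenvalues <- function(mask, spacing) {
  idx <- which(mask)
  co <- arrayInd(idx, dim(mask))
  co <- sweep(co, 2, spacing[seq_len(ncol(co))], `*`)
  if (nrow(co) < 2) return(rep(0, ncol(co)))
  ev <- eigen(stats::cov(co), symmetric = TRUE, only.values = TRUE)$values
  pmax(ev, 0)
}

## Candidate extreme voxels for the maximum diameter: foreground voxels that
## are extremal along at least one axis line through them.
diameter_candidates <- function(mask) {
  d <- dim(mask)
  ndim <- length(d)
  keep <- array(FALSE, dim = d)
  for (ax in seq_len(ndim)) {
    perm <- c(ax, seq_len(ndim)[-ax])
    m <- matrix(aperm(mask, perm), nrow = d[ax])
    first <- max.col(t(m), ties.method = "first")
    last <- max.col(t(m), ties.method = "last")
    anyfg <- colSums(m) > 0
    sel <- matrix(FALSE, nrow(m), ncol(m))
    cols <- which(anyfg)
    sel[cbind(first[cols], cols)] <- TRUE
    sel[cbind(last[cols], cols)] <- TRUE
    keep <- keep | aperm(array(sel, dim = d[perm]), order(perm))
  }
  keep & mask
}

max_diameter <- function(mask, spacing, max_candidates = 4000L) {
  cand <- which(diameter_candidates(mask))
  co <- arrayInd(cand, dim(mask))
  co <- sweep(co, 2, spacing[seq_len(ncol(co))], `*`)
  n <- nrow(co)
  if (n < 2) return(0)
  if (n > max_candidates) {
    ## support-point reduction: extremes over a fan of directions
    set <- unique(unlist(lapply(seq_len(64), function(k) {
      dir <- c(cos(k), sin(k * 1.3), cos(k * 0.7))[seq_len(ncol(co))]
      pr <- as.vector(co %*% dir)
      c(which.max(pr), which.min(pr))
    })))
    co <- co[set, , drop = FALSE]
    n <- nrow(co)
  }
  dm <- 0
  chunk <- 512L
  for (s in seq(1, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    block <- co[s:e, , drop = FALSE]
    d2 <- outer(rowSums(block^2), rowSums(co^2), `+`) - 2 * block %*% t(co)
    dm <- max(dm, max(d2))
  }
  sqrt(max(dm, 0))
}

#' Shape features of a binary mask
#'
#' 3D mode returns volume (mm^3), surface area (exposed voxel faces corrected
#' by the isotropic factor 3/2), sphericity, maximum 3D diameter, elongation
#' and flatness from principal-axis eigenvalues. 2D mode (single-slice masks)
#' returns area, perimeter (exposed edges corrected by 4/pi), elongation, and
#' maximum 2D diameter. Degenerate single-voxel masks yield `NA` elongation,
#' reported in the `flagged` attribute.
#'
#' @param mask Binary 2D matrix or 3D array (or a [muscle_mask()]).
#' @param spacing Spacing in mm per array axis.
#' @return Named numeric vector with a `flagged` attribute.
#' @export
shape_features <- function(mask, spacing = c(1, 1, 1)) {
  if (inherits(mask, "muscle_mask")) mask <- mask$voxels
  assert_that(is.array(mask) || is.matrix(mask), "mask must be an array")
  mask <- if (is.matrix(mask)) matrix(as.logical(mask), nrow(mask), ncol(mask)) else array(as.logical(mask), dim = dim(mask))
  assert_that(any(mask), "mask has no foreground voxels")
  ndim <- length(dim(mask))
  spacing <- spacing[seq_len(ndim)]
  nv <- sum(mask)
  ev <- shape_eigenvalues(mask, spacing)
  elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else NA_real_
  if (ndim == 3L) {
    vol <- nv * prod(spacing)
    area <- exposed_faces(mask, spacing) / 1.5
    sph <- if (area > 0) (36 * pi * vol^2)^(1 / 3) / area else NA_real_
    flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else NA_real_
    out <- c(shape_volume = vol,
             shape_surface_area = area,
             shape_sphericity = sph,
             shape_max_3d_diameter = max_diameter(mask, spacing),
             shape_elongation = elong,
             shape_flatness = flat)
  } else {
    area <- nv * prod(spacing)
    per <- exposed_faces(mask, spacing) / (4 / pi)
    out <- c(shape_area = area,
             shape_perimeter = per,
             shape_elongation = elong,
             shape_max_2d_diameter = max_diameter(mask, spacing))
  }
  attr(out, "flagged") <- names(out)[is.na(out)]
  out
}
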