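## Texture matrices (GLCM, GLRLM, GLSZM, GLDM, NGTDM) and their features,
## following IBSI-consistent definitions: symmetric distance-1 GLCM averaged
## over directions, run matrices over the same direction set, size zones by
## full connectivity (8-connected in 2D, 26-connected in 3D), dependence
## matrices with threshold alpha = 0, and a distance-1 NGTDM neighbourhood.
## Masked-out neighbours are excluded from every counting.

## Unique positive lattice offsets at Chebyshev distance `distance`.
texture_offsets <- function(ndim, distance = 1L) {
  if (ndim == 2L) {
    base <- rbind(c(1, 0), c(1, 1), c(0, 1), c(-1, 1))
  } else {
    g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    keep <- apply(g, 1, function(o) {
      if (all(o == 0)) return(FALSE)
      nz <- o[which(o != 0)[1]]
      nz > 0 # one representative per +/- pair
    })
    base <- g[keep, , drop = FALSE]
  }
  base * distance
}

## Extract aligned voxel pairs for an offset: returns two equal-length vectors
## of gray levels (NA where outside mask).
shifted_pairs <- function(gray, off) {
  d <- dim(gray)
  idx_from <- lapply(seq_along(d), function(k) {
    lo <- max(1, 1 - off[k]); hi <- min(d[k], d[k] - off[k])
    if (lo > hi) integer(0) else lo:hi
  })
  if (any(vapply(idx_from, length, 0L) == 0L))
    return(list(a = integer(0), b = integer(0)))
  idx_to <- Map(function(ix, o) ix + o, idx_from, as.list(off))
  a <- do.call(`[`, c(list(gray), idx_from, list(drop = FALSE)))
  b <- do.call(`[`, c(list(gray), idx_to, list(drop = FALSE)))
  list(a = as.vector(a), b = as.vector(b))
}

## Per-direction symmetric co-occurrence counts.
glcm_direction <- function(gray, n_levels, off) {
  p <- shifted_pairs(gray, off)
  ok <- !is.na(p$a) & !is.na(p$b)
  m <- matrix(0, n_levels, n_levels)
  if (any(ok)) {
    tab <- tabulate((p$a[ok] - 1L) * n_levels + p$b[ok], nbins = n_levels^2)
    m <- matrix(tab, n_levels, n_levels, byrow = TRUE)
  }
  m + t(m)
}

## Per-direction run-length counts. Voxels on a common line for offset `off`
## share the cross-product line id; position along the line is the dot
## product. Runs break at line changes, gaps (masked-out voxels), or gray
## level changes.
glrlm_direction <- function(gray, n_levels, off) {
  ok <- which(!is.na(gray))
  if (!length(ok)) return(matrix(0, n_levels, 1))
  co <- arrayInd(ok, dim(gray))
  if (ncol(co) == 2L) co <- cbind(co, 1L)
  o3 <- c(off, rep(0L, 3 - length(off)))
  g <- gray[ok]
  lid1 <- co[, 1] * o3[2] - co[, 2] * o3[1]
  lid2 <- co[, 2] * o3[3] - co[, 3] * o3[2]
  lid3 <- co[, 1] * o3[3] - co[, 3] * o3[1]
  ord <- co[, 1] * o3[1] + co[, 2] * o3[2] + co[, 3] * o3[3]
  step <- sum(o3^2)
  os <- order(lid1, lid2, lid3, ord)
  lid1 <- lid1[os]; lid2 <- lid2[os]; lid3 <- lid3[os]; ord <- ord[os]; g <- g[os]
  n <- length(g)
  newrun <- c(TRUE, lid1[-1] != lid1[-n] | lid2[-1] != lid2[-n] | lid3[-1] != lid3[-n] |
                ord[-1] != ord[-n] + step | g[-1] != g[-n])
  run_id <- cumsum(newrun)
  rl <- tabulate(run_id)
  rg <- g[newrun]
  mat <- matrix(0, n_levels, max(rl))
  tab <- tapply(rep(1L, length(rl)), list(factor(rg, levels = seq_len(n_levels)), factor(rl, levels = seq_len(max(rl)))), sum)
  tab[is.na(tab)] <- 0
  mat[, ] <- tab
  mat
}

## Size-zone counts: connected components of equal gray level under full
## connectivity.
glszm_matrix <- function(gray, n_levels, offsets) {
  ok <- which(!is.na(gray))
  nv <- length(ok)
  if (!nv) return(matrix(0, n_levels, 1))
  vid <- array(NA_integer_, dim = dim(gray))
  vid[ok] <- seq_len(nv)
  edges_a <- integer(0); edges_b <- integer(0)
  for (r in seq_len(nrow(offsets))) {
    off <- offsets[r, ]
    pa <- shifted_pairs(gray, off)
    va <- shifted_pairs(vid, off)
    same <- !is.na(pa$a) & !is.na(pa$b) & pa$a == pa$b
    if (any(same)) {
      edges_a <- c(edges_a, va$a[same])
      edges_b <- c(edges_b, va$b[same])
    }
  }
  g <- igraph::make_empty_graph(n = nv, directed = FALSE)
  if (length(edges_a))
    g <- igraph::add_edges(g, rbind(edges_a, edges_b))
  comp <- igraph::components(g)
  zsize <- tabulate(comp$membership)
  zlevel <- gray[ok][match(seq_len(comp$no), comp$membership)]
  mat <- matrix(0, n_levels, max(zsize))
  for (z in seq_len(comp$no)) mat[zlevel[z], zsize[z]] <- mat[zlevel[z], zsize[z]] + 1
  mat
}

## One pass over all +/- offsets accumulating, per voxel: the count of
## in-mask neighbours, their gray-level sum, and the count of neighbours
## within `alpha` gray levels (for GLDM). Offsets are applied via flat-index
## shifts on the NA-padded array.
neighbor_scan <- function(gray, offsets, alpha = 0) {
  d <- dim(gray)
  nv <- prod(d)
  strides <- cumprod(c(1, d[-length(d)]))
  dep <- numeric(nv); nb_sum <- numeric(nv); nb_cnt <- numeric(nv)
  gv <- as.vector(gray)
  co <- arrayInd(seq_len(nv), d)
  for (r in seq_len(nrow(offsets))) {
    for (sgn in c(1L, -1L)) {
      o <- offsets[r, ] * sgn
      shift <- sum(o * strides)
      ## voxels whose neighbour stays inside the array bounds
      inb <- rep(TRUE, nv)
      for (k in seq_along(d)) {
        ck <- co[, k] + o[k]
        inb <- inb & ck >= 1L & ck <= d[k]
      }
      idx <- which(inb)
      nb <- gv[idx + shift]
      here <- gv[idx]
      valid <- !is.na(here) & !is.na(nb)
      vi <- idx[valid]
      nb_cnt[vi] <- nb_cnt[vi] + 1
      nb_sum[vi] <- nb_sum[vi] + nb[valid]
      close_enough <- vi[abs(here[valid] - nb[valid]) <= alpha]
      dep[close_enough] <- dep[close_enough] + 1
    }
  }
  list(dep = dep, nb_sum = nb_sum, nb_cnt = nb_cnt)
}

## Dependence counts: for each voxel, the number of in-mask neighbours with
## |gray difference| <= alpha; dependence size = count + 1 (the voxel itself).
gldm_matrix_from_scan <- function(gray, n_levels, scan) {
  ok <- which(!is.na(gray))
  dep <- scan$dep[ok]
  dmax <- max(dep) + 1L
  mat <- matrix(0, n_levels, dmax)
  tab <- table(factor(gray[ok], levels = seq_len(n_levels)),
               factor(dep + 1L, levels = seq_len(dmax)))
  mat[, ] <- tab
  mat
}

## Neighbourhood gray-tone difference statistics: per level, the count of
## voxels (with at least one valid neighbour) and the summed absolute
## difference from the mean of their valid neighbours.
ngtdm_stats_from_scan <- function(gray, n_levels, scan) {
  okv <- !is.na(gray) & scan$nb_cnt > 0
  gi <- gray[okv]
  abar <- scan$nb_sum[okv] / scan$nb_cnt[okv]
  n_i <- tabulate(gi, nbins = n_levels)
  adiff <- abs(gi - abar)
  s_i <- vapply(seq_len(n_levels), function(l) sum(adiff[gi == l]), 0)
  list(n = n_i, s = s_i, n_valid = sum(okv), levels = seq_len(n_levels))
}

#' Compute texture matrices of a discretized region
#'
#' @param gray Integer 2D or 3D array of gray levels (>= 1), `NA` outside the
#'   mask.
#' @param n_levels Number of gray levels; defaults to the region maximum.
#' @param distance Neighbourhood distance (default 1).
#' @return A `texture_matrices` list with per-direction GLCM and GLRLM counts,
#'   GLSZM, GLDM, NGTDM statistics, and bookkeeping fields.
#' @export
texture_matrices <- function(gray, n_levels = max(gray, na.rm = TRUE), distance = 1L) {
  assert_that(is.array(gray) || is.matrix(gray), "gray must be a matrix or 3D array")
  assert_that(any(!is.na(gray)), "mask is empty")
  vals <- gray[!is.na(gray)]
  assert_that(all(vals >= 1 & vals == round(vals)), "gray levels must be integers >= 1")
  ndim <- length(dim(gray))
  gray <- crop_to_mask(gray)
  offs <- texture_offsets(ndim, distance)
  glcm <- lapply(seq_len(nrow(offs)), function(r) glcm_direction(gray, n_levels, offs[r, ]))
  glrlm <- lapply(seq_len(nrow(offs)), function(r) glrlm_direction(gray, n_levels, offs[r, ]))
  scan <- neighbor_scan(gray, offs, alpha = 0)
  structure(list(glcm = glcm, glrlm = glrlm,
                 glszm = glszm_matrix(gray, n_levels, offs),
                 gldm = gldm_matrix_from_scan(gray, n_levels, scan),
                 ngtdm = ngtdm_stats_from_scan(gray, n_levels, scan),
                 n_levels = n_levels, n_voxels = length(vals),
                 offsets = offs, distance = distance),
            class = "texture_matrices")
}

## ---- feature computations ----

glcm_features_single <- function(counts) {
  tot <- sum(counts)
  if (tot == 0) return(NULL)
  P <- counts / tot
  ng <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(i * P); muy <- sum(j * P)
  sigx <- sqrt(sum((i - mux)^2 * P)); sigy <- sqrt(sum((j - muy)^2 * P))
  k_diff <- 0:(ng - 1)
  p_diff <- vapply(k_diff, function(k) sum(P[abs(i - j) == k]), 0)
  k_sum <- 2:(2 * ng)
  p_sum <- vapply(k_sum, function(k) sum(P[(i + j) == k]), 0)
  nz <- P > 0
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  HXY <- ent(P)
  pxy <- outer(px, py)
  HXY1 <- -sum(P[nz & pxy > 0] * log2(pxy[nz & pxy > 0]))
  HXY2 <- ent(pxy)
  HX <- ent(px); HY <- ent(py)
  da <- sum(k_diff * p_diff)
  corr <- if (sigx > 0 && sigy > 0) (sum(i * j * P) - mux * muy) / (sigx * sigy) else NA_real_
  imc1 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else NA_real_
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (HXY2 - HXY))))
  mcc <- if (sum(px > 0) < 2) NA_real_ else {
    ## Q(i,j) = sum_k P(i,k) P(j,k) / (px(i) py(k))
    Pk <- sweep(P, 2, ifelse(py > 0, py, 1), "/")
    Q <- (P %*% t(Pk)) / ifelse(px > 0, px, 1)
    ev <- suppressWarnings(sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE))
    if (length(ev) < 2) NA_real_ else sqrt(pmax(0, ev[2]))
  }
  iv_mask <- abs(i - j) > 0
  c(glcm_autocorrelation = sum(i * j * P),
    glcm_joint_average = mux,
    glcm_cluster_prominence = sum((i + j - mux - muy)^4 * P),
    glcm_cluster_shade = sum((i + j - mux - muy)^3 * P),
    glcm_cluster_tendency = sum((i + j - mux - muy)^2 * P),
    glcm_contrast = sum((i - j)^2 * P),
    glcm_correlation = corr,
    glcm_difference_average = da,
    glcm_difference_entropy = ent(p_diff),
    glcm_difference_variance = sum((k_diff - da)^2 * p_diff),
    glcm_joint_energy = sum(P^2),
    glcm_joint_entropy = HXY,
    glcm_imc1 = imc1,
    glcm_imc2 = imc2,
    glcm_idm = sum(P / (1 + (i - j)^2)),
    glcm_idmn = sum(P / (1 + (i - j)^2 / ng^2)),
    glcm_id = sum(P / (1 + abs(i - j))),
    glcm_idn = sum(P / (1 + abs(i - j) / ng)),
    glcm_inverse_variance = sum(P[iv_mask] / (i[iv_mask] - j[iv_mask])^2),
    glcm_maximum_probability = max(P),
    glcm_mcc = mcc,
    glcm_sum_average = sum(k_sum * p_sum),
    glcm_sum_entropy = ent(p_sum),
    glcm_sum_squares = sum((i - mux)^2 * P))
}

## Shared machinery for run-length-style matrices (GLRLM/GLSZM/GLDM): rows are
## gray levels, columns are run lengths / zone sizes / dependence sizes.
rl_family_features <- function(mat, n_voxels, prefix, size_name) {
  Ns <- sum(mat)
  if (Ns == 0) return(NULL)
  p <- mat / Ns
  i <- row(mat); j <- col(mat)
  ri <- rowSums(mat); cj <- colSums(mat)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  ent <- function(x) { x <- x[x > 0]; -sum(x * log2(x)) }
  out <- c(sum(cj / seq_len(ncol(mat))^2) / Ns,
           sum(cj * seq_len(ncol(mat))^2) / Ns,
           sum(ri^2) / Ns,
           sum(ri^2) / Ns^2,
           sum(cj^2) / Ns,
           sum(cj^2) / Ns^2,
           Ns / n_voxels,
           sum((i - mu_i)^2 * p),
           sum((j - mu_j)^2 * p),
           ent(p),
           sum(ri / seq_len(nrow(mat))^2) / Ns,
           sum(ri * seq_len(nrow(mat))^2) / Ns,
           sum(mat / (i^2 * j^2)) / Ns,
           sum(mat * i^2 / j^2) / Ns,
           sum(mat * j^2 / i^2) / Ns,
           sum(mat * i^2 * j^2) / Ns)
  names(out) <- paste0(prefix, "_",
                       c(paste0("short_", size_name, "_emphasis"),
                         paste0("long_", size_name, "_emphasis"),
                         "gray_level_non_uniformity",
                         "gray_level_non_uniformity_normalized",
                         paste0(size_name, "_non_uniformity"),
                         paste0(size_name, "_non_uniformity_normalized"),
                         paste0(size_name, "_percentage"),
                         "gray_level_variance",
                         paste0(size_name, "_variance"),
                         paste0(size_name, "_entropy"),
                         "low_gray_level_emphasis",
                         "high_gray_level_emphasis",
                         paste0("short_", size_name, "_low_gray_level_emphasis"),
                         paste0("short_", size_name, "_high_gray_level_emphasis"),
                         paste0("long_", size_name, "_low_gray_level_emphasis"),
                         paste0("long_", size_name, "_high_gray_level_emphasis")))
  out
}

ngtdm_features <- function(st) {
  n_i <- st$n; s_i <- st$s; N <- st$n_valid
  if (N == 0) return(NULL)
  p_i <- n_i / N
  lev <- st$levels
  act <- which(p_i > 0)
  ngp <- length(act)
  ps <- sum(p_i * s_i)
  coarseness <- if (ps > 0) 1 / ps else NA_real_
  contrast <- if (ngp > 1) {
    (sum(outer(p_i[act], p_i[act]) * outer(lev[act], lev[act], `-`)^2) / (ngp * (ngp - 1))) *
      (sum(s_i) / N)
  } else 0
  denom_b <- sum(abs(outer(lev[act] * p_i[act], lev[act] * p_i[act], `-`)))
  busyness <- if (denom_b > 0) ps / denom_b else 0
  complexity <- if (ngp > 0) {
    tot <- 0
    for (a in act) for (b in act)
      tot <- tot + abs(lev[a] - lev[b]) * (p_i[a] * s_i[a] + p_i[b] * s_i[b]) / (p_i[a] + p_i[b])
    tot / N
  } else 0
  strength <- if (sum(s_i) > 0) {
    tot <- 0
    for (a in act) for (b in act)
      tot <- tot + (p_i[a] + p_i[b]) * (lev[a] - lev[b])^2
    tot / sum(s_i)
  } else 0
  c(ngtdm_coarseness = coarseness, ngtdm_contrast = contrast,
    ngtdm_busyness = busyness, ngtdm_complexity = complexity,
    ngtdm_strength = strength)
}

#' Texture features from computed matrices
#'
#' GLCM and GLRLM features are computed per direction and averaged; GLSZM,
#' GLDM, and NGTDM features come from their single aggregated matrices.
#' Features with undefined denominators on degenerate (single-level) regions
#' are returned as `NA` and listed in the `flagged` attribute.
#'
#' @param tm A [texture_matrices()] result.
#' @return Named numeric vector with a `flagged` attribute naming sentinel
#'   (`NA`) entries.
#' @export
texture_features <- function(tm) {
  assert_that(inherits(tm, "texture_matrices"), "tm must come from texture_matrices()")
  glcm_per_dir <- lapply(tm$glcm, glcm_features_single)
  glcm_per_dir <- glcm_per_dir[!vapply(glcm_per_dir, is.null, TRUE)]
  glcm <- if (length(glcm_per_dir)) {
    mat <- do.call(rbind, glcm_per_dir)
    colMeans(mat) # NA propagates for degenerate directions
  } else NULL
  glrlm_per_dir <- lapply(tm$glrlm, rl_family_features, n_voxels = tm$n_voxels,
                          prefix = "glrlm", size_name = "run")
  glrlm_per_dir <- glrlm_per_dir[!vapply(glrlm_per_dir, is.null, TRUE)]
  glrlm <- if (length(glrlm_per_dir)) colMeans(do.call(rbind, glrlm_per_dir)) else NULL
  ## conventional names for the run/zone entropy features
  glszm <- rl_family_features(tm$glszm, tm$n_voxels, "glszm", "zone")
  gldm <- rl_family_features(tm$gldm, tm$n_voxels, "gldm", "dependence")
  ngtdm <- ngtdm_features(tm$ngtdm)
  out <- c(glcm, glrlm, glszm, gldm, ngtdm)
  flagged <- names(out)[is.na(out)]
  attr(out, "flagged") <- flagged
  out
}
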