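# Brute-force texture-matrix enumerators: naive voxel-by-voxel loops kept
# deliberately independent of the package's vectorized implementations.

bf_offsets <- function(ndim, distance = 1L) {
  if (ndim == 2L) {
    m <- rbind(c(1, 0), c(1, 1), c(0, 1), c(-1, 1))
  } else {
    m <- NULL
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      o <- c(dx, dy, dz)
      if (all(o == 0)) next
      nz <- o[which(o != 0)[1]]
      if (nz > 0) m <- rbind(m, o)
    }
  }
  m * distance
}

bf_inside <- function(co, d) all(co >= 1) && all(co <= d)

bf_get <- function(gray, co) {
  if (length(co) == 2) gray[co[1], co[2]] else gray[co[1], co[2], co[3]]
}

bf_glcm <- function(gray, n_levels, off) {
  d <- dim(gray)
  co_all <- arrayInd(seq_len(prod(d)), d)
  m <- matrix(0, n_levels, n_levels)
  for (r in seq_len(nrow(co_all))) {
    co <- co_all[r, ]
    a <- bf_get(gray, co)
    if (is.na(a)) next
    for (sgn in c(1, -1)) {
      nb <- co + off * sgn
      if (!bf_inside(nb, d)) next
      b <- bf_get(gray, nb)
      if (is.na(b)) next
      m[a, b] <- m[a, b] + 1
    }
  }
  m
}

bf_glrlm <- function(gray, n_levels, off) {
  d <- dim(gray)
  co_all <- arrayInd(seq_len(prod(d)), d)
  counts <- list()
  for (r in seq_len(nrow(co_all))) {
    co <- co_all[r, ]
    g <- bf_get(gray, co)
    if (is.na(g)) next
    prev <- co - off
    if (bf_inside(prev, d)) {
      pg <- bf_get(gray, prev)
      if (!is.na(pg) && pg == g) next # not a run start
    }
    len <- 1
    nxt <- co + off
    while (bf_inside(nxt, d) && !is.na(bf_get(gray, nxt)) && bf_get(gray, nxt) == g) {
      len <- len + 1
      nxt <- nxt + off
    }
    key <- paste(g, len)
    counts[[key]] <- (counts[[key]] %||% 0) + 1
  }
  maxlen <- max(1, vapply(strsplit(names(counts), " "), function(p) as.integer(p[2]), 0L))
  m <- matrix(0, n_levels, maxlen)
  for (key in names(counts)) {
    p <- as.integer(strsplit(key, " ")[[1]])
    m[p[1], p[2]] <- counts[[key]]
  }
  m
}

bf_glszm <- function(gray, n_levels) {
  d <- dim(gray)
  ndim <- length(d)
  offs <- bf_offsets(ndim)
  offs <- rbind(offs, -offs)
  visited <- array(FALSE, dim = d)
  zones <- list()
  co_all <- arrayInd(seq_len(prod(d)), d)
  for (r in seq_len(nrow(co_all))) {
    co <- co_all[r, ]
    if (visited[t(co)] || is.na(bf_get(gray, co))) next
    g <- bf_get(gray, co)
    size <- 0
    queue <- list(co)
    visited[t(co)] <- TRUE
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (k in seq_len(nrow(offs))) {
        nb <- cur + offs[k, ]
        if (!bf_inside(nb, d) || visited[t(nb)]) next
        v <- bf_get(gray, nb)
        if (!is.na(v) && v == g) {
          visited[t(nb)] <- TRUE
          queue[[length(queue) + 1]] <- nb
        }
      }
    }
    zones[[length(zones) + 1]] <- c(g, size)
  }
  maxsize <- max(vapply(zones, `[`, 0, 2))
  m <- matrix(0, n_levels, maxsize)
  for (z in zones) m[z[1], z[2]] <- m[z[1], z[2]] + 1
  m
}

bf_gldm <- function(gray, n_levels, alpha = 0) {
  d <- dim(gray)
  offs <- bf_offsets(length(d))
  offs <- rbind(offs, -offs)
  co_all <- arrayInd(seq_len(prod(d)), d)
  deps <- list()
  for (r in seq_len(nrow(co_all))) {
    co <- co_all[r, ]
    g <- bf_get(gray, co)
    if (is.na(g)) next
    dep <- 0
    for (k in seq_len(nrow(offs))) {
      nb <- co + offs[k, ]
      if (!bf_inside(nb, d)) next
      v <- bf_get(gray, nb)
      if (!is.na(v) && abs(v - g) <= alpha) dep <- dep + 1
    }
    key <- paste(g, dep + 1)
    deps[[key]] <- (deps[[key]] %||% 0) + 1
  }
  maxdep <- max(vapply(strsplit(names(deps), " "), function(p) as.integer(p[2]), 0L))
  m <- matrix(0, n_levels, maxdep)
  for (key in names(deps)) {
    p <- as.integer(strsplit(key, " ")[[1]])
    m[p[1], p[2]] <- deps[[key]]
  }
  m
}

bf_ngtdm <- function(gray, n_levels) {
  d <- dim(gray)
  offs <- bf_offsets(length(d))
  offs <- rbind(offs, -offs)
  co_all <- arrayInd(seq_len(prod(d)), d)
  n_i <- numeric(n_levels); s_i <- numeric(n_levels); n_valid <- 0
  for (r in seq_len(nrow(co_all))) {
    co <- co_all[r, ]
    g <- bf_get(gray, co)
    if (is.na(g)) next
    nb_vals <- c()
    for (k in seq_len(nrow(offs))) {
      nb <- co + offs[k, ]
      if (!bf_inside(nb, d)) next
      v <- bf_get(gray, nb)
      if (!is.na(v)) nb_vals <- c(nb_vals, v)
    }
    if (!length(nb_vals)) next
    n_valid <- n_valid + 1
    n_i[g] <- n_i[g] + 1
    s_i[g] <- s_i[g] + abs(g - mean(nb_vals))
  }
  list(n = n_i, s = s_i, n_valid = n_valid, levels = seq_len(n_levels))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random small discretized test instance: gray levels 1..L with NA holes.
random_gray_instance <- function(ndim, max_side = 8, max_levels = 6, na_frac = 0.2) {
  d <- sample(2:max_side, ndim, replace = TRUE)
  g <- array(sample.int(max_levels, prod(d), replace = TRUE), dim = d)
  holes <- runif(prod(d)) < na_frac
  if (all(holes)) holes[sample(prod(d), 1)] <- FALSE
  g[holes] <- NA_integer_
  g
}

# Trim trailing all-zero columns so matrices of different widths compare.
trim_cols <- function(m) {
  nz <- which(colSums(m != 0) > 0)
  if (!length(nz)) return(m[, 1, drop = FALSE])
  m[, seq_len(max(nz)), drop = FALSE]
}

# Naive-formula reference for a subset of features (the study's selected
# feature families), computed from the brute-force matrices with explicit
# loops — an independent route for cross-checking texture_features().
naive_reference_features <- function(g, L) {
  offs <- bf_offsets(length(dim(g)))
  nvox <- sum(!is.na(g))
  ent2 <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }

  glcm_vals <- list()
  for (k in seq_len(nrow(offs))) {
    cm <- bf_glcm(g, L, offs[k, ])
    if (sum(cm) == 0) next
    P <- cm / sum(cm)
    px <- rowSums(P); py <- colSums(P)
    mux <- 0; muy <- 0
    for (i in 1:L) for (j in 1:L) { mux <- mux + i * P[i, j]; muy <- muy + j * P[i, j] }
    sx <- 0; sy <- 0
    for (i in 1:L) for (j in 1:L) { sx <- sx + (i - mux)^2 * P[i, j]; sy <- sy + (j - muy)^2 * P[i, j] }
    iv <- 0; cs <- 0; cp <- 0; corr_num <- 0
    for (i in 1:L) for (j in 1:L) {
      if (i != j) iv <- iv + P[i, j] / (i - j)^2
      cs <- cs + (i + j - mux - muy)^3 * P[i, j]
      cp <- cp + (i + j - mux - muy)^4 * P[i, j]
      corr_num <- corr_num + (i - mux) * (j - muy) * P[i, j]
    }
    pd <- numeric(L)
    for (i in 1:L) for (j in 1:L) pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + P[i, j]
    da <- sum((0:(L - 1)) * pd)
    dv <- sum(((0:(L - 1)) - da)^2 * pd)
    HXY <- ent2(as.vector(P))
    HXY2 <- ent2(as.vector(outer(px, py)))
    imc2 <- sqrt(max(0, 1 - exp(-2 * (HXY2 - HXY))))
    mcc <- if (sum(px > 0) < 2) NA_real_ else {
      Q <- matrix(0, L, L)
      for (i in 1:L) for (j in 1:L) {
        acc <- 0
        for (kk in 1:L) if (px[i] > 0 && py[kk] > 0)
          acc <- acc + P[i, kk] * P[j, kk] / (px[i] * py[kk])
        Q[i, j] <- acc
      }
      ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
      sqrt(max(0, ev[2]))
    }
    glcm_vals[[length(glcm_vals) + 1]] <- c(
      glcm_inverse_variance = iv,
      glcm_maximum_probability = max(P),
      glcm_cluster_shade = cs,
      glcm_cluster_prominence = cp,
      glcm_correlation = if (sx > 0 && sy > 0) corr_num / sqrt(sx * sy) else NA_real_,
      glcm_difference_variance = dv,
      glcm_imc2 = imc2,
      glcm_mcc = mcc)
  }
  glcm_avg <- colMeans(do.call(rbind, glcm_vals))

  glrlm_vals <- list()
  for (k in seq_len(nrow(offs))) {
    rm <- bf_glrlm(g, L, offs[k, ])
    Nr <- sum(rm)
    if (Nr == 0) next
    p <- rm / Nr
    ri <- rowSums(rm)
    re <- ent2(as.vector(p))
    lrlgle <- 0
    for (i in seq_len(nrow(rm))) for (j in seq_len(ncol(rm)))
      lrlgle <- lrlgle + rm[i, j] * j^2 / i^2
    glrlm_vals[[length(glrlm_vals) + 1]] <- c(
      glrlm_run_entropy = re,
      glrlm_gray_level_non_uniformity = sum(ri^2) / Nr,
      glrlm_gray_level_non_uniformity_normalized = sum(ri^2) / Nr^2,
      glrlm_run_non_uniformity = sum(colSums(rm)^2) / Nr,
      glrlm_long_run_low_gray_level_emphasis = lrlgle / Nr)
  }
  glrlm_avg <- colMeans(do.call(rbind, glrlm_vals))

  zm <- bf_glszm(g, L)
  Nz <- sum(zm)
  pz <- zm / Nz
  zi <- rowSums(zm); zj <- colSums(zm)
  mu_i <- 0; mu_j <- 0
  for (i in seq_len(nrow(zm))) for (j in seq_len(ncol(zm))) {
    mu_i <- mu_i + i * pz[i, j]; mu_j <- mu_j + j * pz[i, j]
  }
  glv <- 0; zv <- 0
  for (i in seq_len(nrow(zm))) for (j in seq_len(ncol(zm))) {
    glv <- glv + (i - mu_i)^2 * pz[i, j]; zv <- zv + (j - mu_j)^2 * pz[i, j]
  }
  glszm_vals <- c(glszm_gray_level_non_uniformity = sum(zi^2) / Nz,
                  glszm_gray_level_variance = glv,
                  glszm_zone_variance = zv,
                  glszm_zone_non_uniformity = sum(zj^2) / Nz,
                  glszm_zone_entropy = ent2(as.vector(pz)),
                  glszm_zone_percentage = Nz / nvox)

  dm <- bf_gldm(g, L)
  Nd <- sum(dm)
  pdm <- dm / Nd
  mu_d <- 0
  for (i in seq_len(nrow(dm))) for (j in seq_len(ncol(dm))) mu_d <- mu_d + j * pdm[i, j]
  dvv <- 0
  for (i in seq_len(nrow(dm))) for (j in seq_len(ncol(dm))) dvv <- dvv + (j - mu_d)^2 * pdm[i, j]
  gldm_vals <- c(gldm_dependence_variance = dvv,
                 gldm_dependence_entropy = ent2(as.vector(pdm)))

  nt <- bf_ngtdm(g, L)
  N <- nt$n_valid
  p_i <- nt$n / N
  act <- which(p_i > 0)
  ngp <- length(act)
  ps <- sum(p_i * nt$s)
  contrast <- if (ngp > 1) {
    acc <- 0
    for (a in act) for (b in act) acc <- acc + p_i[a] * p_i[b] * (a - b)^2
    acc / (ngp * (ngp - 1)) * sum(nt$s) / N
  } else 0
  den_b <- 0
  for (a in act) for (b in act) den_b <- den_b + abs(a * p_i[a] - b * p_i[b])
  busy <- if (den_b > 0) ps / den_b else 0
  comp <- 0
  for (a in act) for (b in act)
    comp <- comp + abs(a - b) * (p_i[a] * nt$s[a] + p_i[b] * nt$s[b]) / (p_i[a] + p_i[b])
  comp <- comp / N
  stren <- if (sum(nt$s) > 0) {
    acc <- 0
    for (a in act) for (b in act) acc <- acc + (p_i[a] + p_i[b]) * (a - b)^2
    acc / sum(nt$s)
  } else 0
  ngtdm_vals <- c(ngtdm_coarseness = if (ps > 0) 1 / ps else NA_real_,
                  ngtdm_contrast = contrast,
                  ngtdm_busyness = busy,
                  ngtdm_complexity = comp,
                  ngtdm_strength = stren)

  c(glcm_avg, glrlm_avg, glszm_vals, gldm_vals, ngtdm_vals)
}
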