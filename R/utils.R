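## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_respiromics <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "respiromics_error")))
}

assert_that <- function(ok, msg, class = "respiromics_input_error") {
  if (!isTRUE(ok)) stop_respiromics(msg, class)
}

## Separable box smoother used for spatially correlated noise fields.
## Runs a centred moving average of half-width `h` along one array margin
## via cumulative sums; edges use the truncated window.
box_smooth_margin <- function(a, margin, h) {
  if (h < 1) return(a)
  d <- dim(a)
  n <- d[margin]
  if (n <= 1) return(a)
  perm <- c(margin, seq_along(d)[-margin])
  m <- matrix(aperm(a, perm), nrow = n)
  cs <- matrix(0, n + 1L, ncol(m))
  for (i in seq_len(n)) cs[i + 1L, ] <- cs[i, ] + m[i, ] # columnwise cumsum
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  sm <- (cs[hi + 1, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1)
  out <- array(sm, dim = d[perm])
  aperm(out, order(perm))
}

## Correlated standard-normal field: white noise smoothed in-plane with a
## box kernel of half-width ~corr_len, then rescaled to unit variance.
correlated_noise <- function(dim3, corr_len, plane_axes = c(1L, 2L)) {
  z <- array(stats::rnorm(prod(dim3)), dim = dim3)
  h <- max(0L, as.integer(round(corr_len)))
  if (h >= 1) {
    for (ax in plane_axes) z <- box_smooth_margin(z, ax, h)
    s <- stats::sd(z)
    if (s > 0) z <- z / s
  }
  z
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= 0

## Population moments used by first-order features.
pop_moment <- function(x, k) mean((x - mean(x))^k)

## Crop an array (NA = outside mask) to the bounding box of its non-NA
## voxels; the texture countings are invariant to the surrounding padding.
crop_to_mask <- function(gray) {
  d <- dim(gray)
  idx <- which(!is.na(gray))
  co <- arrayInd(idx, d)
  rng <- lapply(seq_along(d), function(k) min(co[, k]):max(co[, k]))
  do.call(`[`, c(list(gray), rng, list(drop = FALSE)))
}
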