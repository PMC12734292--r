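## Intensity discretization and first-order features over masked HU values.

#' Discretization settings
#'
#' Fixed-bin-width gray-level discretization anchored at the region minimum.
#'
#' @param bin_width Bin width in HU; must be positive.
#' @return A `discretization_settings` object.
#' @export
discretization_settings <- function(bin_width = 25) {
  assert_that(is.numeric(bin_width) && length(bin_width) == 1L && is.finite(bin_width) && bin_width > 0,
              "bin_width must be a positive number")
  structure(list(bin_width = bin_width, mode = "fixed-bin-width"),
            class = "discretization_settings")
}

#' Discretize masked HU values to gray levels
#'
#' `level(v) = floor((v - min) / bin_width) + 1`; levels are integers >= 1 and
#' the number of levels equals `level(max)`.
#'
#' @param values Non-empty numeric vector of HU values.
#' @param settings A [discretization_settings()].
#' @return Integer vector of gray levels.
#' @export
discretize <- function(values, settings = discretization_settings()) {
  assert_that(length(values) > 0, "cannot discretize an empty value set")
  assert_that(all(is.finite(values)), "values must be finite")
  as.integer(floor((values - min(values)) / settings$bin_width) + 1)
}

#' First-order features of a masked region
#'
#' Moment-based statistics use population moments (skewness `m3/m2^1.5`,
#' kurtosis `m4/m2^2` without excess correction, variance `m2`). Percentiles
#' use linear interpolation. Robust mean absolute deviation is the mean
#' absolute deviation from the mean of the values restricted to the
#' [P10, P90] range. Entropy and uniformity are computed on the discretized
#' histogram.
#'
#' @param values Non-empty numeric vector of masked HU values.
#' @param spacing Voxel spacing (mm) used for total energy; scalar voxel
#'   volumes are accepted.
#' @param settings Discretization settings for entropy/uniformity.
#' @return Named numeric vector of first-order features.
#' @export
firstorder_features <- function(values, spacing = c(1, 1, 1),
                                settings = discretization_settings()) {
  assert_that(length(values) > 0, "cannot compute first-order features of an empty region")
  vvol <- if (length(spacing) == 1L) spacing else prod(spacing)
  n <- length(values)
  m <- mean(values)
  m2 <- pop_moment(values, 2)
  p <- stats::quantile(values, c(0.10, 0.90), names = FALSE)
  inr <- values[values >= p[1] & values <= p[2]]
  rmad <- if (length(inr)) mean(abs(inr - mean(inr))) else NA_real_
  lv <- discretize(values, settings)
  pr <- tabulate(lv) / n
  pr <- pr[pr > 0]
  skew <- if (m2 > 0) pop_moment(values, 3) / m2^1.5 else 0
  kurt <- if (m2 > 0) pop_moment(values, 4) / m2^2 else 0
  c(firstorder_mean = m,
    firstorder_median = stats::median(values),
    firstorder_maximum = max(values),
    firstorder_minimum = min(values),
    firstorder_range = max(values) - min(values),
    firstorder_10percentile = p[1],
    firstorder_90percentile = p[2],
    firstorder_interquartile_range = diff(stats::quantile(values, c(0.25, 0.75), names = FALSE)),
    firstorder_rms = sqrt(mean(values^2)),
    firstorder_energy = sum(values^2),
    firstorder_total_energy = vvol * sum(values^2),
    firstorder_variance = m2,
    firstorder_sd = sqrt(m2),
    firstorder_mad = mean(abs(values - m)),
    firstorder_rmad = rmad,
    firstorder_skewness = skew,
    firstorder_kurtosis = kurt,
    firstorder_entropy = -sum(pr * log2(pr)),
    firstorder_uniformity = sum(pr^2))
}
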