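## Jensen-Shannon slice profiling, landmark selection, and construction of the
## landmark-anchored 1S/3S/5S/7S slice sets with offset configurations.

#' Default histogram bin edges for slice density profiling
#'
#' 5 HU bins over [-200, 200] HU, shared across all slices of a muscle: fine
#' enough to resolve fat/muscle bimodality, coarse enough for small slices.
#'
#' @return Numeric vector of bin edges.
#' @export
default_bin_edges <- function() seq(-200, 200, by = 5)

#' Density histogram of masked HU values
#'
#' Values outside the edge range are clipped into the end bins. The result is
#' a probability vector summing to 1.
#'
#' @param values Non-empty numeric vector of HU values.
#' @param bin_edges Increasing vector of bin edges (shared across slices).
#' @return Probability vector of length `length(bin_edges) - 1`.
#' @export
density_histogram <- function(values, bin_edges = default_bin_edges()) {
  assert_that(length(values) > 0, "cannot histogram an empty value set")
  assert_that(length(bin_edges) >= 2 && all(diff(bin_edges) > 0),
              "bin_edges must be increasing with at least two entries")
  nb <- length(bin_edges) - 1L
  bin <- findInterval(values, bin_edges, rightmost.closed = TRUE)
  bin <- pmin(pmax(bin, 1L), nb) # clip out-of-range values to end bins
  tabulate(bin, nbins = nb) / length(values)
}

#' Jensen-Shannon distance between probability vectors
#'
#' Square root of the Jensen-Shannon divergence with base-2 logarithms
#' (`m = (p + q)/2`; `JS = KL(p||m)/2 + KL(q||m)/2`; `0 log 0 = 0`), so the
#' distance is bounded in [0, 1] and symmetric.
#'
#' @param p,q Probability vectors of equal length, each summing to 1.
#' @return The distance, a scalar in [0, 1].
#' @export
js_distance <- function(p, q) {
  if (length(p) != length(q))
    stop_respiromics("probability vectors differ in length", "respiromics_input_error")
  if (any(p < 0) || any(q < 0))
    stop_respiromics("negative probability mass", "respiromics_input_error")
  assert_that(abs(sum(p) - 1) < 1e-6 && abs(sum(q) - 1) < 1e-6,
              "probability vectors must sum to 1")
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  div <- kl(p, m) / 2 + kl(q, m) / 2
  sqrt(max(0, min(1, div)))
}

#' Per-slice Jensen-Shannon profile of a filtered stack
#'
#' Each retained slice's histogram is compared with the whole-muscle
#' histogram pooled over all retained slices.
#'
#' @param stack A filtered `slice_stack`.
#' @param bin_edges Shared histogram bin edges.
#' @return A `slice_profile` data frame: `index`, `js_distance`,
#'   `pixel_count`, `mean_hu`.
#' @export
js_profile <- function(stack, bin_edges = default_bin_edges()) {
  assert_that(inherits(stack, "slice_stack"), "stack must be a slice_stack")
  vals <- slice_values(stack, retained_only = TRUE)
  assert_that(length(vals) > 0, "no retained slices")
  pooled <- density_histogram(unlist(vals, use.names = FALSE), bin_edges)
  js <- vapply(vals, function(v) js_distance(density_histogram(v, bin_edges), pooled), 0)
  ret <- stack[stack$retained, ]
  structure(data.frame(index = ret$index, js_distance = unname(js),
                       pixel_count = ret$pixel_count, mean_hu = ret$mean_hu),
            class = c("slice_profile", "data.frame"))
}

#' Select the protocol landmark slice
#'
#' `fixed` mode validates and returns a supplied index (used when an
#' anatomical landmark accompanies the data). `auto` mode is the data-driven
#' surrogate: the retained slice minimizing a rolling median (window 5) of
#' the Jensen-Shannon distance, restricted to the central 50% of retained
#' slices; ties break toward the muscle midpoint.
#'
#' @param profile A `slice_profile` from [js_profile()].
#' @param mode `"auto"` or `"fixed"`.
#' @param fixed_index Landmark index for `fixed` mode (0-based).
#' @return A 0-based slice index.
#' @export
select_landmark <- function(profile, mode = c("auto", "fixed"), fixed_index = NULL) {
  mode <- match.arg(mode)
  assert_that(inherits(profile, "slice_profile") && nrow(profile) > 0, "profile is empty")
  if (mode == "fixed") {
    assert_that(!is.null(fixed_index), "fixed mode requires fixed_index")
    if (!fixed_index %in% profile$index)
      stop_respiromics(sprintf("fixed landmark %d outside retained range", fixed_index),
                       "respiromics_protocol_error")
    return(as.integer(fixed_index))
  }
  n <- nrow(profile)
  js <- profile$js_distance
  roll <- if (n >= 5) stats::runmed(js, 5, endrule = "median") else js
  lo <- floor(n / 4) + 1L
  hi <- n - floor(n / 4)
  central <- lo:hi
  mid <- (n + 1) / 2
  best <- central[roll[central] <= min(roll[central]) + 1e-12]
  best <- best[order(abs(best - mid), best)][1]
  as.integer(profile$index[best])
}

#' Build landmark-anchored slice sets
#'
#' For anchor `a = landmark + offset`, a set of size `2k + 1` is
#' `{a - k*stride, ..., a, ..., a + k*stride}`. All resolved indices must be
#' retained slices; otherwise a boundary error names the offending set.
#'
#' @param landmark 0-based landmark slice index.
#' @param retained_indices Sorted 0-based indices of retained slices.
#' @param sizes Set sizes (odd); default `c(1, 3, 5, 7)`.
#' @param stride Slices between consecutive sampled slices (default 6, i.e.
#'   five slices interposed).
#' @param offsets Landmark offsets; default `-2:2`.
#' @return A `slice_set` list, one element per (size, offset) combination,
#'   each with fields `landmark`, `size`, `stride`, `offset`, `indices`.
#' @export
build_slice_sets <- function(landmark, retained_indices, sizes = c(1, 3, 5, 7),
                             stride = 6L, offsets = -2:2) {
  assert_that(landmark %in% retained_indices, "landmark must be a retained slice")
  assert_that(all(sizes %% 2 == 1), "set sizes must be odd")
  sets <- list()
  for (size in sizes) {
    k <- (size - 1) / 2
    for (off in offsets) {
      a <- landmark + off
      idx <- a + stride * (-k:k)
      missing <- setdiff(idx, retained_indices)
      if (length(missing))
        stop_respiromics(sprintf("slice set %dS offset %+d: indices {%s} outside the retained slices",
                                 size, off, paste(missing, collapse = ", ")),
                         "respiromics_boundary_error")
      sets[[length(sets) + 1L]] <- structure(
        list(landmark = as.integer(landmark), size = as.integer(size),
             stride = as.integer(stride), offset = as.integer(off),
             indices = as.integer(idx)),
        class = "slice_set")
    }
  }
  sets
}

#' Serialize slice sets to JSON
#'
#' @param sets A list of `slice_set`s from [build_slice_sets()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_slice_sets <- function(sets, path) {
  jsonlite::write_json(lapply(sets, unclass), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
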