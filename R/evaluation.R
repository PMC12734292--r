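## Deviation of slice-set metrics from whole-muscle references (MAE in HU for
## density/SD, MAPE in % for radiomic features) and the statistical battery
## comparing set sizes and offsets.

#' Per-set deviation rows against a whole-muscle reference
#'
#' Density and SD deviations are absolute differences in HU; radiomic
#' deviations are absolute percentage errors. Features whose reference
#' magnitude is below `epsilon`, or which are flagged/`NA` in either vector,
#' yield flagged rows that aggregation excludes.
#'
#' @param whole Reference `feature_vector` (whole retained muscle).
#' @param sets List of elements, each a list with `set` (a `slice_set`) and
#'   `features` (its `feature_vector`).
#' @param epsilon Minimum reference magnitude for a percentage error.
#' @return Data frame with columns `feature`, `class`, `category`,
#'   `set_size`, `offset`, `deviation`, `unit`, `flagged`.
#' @export
deviation_table <- function(whole, sets, epsilon = 1e-8) {
  assert_that(inherits(whole, "feature_vector"), "whole must be a feature_vector")
  out <- list()
  wflag <- attr(whole, "flagged")
  for (entry in sets) {
    st <- entry$set; fv <- entry$features
    missing <- setdiff(names(fv), names(whole))
    if (length(missing))
      stop_respiromics(sprintf("reference lacks features: %s",
                               paste(utils::head(missing, 5), collapse = ", ")),
                       "respiromics_input_error")
    cls <- feature_class(names(fv))
    w <- as.numeric(whole[names(fv)])
    v <- as.numeric(fv)
    hu <- cls == "density"
    dev <- ifelse(hu, abs(v - w),
                  ifelse(abs(w) >= epsilon, 100 * abs(v - w) / abs(w), NA_real_))
    flagged <- is.na(v) | is.na(w) | names(fv) %in% c(wflag, attr(fv, "flagged")) |
      (!hu & abs(w) < epsilon)
    out[[length(out) + 1L]] <- data.frame(
      feature = names(fv), class = cls, category = feature_category(names(fv)),
      set_size = paste0(st$size, "S"), offset = st$offset,
      deviation = dev, unit = ifelse(hu, "HU", "%"), flagged = flagged,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Aggregate deviation rows into MAE/MAPE tables
#'
#' Aggregates are means of non-flagged deviations over subjects and offsets,
#' per (muscle if present, feature, set size). A min-max normalized MAPE
#' across set sizes is added per feature for plotting.
#'
#' @param rows Deviation rows from [deviation_table()] (optionally with
#'   `subject`/`muscle` columns prepended).
#' @return Data frame with columns `muscle` (if supplied), `feature`,
#'   `class`, `category`, `unit`, `set_size`, `error` (MAE in HU or MAPE in
#'   %), `n`, and `normalized_error`.
#' @export
aggregate_errors <- function(rows) {
  assert_that(nrow(rows) > 0, "no deviation rows to aggregate")
  ok <- !rows$flagged & is.finite(rows$deviation)
  rows <- rows[ok, , drop = FALSE]
  assert_that(nrow(rows) > 0, "all deviation rows are flagged")
  keys <- c(intersect("muscle", names(rows)), "feature", "class", "category", "unit", "set_size")
  agg <- stats::aggregate(rows["deviation"], rows[keys], mean)
  cnt <- stats::aggregate(list(n = rows$deviation), rows[keys], length)
  agg <- merge(agg, cnt, by = keys)
  names(agg)[names(agg) == "deviation"] <- "error"
  fkeys <- setdiff(keys, "set_size")
  agg$normalized_error <- stats::ave(agg$error, agg[fkeys], FUN = function(e) {
    r <- range(e)
    if (diff(r) == 0) rep(0, length(e)) else (e - r[1]) / diff(r)
  })
  agg[order(agg$feature, agg$set_size), , drop = FALSE]
}

#' Dunn's post hoc test
#'
#' Rank-based pairwise z-tests after a Kruskal-Wallis rejection, with tie
#' correction and p-value adjustment.
#'
#' @param x Numeric values.
#' @param g Grouping vector.
#' @param method Multiplicity correction passed to [stats::p.adjust()]
#'   (default `"holm"`).
#' @return Data frame with `group1`, `group2`, `z`, `p`, `p_adjusted`.
#' @export
dunn_test <- function(x, g, method = "holm") {
  g <- factor(g)
  assert_that(nlevels(g) >= 2, "need at least two groups")
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ni <- tabulate(g)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_term
  combs <- utils::combn(levels(g), 2)
  z <- apply(combs, 2, function(pr) {
    i <- which(levels(g) == pr[1]); j <- which(levels(g) == pr[2])
    (rbar[i] - rbar[j]) / sqrt(s2 * (1 / ni[i] + 1 / ni[j]))
  })
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = combs[1, ], group2 = combs[2, ], z = as.numeric(z),
             p = as.numeric(p), p_adjusted = stats::p.adjust(p, method = method),
             stringsAsFactors = FALSE)
}

#' Normality-routed group comparison
#'
#' Shapiro-Wilk on pooled within-group residuals routes to one-way ANOVA
#' (normal) or Kruskal-Wallis; when the omnibus test rejects at `alpha`,
#' Dunn's pairwise test with Holm correction follows. Degenerate (zero
#' variance) inputs are flagged rather than tested.
#'
#' @param x Numeric values.
#' @param g Grouping vector (>= 2 groups, >= 3 observations each).
#' @param alpha Significance level (default 0.05).
#' @param correction Dunn correction method (default `"holm"`).
#' @return A `comparison_result` list: `normality_p`, `omnibus`, `omnibus_p`,
#'   `posthoc` (data frame or `NULL`), `significant_pairs`, `degenerate`.
#' @export
compare_groups <- function(x, g, alpha = 0.05, correction = "holm") {
  g <- factor(g)
  assert_that(nlevels(g) >= 2, "need at least two groups")
  if (any(tabulate(g) < 3))
    stop_respiromics("need at least three observations per group", "respiromics_input_error")
  if (stats::sd(x) == 0) {
    return(structure(list(normality_p = NA_real_, omnibus = "none",
                          omnibus_p = NA_real_, posthoc = NULL,
                          significant_pairs = character(0), degenerate = TRUE),
                     class = "comparison_result"))
  }
  resid <- x - stats::ave(x, g)
  rs <- resid
  if (length(rs) > 5000) rs <- rs[seq(1, length(rs), length.out = 5000)]
  norm_p <- if (stats::sd(rs) == 0) 0 else stats::shapiro.test(rs)$p.value
  if (norm_p >= alpha) {
    omnibus <- "anova"
    fit <- stats::aov(x ~ g)
    p <- summary(fit)[[1]][["Pr(>F)"]][1]
  } else {
    omnibus <- "kruskal-wallis"
    p <- stats::kruskal.test(x, g)$p.value
  }
  posthoc <- NULL
  sig <- character(0)
  if (is.finite(p) && p < alpha) {
    posthoc <- dunn_test(x, g, method = correction)
    sel <- posthoc$p_adjusted < alpha
    sig <- paste(posthoc$group1[sel], posthoc$group2[sel], sep = " vs ")
  }
  structure(list(normality_p = norm_p, omnibus = omnibus, omnibus_p = p,
                 posthoc = posthoc, significant_pairs = sig, degenerate = FALSE),
            class = "comparison_result")
}

#' Compare deviations across slice-set sizes (or offsets)
#'
#' Runs [compare_groups()] per feature (and muscle, when present) on
#' deviation rows, grouping by `group_by`.
#'
#' @param rows Deviation rows (see [deviation_table()]).
#' @param group_by Grouping column, default `"set_size"`.
#' @param value Value column, default `"deviation"`.
#' @param alpha Significance level.
#' @return Named list of `comparison_result`s, keyed by `muscle:feature` (or
#'   `feature`).
#' @export
compare_set_sizes <- function(rows, group_by = "set_size", value = "deviation",
                              alpha = 0.05) {
  rows <- rows[!rows$flagged & is.finite(rows[[value]]), , drop = FALSE]
  assert_that(nrow(rows) > 0, "no usable rows")
  key <- if ("muscle" %in% names(rows)) paste(rows$muscle, rows$feature, sep = ":") else rows$feature
  out <- lapply(split(rows, key), function(d)
    compare_groups(d[[value]], d[[group_by]], alpha = alpha))
  out
}

#' Kendall's W to Cohen's f conversion
#'
#' @param w Kendall's W in [0, 1).
#' @return `sqrt(w / (1 - w))`.
#' @export
cohen_f_from_w <- function(w) {
  assert_that(all(w >= 0 & w < 1), "Kendall's W must lie in [0, 1)")
  sqrt(w / (1 - w))
}

#' Friedman-based effect size and post hoc power
#'
#' Computes the Friedman chi-square (tie-corrected, implemented directly;
#' cross-checked against [stats::friedman.test()] in the test suite),
#' Kendall's W `= chi2 / (n (k - 1))`, Cohen's f `= sqrt(W / (1 - W))`, and
#' an approximate power from the noncentral-F distribution with numerator df
#' `k - 1`, denominator df `(n - 1)(k - 1)`, and noncentrality `f^2 n k`.
#'
#' @param values Complete numeric matrix, subjects in rows, conditions (e.g.
#'   set sizes) in columns, k >= 2.
#' @param alpha Significance level for the power computation.
#' @return An `effect_size_result` list with `friedman_chi2`, `kendall_w`,
#'   `cohen_f`, `power`, `k`, `n`, `alpha`, `method`.
#' @export
friedman_effect <- function(values, alpha = 0.05) {
  values <- as.matrix(values)
  assert_that(ncol(values) >= 2, "need at least two conditions")
  if (any(!is.finite(values)))
    stop_respiromics("values matrix must be complete", "respiromics_input_error")
  n <- nrow(values); k <- ncol(values)
  r <- t(apply(values, 1, rank))
  Rj <- colSums(r)
  A <- sum(r^2)
  C <- n * k * (k + 1)^2 / 4
  chi2 <- if (A == C) 0 else (k - 1) * sum((Rj - n * (k + 1) / 2)^2) / (A - C)
  w <- chi2 / (n * (k - 1))
  w <- min(max(w, 0), 1 - 1e-12)
  f <- cohen_f_from_w(w)
  df1 <- k - 1
  df2 <- (n - 1) * (k - 1)
  lambda <- f^2 * n * k
  power <- 1 - stats::pf(stats::qf(1 - alpha, df1, df2), df1, df2, ncp = lambda)
  structure(list(friedman_chi2 = chi2, kendall_w = w, cohen_f = f, power = power,
                 k = k, n = n, alpha = alpha,
                 method = "noncentral-F approximation (df1 = k-1, df2 = (n-1)(k-1), ncp = f^2*n*k)"),
            class = "effect_size_result")
}
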