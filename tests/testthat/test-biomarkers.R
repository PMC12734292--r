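test_that("density group statistics run the routed two-group tests", {
  set.seed(70)
  n <- 30; sarc <- rep(c(TRUE, FALSE), c(17, 13))
  dens <- data.frame(PM = stats::rnorm(n, ifelse(sarc, 15, 37), 15),
                     Pm = stats::rnorm(n, ifelse(sarc, 23, 33), 14))
  age <- stats::rnorm(n, ifelse(sarc, 70, 56), 12)
  bmi <- stats::rnorm(n, 23, 3)
  res <- density_group_stats(dens, sarc, age, bmi)
  expect_true(all(res$group_tests$delta < 0))
  expect_lt(res$group_tests$p[res$group_tests$muscle == "PM"], 0.05)
  expect_gt(res$age_sarcopenia$rho, 0)
  expect_equal(nrow(res$age_table), 2 * 3)
  ## identical groups: p near 1, delta 0
  dens2 <- data.frame(PM = rep(c(10, 20, 30, 40, 50), 6))
  r2 <- density_group_stats(dens2, rep(c(TRUE, FALSE), each = 15),
                            age, bmi)
  expect_equal(r2$group_tests$delta, 0)
  expect_gt(r2$group_tests$p, 0.9)
  expect_error(density_group_stats(dens[1:4, ], c(TRUE, TRUE, FALSE, FALSE), age[1:4], bmi[1:4]))
})

test_that("permuted labels keep the per-muscle false-positive rate at alpha", {
  set.seed(71)
  n <- 30
  dens <- matrix(stats::rnorm(n * 4, 20, 15), n, 4,
                 dimnames = list(NULL, c("PM", "Pm", "SA", "4I")))
  age <- stats::rnorm(n, 60, 15); bmi <- stats::rnorm(n, 23, 3)
  n_rep <- 200; sig <- 0; tot <- 0
  for (i in seq_len(n_rep)) {
    sarc <- sample(rep(c(TRUE, FALSE), c(17, 13)))
    res <- density_group_stats(dens, sarc, age, bmi)
    sig <- sig + sum(res$group_tests$p < 0.05)
    tot <- tot + nrow(res$group_tests)
  }
  rate <- sig / tot
  expect_lte(rate, 0.05 + 2 * sqrt(0.05 * 0.95 / tot))
})

test_that("cleaning removes constants, duplicates, and correlation hubs", {
  set.seed(72)
  n <- 2000
  ## hub construction: r(hub, a) = r(hub, b) ~ 0.93 (above threshold), while
  ## r(a, b) ~ 0.87 stays below it, so only the hub must go
  z0 <- stats::rnorm(n); delta <- 0.3952
  c1 <- z0
  c2 <- z0 + delta * stats::rnorm(n)
  c3 <- z0 + delta * stats::rnorm(n)
  x <- cbind(hub = c1, a = c2, b = c3, const = rep(1, n),
             withna = c(NA, stats::rnorm(n - 1)))
  cl <- clean_features(x, corr_threshold = 0.9)
  expect_identical(attr(cl, "dropped_zero_variance"), "const")
  expect_identical(attr(cl, "dropped_missing"), "withna")
  expect_identical(attr(cl, "dropped_correlated"), "hub")
  expect_identical(colnames(cl), c("a", "b"))
  expect_equal(unname(colMeans(cl)), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(apply(cl, 2, stats::sd)), c(1, 1), tolerance = 1e-9)
  ## duplicated column: exactly one of the pair is removed
  z4 <- stats::rnorm(n)
  y <- cbind(f1 = z0, f2 = z0, f3 = z4)
  cly <- clean_features(y)
  expect_length(attr(cly, "dropped_correlated"), 1L)
  expect_true("f3" %in% colnames(cly))
  ## idempotence
  cl2 <- clean_features(cl)
  expect_identical(colnames(cl2), colnames(cl))
})

test_that("LASSO recovers planted informative features and is deterministic", {
  ## the CV-deviance minimizer is deliberately liberal (it admits a handful
  ## of noise features alongside every informative one), so false-positive
  ## control is asserted as the per-feature selection rate: informative
  ## features are selected nearly always, each noise feature only rarely
  recalls <- c(); noise_rates <- c()
  for (s in 1:20) {
    set.seed(s)
    d <- planted_matrix(n = 120, p = 50, informative = 5, effect = 1.0)
    sel <- lasso_select(scale(d$x), d$labels, seed = s)
    recalls <- c(recalls, length(intersect(sel, d$informative)) / 5)
    noise_rates <- c(noise_rates, length(setdiff(sel, d$informative)) / 45)
  }
  expect_gte(mean(recalls), 0.8)
  expect_lte(mean(noise_rates), 0.3)
  set.seed(1)
  d <- planted_matrix()
  s1 <- lasso_select(scale(d$x), d$labels, seed = 9)
  s2 <- lasso_select(scale(d$x), d$labels, seed = 9)
  expect_identical(as.character(s1), as.character(s2))
})

test_that("LASSO selects little under an all-noise design", {
  counts <- vapply(1:20, function(s) {
    set.seed(s)
    x <- matrix(stats::rnorm(120 * 50), 120, 50,
                dimnames = list(NULL, paste0("f", 1:50)))
    labels <- rep(c(TRUE, FALSE), each = 60)
    length(lasso_select(x, labels, seed = s))
  }, 0)
  expect_lte(median(counts), 2)
  expect_error(lasso_select(matrix(stats::rnorm(40), 20), rep(TRUE, 20), seed = 1))
})

test_that("backward refinement keeps strong predictors and drops noise", {
  keep_strong <- 0; kept_noise <- 0
  for (s in 1:20) {
    set.seed(s)
    n <- 90
    x <- cbind(strong = stats::rnorm(n), n1 = stats::rnorm(n), n2 = stats::rnorm(n),
               n3 = stats::rnorm(n))
    eta <- 1.5 * x[, "strong"]
    y <- stats::runif(n) < stats::plogis(eta)
    res <- stepwise_refine(x, y)
    if ("strong" %in% res$features$feature) keep_strong <- keep_strong + 1
    kept_noise <- kept_noise + length(setdiff(res$features$feature, "strong"))
  }
  expect_gte(keep_strong, 15) # majority of seeds
  expect_lte(kept_noise / 20, 1)
  ## surviving coefficients all satisfy the Wald threshold
  set.seed(5)
  x <- cbind(strong = stats::rnorm(120), n1 = stats::rnorm(120))
  y <- stats::runif(120) < stats::plogis(1.5 * x[, "strong"])
  res <- stepwise_refine(x, y)
  expect_true(all(res$features$p < 0.05))
})

test_that("degenerate stepwise inputs behave per contract", {
  res <- stepwise_refine(matrix(numeric(0), 10, 0), rep(c(TRUE, FALSE), 5))
  expect_equal(nrow(res$features), 0L)
  expect_false(res$separation)
  ## two identical candidates: the aliased (later) one is eliminated
  set.seed(73)
  z <- stats::rnorm(60)
  x <- cbind(f1 = z, f2 = z)
  y <- stats::runif(60) < stats::plogis(z)
  res2 <- stepwise_refine(x, y)
  expect_false("f2" %in% res2$features$feature)
  ## separation: flagged with penalized fallback
  xs <- cbind(f1 = c(rep(-2, 15), rep(2, 15)))
  ys <- xs[, 1] > 0
  res3 <- stepwise_refine(xs, ys)
  expect_true(res3$separation)
  expect_true(nrow(res3$features) >= 1)
})

test_that("group deltas are standardized differences with the stated sign convention", {
  set.seed(74)
  labels <- rep(c(TRUE, FALSE), each = 20)
  x <- cbind(up = stats::rnorm(40) + labels * 1.0, flat = stats::rnorm(40))
  d <- group_delta(x, labels)
  expect_gt(d$delta[d$feature == "up"], 0) # sarcopenic-higher => positive
  ## identical groups
  x0 <- cbind(f = rep(c(1, 2, 3, 4), 10))
  d0 <- group_delta(x0, rep(c(TRUE, FALSE), each = 20))
  expect_equal(d0$delta, 0)
  expect_gt(d0$p, 0.9)
  ## 1 SD planted effect: delta near 1 and usually significant
  hits <- 0; deltas <- c()
  for (s in 1:20) {
    set.seed(s)
    lab <- rep(c(TRUE, FALSE), each = 15)
    xx <- cbind(glcm_f = stats::rnorm(30) + lab * 1.0)
    dd <- group_delta(xx, lab)
    deltas <- c(deltas, dd$delta)
    if (dd$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 20, 0.8)
  expect_gt(mean(deltas), 0.6)
  expect_lt(mean(deltas), 1.2)
})

test_that("logistic odds ratios reproduce the contingency-table cross product", {
  ## a = 8, b = 2, c = 4, d = 6 -> OR = (8 * 6) / (2 * 4) = 6
  exposure <- c(rep(1, 10), rep(0, 10))
  outcome <- c(rep(TRUE, 8), rep(FALSE, 2), rep(TRUE, 4), rep(FALSE, 6))
  or <- respiromics:::logistic_odds_ratio(data.frame(exposure = exposure), outcome)
  expect_equal(or$or, 6, tolerance = 1e-6)
})

test_that("cluster score CIs cover 1 under label-independent features", {
  set.seed(75)
  cover_v <- 0; cover_s <- 0; n_rep <- 100
  for (i in seq_len(n_rep)) {
    x <- matrix(stats::rnorm(30 * 8), 30, 8,
                dimnames = list(NULL, c(paste0("glcm_f", 1:4), paste0("firstorder_f", 1:4))))
    labels <- sample(rep(c(TRUE, FALSE), c(17, 13)))
    or <- cluster_association(x, labels)
    v <- or[or$term == "variability_score", ]
    s <- or[or$term == "structural_score", ]
    if (v$ci_lower <= 1 && v$ci_upper >= 1) cover_v <- cover_v + 1
    if (s$ci_lower <= 1 && s$ci_upper >= 1) cover_s <- cover_s + 1
  }
  expect_gte(cover_v / n_rep, 0.9)
  expect_gte(cover_s / n_rep, 0.9)
  expect_error(cluster_association(matrix(1, 10, 2, dimnames = list(NULL, c("glcm_a", "shape_b"))),
                                   rep(c(TRUE, FALSE), 5)))
})

test_that("sarcopenic muscles raise variability scores and depress structural scores", {
  ## reduced cohorts of PM-like muscles, whole-volume radiomics, full
  ## selection pipeline; direction must hold in the majority of seeds
  n_seeds <- 12
  v_up <- 0; s_dn <- 0; usable <- 0
  specs <- list(s = default_muscle_specs("sarcopenic"),
                n = default_muscle_specs("non_sarcopenic"))
  anc <- respiromics:::.density_anchors$PM
  for (s in seq_len(n_seeds)) {
    set.seed(500 + s)
    rows <- list(); labs <- c(); nm <- NULL
    for (i in 1:14) {
      grp <- if (i <= 8) "s" else "n"
      full <- if (grp == "s") "sarcopenic" else "non_sarcopenic"
      sp <- specs[[grp]]$PM
      sp$n_slices <- 50L; sp$landmark_true <- 25L
      sp$fat_fraction <- min(0.85, max(0.02, stats::rnorm(1, sp$fat_fraction, 0.04)))
      sp$mu_muscle <- respiromics:::calibrate_mu(sp, anc$mean[[full]] + stats::rnorm(1, 0, anc$sd[[full]]))
      g <- generate_muscle_volume(NULL, sp)
      st <- filter_slices(build_stack(g$volume, g$mask))
      fv <- extract_features(g$volume, g$mask, "whole_3d", stack = st)
      rows[[i]] <- as.numeric(fv); labs <- c(labs, grp == "s"); nm <- names(fv)
    }
    mat <- do.call(rbind, rows); colnames(mat) <- nm
    sel <- select_biomarkers(mat, labs, seed = s)
    or <- sel$cluster_or
    if (is.null(or)) next
    usable <- usable + 1
    if (or$or[or$term == "variability_score"] > 1) v_up <- v_up + 1
    if (or$or[or$term == "structural_score"] < 1) s_dn <- s_dn + 1
  }
  expect_gte(usable, 8)
  expect_gt(v_up / usable, 0.5)
  expect_gt(s_dn / usable, 0.5)
})

test_that("selection stages nest and separate planted signal from permuted labels", {
  planted_hits <- 0; permuted_hits <- 0
  for (s in 1:10) {
    set.seed(s)
    d <- planted_matrix(n = 80, p = 20, informative = 3, effect = 1.2)
    sel <- select_biomarkers(d$x, d$labels, seed = s)
    expect_true(all(sel$lasso_selected %in% sel$cleaned))
    expect_true(all(sel$final$feature %in% sel$lasso_selected))
    if (any(d$informative %in% sel$final$feature)) planted_hits <- planted_hits + 1
    perm <- sample(d$labels)
    selp <- select_biomarkers(d$x, perm, seed = s)
    if (nrow(selp$final) >= 1) permuted_hits <- permuted_hits + 1
  }
  expect_gte(planted_hits / 10, 0.8)
  expect_gte(planted_hits - permuted_hits, 2) # clear sanity separation
})
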