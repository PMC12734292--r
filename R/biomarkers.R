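## Sarcopenia-association analysis: density group statistics, feature
## cleaning, penalized selection with backward refinement, standardized group
## deltas, and variability-vs-structural cluster odds ratios.

#' Density group and demographic statistics
#'
#' Per-muscle two-group comparison (Shapiro-routed Welch t-test or
#' Mann-Whitney U), an age-group density table (18-45, 46-69, >= 70 years),
#' the Spearman correlation of age with sarcopenia status (Fisher-z
#' approximate CI), and the BMI-density correlation per muscle.
#'
#' @param densities Data frame or matrix of whole-muscle mean densities,
#'   subjects in rows, muscles in columns.
#' @param sarcopenic Logical vector of labels.
#' @param age,bmi Numeric vectors.
#' @param alpha Normality-routing level.
#' @return List with `group_tests`, `age_table`, `age_sarcopenia`,
#'   `bmi_density`.
#' @export
density_group_stats <- function(densities, sarcopenic, age, bmi, alpha = 0.05) {
  densities <- as.data.frame(densities)
  n1 <- sum(sarcopenic); n0 <- sum(!sarcopenic)
  assert_that(n1 >= 3 && n0 >= 3, "need at least three subjects per group")
  group_tests <- do.call(rbind, lapply(names(densities), function(mu) {
    x1 <- densities[[mu]][sarcopenic]
    x0 <- densities[[mu]][!sarcopenic]
    normal <- all(vapply(list(x1, x0), function(v)
      stats::sd(v) == 0 || stats::shapiro.test(v)$p.value >= alpha, TRUE))
    if (stats::sd(c(x1, x0)) == 0) {
      test <- "degenerate"; p <- 1
    } else if (normal) {
      test <- "welch"; p <- stats::t.test(x1, x0)$p.value
    } else {
      test <- "mann-whitney"; p <- stats::wilcox.test(x1, x0, exact = FALSE)$p.value
    }
    data.frame(muscle = mu, mean_sarcopenic = mean(x1), mean_non_sarcopenic = mean(x0),
               delta = mean(x1) - mean(x0), test = test, p = p, stringsAsFactors = FALSE)
  }))
  age_group <- cut(age, c(18, 46, 70, Inf), right = FALSE,
                   labels = c("18-45", "46-69", ">=70"), include.lowest = TRUE)
  age_table <- do.call(rbind, lapply(names(densities), function(mu) {
    data.frame(muscle = mu, age_group = levels(age_group),
               mean = as.numeric(tapply(densities[[mu]], age_group, mean)),
               sd = as.numeric(tapply(densities[[mu]], age_group, stats::sd)),
               n = as.numeric(table(age_group)), stringsAsFactors = FALSE)
  }))
  rho <- suppressWarnings(stats::cor.test(age, as.numeric(sarcopenic), method = "spearman"))
  nz <- length(age)
  ci <- if (nz > 3) tanh(atanh(rho$estimate) + c(-1, 1) * 1.96 / sqrt(nz - 3)) else c(NA, NA)
  bmi_density <- do.call(rbind, lapply(names(densities), function(mu) {
    ct <- suppressWarnings(stats::cor.test(bmi, densities[[mu]], method = "spearman"))
    data.frame(muscle = mu, rho = unname(ct$estimate), p = ct$p.value, stringsAsFactors = FALSE)
  }))
  list(group_tests = group_tests, age_table = age_table,
       age_sarcopenia = list(rho = unname(rho$estimate), p = rho$p.value,
                             ci95 = as.numeric(ci), ci_method = "Fisher z, approximate"),
       bmi_density = bmi_density)
}

#' Clean a feature matrix
#'
#' Drops zero-variance and any-missing columns, then iteratively removes one
#' member of the most correlated pair above `corr_threshold` (the member
#' with the larger mean absolute correlation to all remaining features),
#' and finally z-scores the surviving columns.
#'
#' @param x Numeric matrix or data frame, subjects x features.
#' @param corr_threshold Absolute Pearson correlation threshold (default 0.9).
#' @return Z-scored matrix with attributes `dropped_zero_variance`,
#'   `dropped_missing`, `dropped_correlated`.
#' @export
clean_features <- function(x, corr_threshold = 0.9) {
  x <- as.matrix(x)
  assert_that(ncol(x) > 0 && nrow(x) > 1, "feature matrix must have rows and columns")
  has_na <- colnames(x)[apply(x, 2, function(v) any(!is.finite(v)))]
  x <- x[, setdiff(colnames(x), has_na), drop = FALSE]
  zero_var <- colnames(x)[apply(x, 2, stats::sd) == 0]
  x <- x[, setdiff(colnames(x), zero_var), drop = FALSE]
  dropped_corr <- character(0)
  repeat {
    if (ncol(x) < 2) break
    C <- abs(stats::cor(x))
    diag(C) <- 0
    mx <- max(C)
    if (mx <= corr_threshold) break
    pair <- which(C == mx, arr.ind = TRUE)[1, ]
    mean_abs <- colMeans(C)
    drop_idx <- if (mean_abs[pair[1]] >= mean_abs[pair[2]]) pair[1] else pair[2]
    dropped_corr <- c(dropped_corr, colnames(x)[drop_idx])
    x <- x[, -drop_idx, drop = FALSE]
  }
  if (ncol(x) == 0)
    stop_respiromics("cleaning removed every feature", "respiromics_input_error")
  x <- scale(x)
  attr(x, "scaled:center") <- NULL
  attr(x, "scaled:scale") <- NULL
  structure(x, dropped_zero_variance = zero_var, dropped_missing = has_na,
            dropped_correlated = dropped_corr)
}

#' LASSO feature selection for sarcopenia
#'
#' Penalized logistic regression with the regularization weight chosen as
#' the 10-fold cross-validated deviance minimizer on a seeded fold split;
#' returns features with nonzero coefficients.
#'
#' @param x Cleaned (z-scored) feature matrix.
#' @param labels Logical or 0/1 sarcopenia labels.
#' @param folds Number of CV folds (default 10).
#' @param seed Integer seed fixing the fold assignment.
#' @return Character vector of selected feature names, with attribute
#'   `lambda`.
#' @export
lasso_select <- function(x, labels, folds = 10, seed = 1L) {
  x <- as.matrix(x)
  y <- as.numeric(labels)
  assert_that(length(unique(y)) == 2, "labels must contain both classes")
  set.seed(seed)
  foldid <- sample(rep(seq_len(folds), length.out = nrow(x)))
  fit <- glmnet::cv.glmnet(x, y, family = "binomial", foldid = foldid,
                           type.measure = "deviance")
  cf <- as.matrix(stats::coef(fit, s = "lambda.min"))
  sel <- rownames(cf)[cf[, 1] != 0 & rownames(cf) != "(Intercept)"]
  structure(sel, lambda = fit$lambda.min)
}

#' Backward stepwise refinement of a candidate feature set
#'
#' AIC-driven backward elimination from the full logistic model, followed by
#' iterative removal of coefficients with Wald p >= 0.05. Aliased duplicate
#' columns are dropped (later-indexed first). If complete separation is
#' detected, the result is flagged and a ridge-penalized fallback supplies
#' the surviving feature set (without Wald p-values).
#'
#' @param x Feature matrix restricted to the candidate features.
#' @param labels Logical or 0/1 labels.
#' @param alpha Wald retention threshold (default 0.05).
#' @return List with `features` (data frame `feature`, `estimate`, `p`) and
#'   `separation` flag.
#' @export
stepwise_refine <- function(x, labels, alpha = 0.05) {
  x <- as.matrix(x)
  y <- as.numeric(labels)
  if (ncol(x) == 0)
    return(list(features = data.frame(feature = character(0), estimate = numeric(0),
                                      p = numeric(0), stringsAsFactors = FALSE),
                separation = FALSE))
  assert_that(nrow(x) > ncol(x) + 2, "need n > number of candidate features + 2")
  colnames(x) <- colnames(x) %||% paste0("f", seq_len(ncol(x)))
  dat <- data.frame(.y = y, x, check.names = FALSE)
  sep <- FALSE
  fit_glm <- function(d) {
    withCallingHandlers(
      ## do.call embeds the evaluated data frame in the call so that
      ## stepAIC's model updates can re-fit outside this scope
      do.call(stats::glm, list(formula = .y ~ ., data = d, family = stats::binomial())),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          sep <<- TRUE
        invokeRestart("muffleWarning")
      })
  }
  full <- fit_glm(dat)
  aliased <- names(stats::coef(full))[is.na(stats::coef(full))]
  if (length(aliased)) {
    dat <- dat[, setdiff(names(dat), aliased), drop = FALSE]
    full <- fit_glm(dat)
  }
  ## a perfectly separating model can converge without glm's warning:
  ## vanishing deviance against a non-trivial null is the giveaway
  if (full$deviance < 1e-6 && full$null.deviance > 1) sep <- TRUE
  if (sep) {
    xr <- if (ncol(x) == 1L) cbind(x, .pad = 0) else x
    rf <- glmnet::glmnet(xr, y, family = "binomial", alpha = 0, lambda = 0.05)
    cf <- as.matrix(stats::coef(rf))
    keep <- rownames(cf)[abs(cf[, 1]) > 1e-6 & !rownames(cf) %in% c("(Intercept)", ".pad")]
    return(list(features = data.frame(feature = keep,
                                      estimate = cf[keep, 1], p = NA_real_,
                                      stringsAsFactors = FALSE, row.names = NULL),
                separation = TRUE,
                note = "complete separation; ridge-penalized fallback, Wald p unavailable"))
  }
  red <- suppressWarnings(MASS::stepAIC(full, direction = "backward", trace = 0))
  vars <- setdiff(names(stats::coef(red)), "(Intercept)")
  repeat {
    if (!length(vars)) break
    d <- dat[, c(".y", vars), drop = FALSE]
    fit <- fit_glm(d)
    sm <- summary(fit)$coefficients
    rows <- setdiff(rownames(sm), "(Intercept)")
    pv <- stats::setNames(sm[rows, "Pr(>|z|)"], rows)
    if (!length(pv) || max(pv) < alpha) break
    vars <- setdiff(vars, names(which.max(pv)))
  }
  if (!length(vars))
    return(list(features = data.frame(feature = character(0), estimate = numeric(0),
                                      p = numeric(0), stringsAsFactors = FALSE),
                separation = sep))
  fit <- fit_glm(dat[, c(".y", vars), drop = FALSE])
  sm <- summary(fit)$coefficients
  rows <- setdiff(rownames(sm), "(Intercept)")
  list(features = data.frame(feature = rows, estimate = sm[rows, "Estimate"],
                             p = sm[rows, "Pr(>|z|)"], stringsAsFactors = FALSE,
                             row.names = NULL),
       separation = sep)
}

#' Standardized group deltas for final features
#'
#' Features are z-scored on the full cohort; the delta is the sarcopenic
#' minus non-sarcopenic standardized group mean, with a two-group
#' Kruskal-Wallis p-value.
#'
#' @param x Feature matrix (subjects x features).
#' @param labels Logical labels.
#' @param features Feature names to evaluate.
#' @param alpha Significance threshold for the `significant` flag.
#' @return Data frame `feature`, `delta`, `p`, `significant`.
#' @export
group_delta <- function(x, labels, features = colnames(x), alpha = 0.05) {
  x <- as.matrix(x)[, features, drop = FALSE]
  if (!ncol(x)) return(data.frame(feature = character(0), delta = numeric(0),
                                  p = numeric(0), significant = logical(0)))
  z <- scale(x)
  out <- do.call(rbind, lapply(seq_len(ncol(z)), function(j) {
    v <- z[, j]
    d <- mean(v[labels]) - mean(v[!labels])
    p <- if (stats::sd(v) == 0 || all(v[labels] == v[!labels][1])) 1 else
      stats::kruskal.test(v, factor(labels))$p.value
    data.frame(feature = colnames(z)[j], delta = d, p = p, stringsAsFactors = FALSE)
  }))
  out$significant <- out$p < alpha
  out
}

## Logistic odds ratios (per unit of each predictor) with Wald 95% CI.
logistic_odds_ratio <- function(predictors, labels) {
  d <- data.frame(.y = as.numeric(labels), predictors, check.names = FALSE)
  fit <- suppressWarnings(stats::glm(.y ~ ., data = d, family = stats::binomial()))
  sm <- summary(fit)$coefficients
  rows <- setdiff(rownames(sm), "(Intercept)")
  data.frame(term = rows,
             or = exp(sm[rows, "Estimate"]),
             ci_lower = exp(sm[rows, "Estimate"] - 1.96 * sm[rows, "Std. Error"]),
             ci_upper = exp(sm[rows, "Estimate"] + 1.96 * sm[rows, "Std. Error"]),
             p = sm[rows, "Pr(>|z|)"], stringsAsFactors = FALSE, row.names = NULL)
}

#' Variability vs structural cluster association with sarcopenia
#'
#' Per-subject cluster scores are the means of the standardized features in
#' each category; a logistic model of sarcopenia on both scores yields odds
#' ratios per 1-SD score with Wald 95% CIs.
#'
#' @param x Feature matrix (subjects x features), raw or standardized.
#' @param labels Logical labels.
#' @param categories Named character vector mapping feature names to
#'   `"variability"` or `"structural"`; defaults to [feature_category()] of
#'   the column names.
#' @return Data frame from [logistic_odds_ratio()], terms
#'   `variability_score` and `structural_score`.
#' @export
cluster_association <- function(x, labels, categories = NULL) {
  x <- as.matrix(x)
  if (is.null(categories)) categories <- stats::setNames(feature_category(colnames(x)), colnames(x))
  v_cols <- colnames(x)[categories[colnames(x)] == "variability"]
  s_cols <- colnames(x)[categories[colnames(x)] == "structural"]
  assert_that(length(v_cols) > 0 && length(s_cols) > 0,
              "both variability and structural features are required")
  z <- scale(x)
  scores <- data.frame(
    variability_score = rowMeans(z[, v_cols, drop = FALSE]),
    structural_score = rowMeans(z[, s_cols, drop = FALSE]))
  sds <- vapply(scores, stats::sd, 0)
  if (any(sds == 0))
    stop_respiromics("degenerate (zero-variance) cluster score", "respiromics_input_error")
  scores[] <- lapply(scores, function(v) v / stats::sd(v)) # ORs per 1 SD
  logistic_odds_ratio(scores, labels)
}

#' Full biomarker selection pipeline for one muscle
#'
#' clean -> LASSO -> backward refinement -> group deltas -> cluster ORs.
#' An empty final feature list is an accepted outcome (reported, not an
#' error); cluster ORs are computed on the cleaned matrix whenever both
#' categories survive cleaning.
#'
#' @param x Raw feature matrix (subjects x features).
#' @param labels Logical sarcopenia labels.
#' @param corr_threshold,folds,seed,alpha Stage parameters.
#' @return A `selection_result` list: `cleaned`, `lasso_selected`, `final`
#'   (with p-values), `deltas`, `cluster_or`, `separation`.
#' @export
select_biomarkers <- function(x, labels, corr_threshold = 0.9, folds = 10,
                              seed = 1L, alpha = 0.05) {
  cl <- clean_features(x, corr_threshold = corr_threshold)
  lasso <- lasso_select(cl, labels, folds = folds, seed = seed)
  step <- if (length(lasso) && nrow(cl) > length(lasso) + 2)
    stepwise_refine(cl[, lasso, drop = FALSE], labels, alpha = alpha)
  else if (length(lasso)) {
    ## more candidates than the sample can support: rank by univariate p
    ## and keep the strongest affordable subset before refinement
    ps <- vapply(lasso, function(f)
      stats::kruskal.test(cl[, f], factor(labels))$p.value, 0)
    keep <- names(sort(ps))[seq_len(max(1, nrow(cl) - 3))]
    stepwise_refine(cl[, keep, drop = FALSE], labels, alpha = alpha)
  } else list(features = data.frame(feature = character(0), estimate = numeric(0),
                                    p = numeric(0)), separation = FALSE)
  final <- step$features$feature
  deltas <- group_delta(cl, labels, final, alpha = alpha)
  ## cluster model on the final features (as selected biomarkers); falls back
  ## to the cleaned matrix when selection retains nothing or one category
  cluster_mat <- if (length(final) >= 2 &&
                     length(unique(feature_category(final))) == 2)
    cl[, final, drop = FALSE] else cl
  cluster_or <- tryCatch(cluster_association(cluster_mat, labels), error = function(e) NULL)
  structure(list(cleaned = colnames(cl), lasso_selected = as.character(lasso),
                 final = step$features, deltas = deltas, cluster_or = cluster_or,
                 separation = isTRUE(step$separation)),
            class = "selection_result")
}
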