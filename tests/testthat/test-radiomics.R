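test_that("fixed-bin-width discretization follows the floor rule", {
  expect_identical(discretize(c(0, 24.9, 25, 60), discretization_settings(25)),
                   c(1L, 1L, 2L, 3L))
  expect_identical(discretize(rep(7.3, 5)), rep(1L, 5))
  expect_error(discretization_settings(0))
  expect_error(discretization_settings(-3))
  expect_error(discretize(numeric(0)))
})

test_that("first-order features match direct arithmetic", {
  f <- firstorder_features(c(10, 20, 30))
  expect_equal(unname(f["firstorder_mean"]), 20)
  expect_equal(unname(f["firstorder_median"]), 20)
  expect_equal(unname(f["firstorder_maximum"]), 30)
  expect_equal(unname(f["firstorder_rms"]), sqrt(1400 / 3))
  expect_equal(unname(firstorder_features(c(-1, 0, 1))["firstorder_skewness"]), 0)
  fc <- firstorder_features(rep(-5, 10))
  expect_equal(unname(fc["firstorder_variance"]), 0)
  expect_equal(unname(fc["firstorder_rms"]), 5)
  ## robust MAD restricts to [P10, P90] before averaging deviations
  x <- c(0, rep(10, 8), 100)
  p <- stats::quantile(x, c(0.1, 0.9))
  inr <- x[x >= p[1] & x <= p[2]]
  expect_equal(unname(firstorder_features(x)["firstorder_rmad"]),
               mean(abs(inr - mean(inr))))
})

test_that("first-order statistics are permutation invariant and shift equivariant", {
  set.seed(12)
  x <- stats::rnorm(200, 30, 15)
  f1 <- firstorder_features(x)
  f2 <- firstorder_features(sample(x))
  expect_equal(f1, f2)
  f3 <- firstorder_features(x + 100)
  expect_equal(unname(f3["firstorder_mean"] - f1["firstorder_mean"]), 100)
  expect_equal(unname(f3["firstorder_median"] - f1["firstorder_median"]), 100)
  expect_equal(unname(f3["firstorder_variance"]), unname(f1["firstorder_variance"]))
})

test_that("degenerate constant regions give the conventional texture values", {
  tm <- texture_matrices(matrix(1L, 2, 2), n_levels = 1)
  tx <- texture_features(tm)
  expect_equal(unname(tx["glcm_maximum_probability"]), 1)
  expect_equal(unname(tx["glcm_cluster_shade"]), 0)
  expect_equal(unname(tx["ngtdm_contrast"]), 0)
  ## undefined denominators are NA sentinels, flagged, never silent zeros
  expect_true(is.na(tx["glcm_correlation"]))
  expect_true(all(c("glcm_correlation", "glcm_mcc") %in% attr(tx, "flagged")))
})

test_that("run matrices enumerate runs by gray level and length", {
  g <- matrix(c(1L, 2L, 1L, 2L), 2, 2) # rows: (1 1) and (2 2)
  m <- respiromics:::glrlm_direction(g, 2, c(0, 1))
  expect_equal(m, rbind(c(0, 1), c(0, 1))) # one run of length 2 per level
  mv <- respiromics:::glrlm_direction(g, 2, c(1, 0))
  expect_equal(mv, matrix(c(2, 2), 2, 1)) # vertically: four runs of length 1
})

test_that("checkerboard co-occurrences match exhaustive pair enumeration", {
  cb <- matrix(rep(c(1L, 2L), 8), 4, 4)
  cb[, c(2, 4)] <- 3L - cb[, c(2, 4)]
  ## horizontal + vertical: every adjacent pair discordant
  for (off in list(c(1, 0), c(0, 1))) {
    m <- respiromics:::glcm_direction(cb, 2, off)
    expect_equal(m[1, 1] + m[2, 2], 0)
    expect_equal(sum(m), 2 * 12) # 12 adjacent pairs, symmetric counting
  }
})

test_that("small random instances agree with the brute-force enumerators", {
  set.seed(77)
  for (i in 1:6) {
    g <- random_gray_instance(2, max_side = 5)
    L <- max(g, na.rm = TRUE)
    tm <- texture_matrices(g, n_levels = L)
    offs <- bf_offsets(2)
    for (k in seq_len(nrow(offs)))
      expect_equal(trim_cols(tm$glcm[[k]]), trim_cols(bf_glcm(g, L, offs[k, ])))
    expect_equal(trim_cols(tm$glszm), trim_cols(bf_glszm(g, L)))
    expect_equal(trim_cols(tm$gldm), trim_cols(bf_gldm(g, L)))
  }
})

test_that("shape features recover exact values on axis-aligned solids", {
  s <- shape_features(array(TRUE, dim = c(2, 3, 4)))
  expect_equal(unname(s["shape_volume"]), 24)
  expect_equal(unname(s["shape_max_3d_diameter"]), sqrt(1^2 + 2^2 + 3^2))
  sp <- shape_features(array(TRUE, dim = c(2, 3, 4)), spacing = c(0.5, 1, 2))
  expect_equal(unname(sp["shape_volume"]), 24 * 1)
  ## single voxel: defined volume, flagged elongation
  s1 <- shape_features(array(TRUE, dim = c(1, 1, 1)))
  expect_equal(unname(s1["shape_volume"]), 1)
  expect_true(is.na(s1["shape_elongation"]))
  expect_true("shape_elongation" %in% attr(s1, "flagged"))
})

test_that("digitized balls approach unit sphericity", {
  r <- 15; n <- 2 * r + 3; ctr <- (n + 1) / 2
  co <- as.matrix(expand.grid(1:n, 1:n, 1:n))
  ball <- array(rowSums((co - ctr)^2) <= r^2, dim = c(n, n, n))
  s <- shape_features(ball)
  expect_gte(unname(s["shape_sphericity"]), 0.9)
  expect_equal(unname(s["shape_elongation"]), 1, tolerance = 0.02)
})

test_that("whole-volume extraction is self-consistent and schema-complete", {
  set.seed(21)
  g <- generate_muscle_volume(NULL, small_spec(fat_fraction = 0.15))
  st <- filter_slices(build_stack(g$volume, g$mask))
  fv <- extract_features(g$volume, g$mask, "whole_3d", stack = st)
  pooled <- unlist(slice_values(st), use.names = FALSE)
  expect_equal(unname(fv["firstorder_mean"]), mean(pooled), tolerance = 1e-9)
  expect_equal(unname(fv["density_mean"]), mean(pooled), tolerance = 1e-9)
  required <- c(
    "glcm_inverse_variance", "glcm_mcc", "glcm_maximum_probability", "glcm_imc2",
    "glcm_cluster_shade", "glcm_cluster_prominence", "glcm_correlation",
    "glcm_difference_variance", "gldm_dependence_variance", "gldm_dependence_entropy",
    "glrlm_run_entropy", "glrlm_gray_level_non_uniformity", "glrlm_run_non_uniformity",
    "glrlm_long_run_low_gray_level_emphasis", "glrlm_gray_level_non_uniformity_normalized",
    "glszm_gray_level_non_uniformity", "glszm_gray_level_variance", "glszm_zone_variance",
    "glszm_zone_non_uniformity", "glszm_zone_entropy", "glszm_zone_percentage",
    "ngtdm_busyness", "ngtdm_coarseness", "ngtdm_complexity", "ngtdm_strength",
    "ngtdm_contrast", "firstorder_maximum", "firstorder_median", "firstorder_minimum",
    "firstorder_rms", "firstorder_skewness", "firstorder_kurtosis",
    "firstorder_total_energy", "firstorder_10percentile", "firstorder_rmad",
    "shape_volume", "shape_elongation", "shape_sphericity")
  expect_true(all(required %in% names(fv)))
  expect_gte(length(fv), 100)
  expect_true(all(is.finite(fv[setdiff(names(fv), attr(fv, "flagged"))])))
})

test_that("per-slice averaging of identical slices equals the single-slice vector", {
  slice <- matrix(c(10, 20, 35, 50, 80, 10, 20, 35), 4, 2)
  vox <- array(rep(slice, 5), dim = c(4, 2, 5))
  msk <- array(TRUE, dim = c(4, 2, 5))
  vol <- ct_volume(vox)
  mk <- muscle_mask(msk, plane = "axial")
  st <- filter_slices(build_stack(vol, mk))
  avg <- extract_features(vol, mk, "per_slice_2d", stack = st)
  one <- extract_features(vol, mk, "per_slice_2d", stack = st, slices = 2L)
  ## pooled density_sd legitimately differs (sample-SD n differs with pooling)
  common <- setdiff(names(avg), c(attr(avg, "flagged"), "density_sd"))
  expect_equal(avg[common], one[common], tolerance = 1e-12)
})

test_that("texture features are invariant to a constant HU shift", {
  set.seed(33)
  g <- generate_muscle_volume(NULL, small_spec(fat_fraction = 0.15))
  st <- filter_slices(build_stack(g$volume, g$mask))
  fv1 <- extract_features(g$volume, g$mask, "whole_3d", stack = st)
  v2 <- g$volume; v2$voxels <- v2$voxels + 57
  st2 <- filter_slices(build_stack(v2, g$mask))
  fv2 <- extract_features(v2, g$mask, "whole_3d", stack = st2)
  tex <- names(fv1)[feature_class(names(fv1)) %in% c("glcm", "glrlm", "glszm", "gldm", "ngtdm")]
  tex <- setdiff(tex, attr(fv1, "flagged"))
  expect_equal(fv1[tex], fv2[tex], tolerance = 1e-9)
  expect_equal(unname(fv2["firstorder_mean"] - fv1["firstorder_mean"]), 57, tolerance = 1e-9)
})

test_that("feature classes partition into the variability/structural categories", {
  expect_identical(feature_category(c("glcm_contrast", "glrlm_run_entropy",
                                      "glszm_zone_entropy", "gldm_dependence_variance",
                                      "ngtdm_busyness")),
                   rep("variability", 5))
  expect_identical(feature_category(c("firstorder_mean", "shape_volume", "density_mean")),
                   rep("structural", 3))
})
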