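test_that("identical seeds give byte-identical bundles", {
  cfg <- cohort_config(n_subjects = 3, sarcopenic_fraction = 1 / 3, seed = 11L)
  b1 <- generate_cohort(cfg)
  b2 <- generate_cohort(cfg)
  expect_identical(b1$subjects, b2$subjects)
  expect_identical(b1$data[["S001"]]$PM$volume$voxels, b2$data[["S001"]]$PM$volume$voxels)
  expect_identical(b1$data[["S003"]]$`4I`$mask$voxels, b2$data[["S003"]]$`4I`$mask$voxels)
})

test_that("noise-free degenerate spec yields constant muscle voxels", {
  sp <- small_spec(fat_fraction = 0, sigma_within = 0, axial_gradient = 0)
  sp$mu_muscle <- 42
  set.seed(1)
  g <- generate_muscle_volume(NULL, sp)
  vals <- g$volume$voxels[g$mask$voxels]
  expect_true(all(abs(vals - 42) < 1e-9))
  expect_equal(mean(vals), 42)
})

test_that("masks are non-empty on every slice and landmark is central", {
  set.seed(2)
  b <- generate_cohort(cohort_config(n_subjects = 2, sarcopenic_fraction = 0.5, seed = 5L))
  for (id in names(b$data)) for (lab in names(b$data[[id]])) {
    entry <- b$data[[id]][[lab]]
    axis <- entry$volume$axis_roles[[entry$mask$plane]]
    per_slice <- apply(entry$mask$voxels, axis, sum)
    expect_true(all(per_slice > 0))
    st <- filter_slices(build_stack(entry$volume, entry$mask))
    ret <- st$index[st$retained]
    qlo <- stats::quantile(ret, 0.25); qhi <- stats::quantile(ret, 0.75)
    expect_gte(entry$landmark_true, qlo)
    expect_lte(entry$landmark_true, qhi)
  }
})

test_that("increasing fat fraction strictly decreases the expected mean", {
  means <- vapply(c(0.05, 0.15, 0.30), function(f) {
    sp <- small_spec(fat_fraction = f)
    sp$mu_muscle <- 45
    set.seed(99) # matched seeds
    g <- generate_muscle_volume(NULL, sp)
    mean(g$volume$voxels[g$mask$voxels])
  }, 0)
  expect_true(all(diff(means) < 0))
})

test_that("slice counts below the protocol span are refused with the muscle named", {
  err <- expect_error(muscle_spec("Pm", n_slices = 42), class = "respiromics_config_error")
  expect_match(conditionMessage(err), "Pm")
  expect_match(conditionMessage(err), "42")
})

test_that("non-finite spec values are refused", {
  expect_error(muscle_spec("PM", n_slices = 60, mu_muscle = NaN), "non-finite")
})

test_that("sarcopenic spec yields lower whole-muscle density than non-sarcopenic", {
  sp_s <- default_muscle_specs("sarcopenic")$PM
  sp_n <- default_muscle_specs("non_sarcopenic")$PM
  set.seed(31)
  m_s <- replicate(30, {
    g <- generate_muscle_volume(NULL, sp_s)
    st <- filter_slices(build_stack(g$volume, g$mask))
    mean(unlist(slice_values(st), use.names = FALSE))
  })
  m_n <- replicate(30, {
    g <- generate_muscle_volume(NULL, sp_n)
    st <- filter_slices(build_stack(g$volume, g$mask))
    mean(unlist(slice_values(st), use.names = FALSE))
  })
  expect_lt(stats::t.test(m_s, m_n, alternative = "less")$p.value, 0.01)
})

test_that("peripheral fat enrichment raises Jensen-Shannon distance at the muscle ends", {
  sp <- small_spec(n_slices = 80, fat_fraction = 0.12, edge_fat_boost = 2)
  sp$mu_muscle <- 45
  set.seed(7)
  g <- generate_muscle_volume(NULL, sp)
  st <- filter_slices(build_stack(g$volume, g$mask))
  pr <- js_profile(st)
  n <- nrow(pr)
  outer_idx <- c(seq_len(ceiling(0.15 * n)), seq(n - ceiling(0.15 * n) + 1, n))
  central_idx <- seq(floor(n / 4) + 1, n - floor(n / 4))
  expect_gt(mean(pr$js_distance[outer_idx]), mean(pr$js_distance[central_idx]))
})

test_that("homogeneous muscles show no central-vs-peripheral JS difference", {
  ## untapered cylinder with every heterogeneity mechanism off
  sp <- small_spec(n_slices = 80, fat_fraction = 0.12, edge_fat_boost = 0,
                   taper_min = 1, belly_sigma_boost = 0)
  sp$mu_muscle <- 45
  set.seed(8)
  g <- generate_muscle_volume(NULL, sp)
  st <- filter_slices(build_stack(g$volume, g$mask))
  pr <- js_profile(st)
  n <- nrow(pr)
  outer_idx <- c(seq_len(ceiling(0.15 * n)), seq(n - ceiling(0.15 * n) + 1, n))
  central_idx <- seq(floor(n / 4) + 1, n - floor(n / 4))
  obs <- mean(pr$js_distance[outer_idx]) - mean(pr$js_distance[central_idx])
  set.seed(9)
  null <- replicate(199, {
    sh <- sample(pr$js_distance)
    mean(sh[outer_idx]) - mean(sh[central_idx])
  })
  p <- mean(c(abs(null), abs(obs)) >= abs(obs))
  expect_gt(p, 0.05)
})

test_that("bundles round-trip through NIfTI and the manifest records the seed", {
  b <- generate_cohort(cohort_config(n_subjects = 2, sarcopenic_fraction = 0.5, seed = 21L,
                                     specs = list(
                                       sarcopenic = list(PM = small_spec()),
                                       non_sarcopenic = list(PM = small_spec()))))
  dir <- file.path(tempdir(), "bundle_rt")
  unlink(dir, recursive = TRUE)
  manifest <- write_bundle(b, dir)
  expect_true(file.exists(manifest))
  man <- jsonlite::read_json(manifest)
  expect_identical(man$seed, 21L)
  rt <- read_bundle(dir)
  expect_equal(rt$data[["S001"]]$PM$volume$voxels, b$data[["S001"]]$PM$volume$voxels,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_identical(dim(rt$data[["S002"]]$PM$mask$voxels), dim(b$data[["S002"]]$PM$mask$voxels))
  expect_error(write_bundle(b, dir), class = "respiromics_io_error")
  expect_silent(write_bundle(b, dir, overwrite = TRUE))
})

test_that("an empty cohort refuses to write", {
  b <- generate_cohort(cohort_config(n_subjects = 0, seed = 1L))
  expect_error(write_bundle(b, file.path(tempdir(), "empty_bundle")),
               class = "respiromics_config_error")
})

test_that("default cohorts reproduce the group density anchors across seeds", {
  ## per-muscle, per-group means within 2 SE of the anchors in >= 90% of seeds
  anchors <- respiromics:::.density_anchors
  n_seeds <- 50
  hits <- array(0, dim = c(4, 2), dimnames = list(names(anchors), c("sarcopenic", "non_sarcopenic")))
  for (s in seq_len(n_seeds)) {
    b <- generate_cohort(cohort_config(seed = 1000L + s))
    sarc <- b$subjects$sarcopenic
    for (lab in names(anchors)) {
      dens <- vapply(names(b$data), function(id) {
        st <- filter_slices(build_stack(b$data[[id]][[lab]]$volume, b$data[[id]][[lab]]$mask))
        mean(unlist(slice_values(st), use.names = FALSE))
      }, 0)
      for (grp in c("sarcopenic", "non_sarcopenic")) {
        sel <- if (grp == "sarcopenic") sarc else !sarc
        se <- anchors[[lab]]$sd[[grp]] / sqrt(sum(sel))
        if (abs(mean(dens[sel]) - anchors[[lab]]$mean[[grp]]) <= 2 * se)
          hits[lab, grp] <- hits[lab, grp] + 1
      }
    }
  }
  ## a 2 SE criterion has ~95% coverage per cell, so the aggregate rate over
  ## all muscle x group cells is the stable check; each cell also gets a
  ## coarser guard against a single broken calibration
  expect_gte(sum(hits) / (length(hits) * n_seeds), 0.9)
  expect_true(all(hits / n_seeds >= 0.8),
              info = paste(capture.output(print(hits / n_seeds)), collapse = "\n"))
})
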