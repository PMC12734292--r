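## Synthetic cohort generator: CT-like respiratory-muscle volumes with aligned
## binary masks, calibrated so that whole-muscle group densities, age trends,
## peripheral-slice heterogeneity, and sarcopenic texture contrasts emulate the
## study cohort the downstream protocol assumes.

MUSCLE_LABELS <- c("PM", "Pm", "SA", "4I")

## Group-level density anchors (HU): whole-muscle mean by sarcopenia status,
## between-subject SD, and an age slope (HU per year) shared across groups.
.density_anchors <- list(
  PM = list(mean = c(sarcopenic = 15.2, non_sarcopenic = 36.9),
            sd   = c(sarcopenic = 18.8, non_sarcopenic = 14.1), beta_age = -0.70),
  Pm = list(mean = c(sarcopenic = 23.3, non_sarcopenic = 32.8),
            sd   = c(sarcopenic = 13.6, non_sarcopenic = 15.9), beta_age = -0.48),
  SA = list(mean = c(sarcopenic = 3.1, non_sarcopenic = 23.9),
            sd   = c(sarcopenic = 21.6, non_sarcopenic = 16.6), beta_age = -0.59),
  `4I` = list(mean = c(sarcopenic = -38.8, non_sarcopenic = -18.4),
              sd   = c(sarcopenic = 23.0, non_sarcopenic = 25.3), beta_age = -0.99)
)

.age_anchors <- list(sarcopenic = c(mean = 70.4, sd = 12.5),
                     non_sarcopenic = c(mean = 56.1, sd = 20.0))
.bmi_anchors <- list(sarcopenic = c(mean = 22.0, sd = 2.9),
                     non_sarcopenic = c(mean = 24.9, sd = 3.2))
.female_prob <- c(sarcopenic = 11 / 17, non_sarcopenic = 5 / 13)

FAT_MEAN <- -100 # HU, fixed adipose component
FAT_SD <- 20
EDGE_FRAC <- 0.15   # fraction of slices at each end forming the peripheral ramp
TAPER_MIN <- 0.42   # in-plane radius scale at the muscle ends
CENTRAL_Q <- 0.70   # |q| at which the mean-neutral heterogeneity gradient saturates

#' Muscle generation specification
#'
#' Describes one muscle's synthetic geometry and HU mixture model. Voxels are a
#' two-component mixture: a muscle component `N(mu_muscle, sigma_within)` and a
#' fat component `N(-100, 20)`. The per-voxel fat probability is
#' `fat_fraction * (1 + edge_fat_boost * edge_weight(slice))` plus a
#' mean-compensated central gradient (`central_fat_boost`) that raises
#' distributional heterogeneity away from the landmark without shifting slice
#' mean density. Mask cross-sections are end-tapered ellipses.
#'
#' @param label One of `"PM"`, `"Pm"`, `"SA"`, `"4I"`.
#' @param plane Segmentation plane, `"axial"` (PM, Pm) or `"coronal"` (SA, 4I).
#' @param n_slices Number of mask slices along the plane axis (>= 43 so a
#'   7-slice, stride-6 set with +/-2 landmark offsets always fits).
#' @param mu_muscle Muscle-component mean attenuation (HU).
#' @param sigma_within Muscle-component SD (HU).
#' @param fat_fraction Baseline per-voxel fat probability in `[0, 1]`.
#' @param edge_fat_boost Multiplicative fat enrichment ramping up over the
#'   first/last 15% of slices (peripheral partial-volume surrogate).
#' @param central_fat_boost Mean-compensated fat enrichment growing
#'   quadratically with distance from the landmark (optional extra
#'   heterogeneity that does not bias slice means; default 0).
#' @param axial_gradient Signed linear axial density gradient (HU): slice
#'   mean density shifts by `axial_gradient * q` where `q in [-1, 1]` is the
#'   signed distance from the landmark. Symmetric about the landmark, so the
#'   whole-muscle mean is essentially unchanged while the slice-to-pooled
#'   Jensen-Shannon distance acquires its minimum at the landmark.
#' @param belly_sigma_boost Local broadening of the muscle-component SD at
#'   the landmark (Gaussian profile of width 0.15 in `q`): the landmark
#'   slice's density mixture then best resembles the pooled whole-muscle
#'   distribution, which is the premise of landmark-anchored sampling.
#' @param texture_corr_len In-plane correlation length (voxels) of the
#'   muscle noise field; shorter lengths give busier texture. 0 = white.
#' @param fat_mode `"binary"` (independent per-voxel fat voxels, the fine
#'   marbling of large muscles) or `"continuous"` (per-voxel partial-volume
#'   fat fractions, for thin fat-infiltrated muscles such as 4I).
#' @param fat_jitter Half-range of the per-voxel fat fraction in continuous
#'   mode.
#' @param landmark_true Ground-truth landmark slice (0-based along plane axis).
#' @param semi_axes In-plane ellipse semi-axes (voxels) at the widest slice.
#' @param taper_min In-plane radius scale at the muscle ends (sine taper
#'   toward 1 at the belly); 1 gives an untapered cylinder.
#' @param spacing Voxel spacing in mm (x, y, z).
#' @return An object of class `muscle_spec`.
#' @export
muscle_spec <- function(label, plane = if (label %in% c("PM", "Pm")) "axial" else "coronal",
                        n_slices, mu_muscle = 45, sigma_within = 12,
                        fat_fraction = 0.1, edge_fat_boost = 2,
                        central_fat_boost = 0, axial_gradient = 40,
                        belly_sigma_boost = 1.0, texture_corr_len = 2,
                        landmark_true = floor(n_slices / 2),
                        semi_axes = c(18, 11), taper_min = 0.42,
                        spacing = c(0.7, 0.7, 2),
                        fat_mode = c("binary", "continuous"), fat_jitter = 0.15) {
  fat_mode <- match.arg(fat_mode)
  assert_that(label %in% MUSCLE_LABELS, sprintf("unknown muscle label '%s'", label))
  assert_that(plane %in% c("axial", "coronal"), "plane must be 'axial' or 'coronal'")
  if (label %in% c("PM", "Pm")) assert_that(plane == "axial", sprintf("%s must use the axial plane", label))
  if (label %in% c("SA", "4I")) assert_that(plane == "coronal", sprintf("%s must use the coronal plane", label))
  vals <- c(n_slices, mu_muscle, sigma_within, fat_fraction, edge_fat_boost,
            central_fat_boost, axial_gradient, belly_sigma_boost,
            texture_corr_len, landmark_true, semi_axes, taper_min, spacing,
            fat_jitter)
  assert_that(all(is.finite(vals)), sprintf("non-finite value in spec for muscle %s", label))
  if (n_slices < 43)
    stop_respiromics(sprintf("muscle %s: n_slices = %d < 43 cannot accommodate a 7-slice stride-6 set with +/-2 offsets",
                             label, n_slices), "respiromics_config_error")
  assert_that(fat_fraction >= 0 && fat_fraction <= 1, "fat_fraction must be in [0, 1]")
  assert_that(sigma_within >= 0 && edge_fat_boost >= 0 && central_fat_boost >= 0,
              "dispersion and boost parameters must be non-negative")
  assert_that(landmark_true >= 0 && landmark_true < n_slices, "landmark_true out of slice range")
  structure(list(label = label, plane = plane, n_slices = as.integer(n_slices),
                 mu_muscle = mu_muscle, sigma_within = sigma_within,
                 fat_fraction = fat_fraction, edge_fat_boost = edge_fat_boost,
                 central_fat_boost = central_fat_boost,
                 axial_gradient = axial_gradient,
                 belly_sigma_boost = belly_sigma_boost,
                 texture_corr_len = texture_corr_len,
                 landmark_true = as.integer(landmark_true),
                 semi_axes = semi_axes, taper_min = taper_min, spacing = spacing,
                 fat_mode = fat_mode, fat_jitter = fat_jitter),
            class = "muscle_spec")
}

## Deterministic slice geometry implied by a spec: taper scale, exact
## rasterized pixel count per slice, edge weight, central heterogeneity
## gradient, and which slices survive the 20%-of-max pixel rule. Pixel
## counts are computed from the same ellipse rasterization the generator
## uses, so the calibration sees the mask it will actually get.
slice_geometry <- function(spec) {
  n <- spec$n_slices
  t <- (seq_len(n) - 0.5) / n
  tm <- spec$taper_min %||% TAPER_MIN
  s <- tm + (1 - tm) * sin(pi * t)
  a0 <- spec$semi_axes[1]; b0 <- spec$semi_axes[2]
  nx <- 2L * ceiling(a0) + 5L
  ny <- 2L * ceiling(b0) + 5L
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  r2 <- outer((seq_len(nx) - cx) / a0, (seq_len(ny) - cy) / b0,
              function(x, y) x^2 + y^2)
  w <- vapply(s, function(si) sum(r2 <= si^2), 0)
  d_end <- pmin(t, 1 - t)
  edge_w <- pmax(0, 1 - d_end / EDGE_FRAC)
  q <- ((seq_len(n) - 1) - spec$landmark_true) / (n / 2)
  grad <- pmin(1, (abs(q) / CENTRAL_Q)^2)
  retained <- w >= 0.2 * max(w)
  list(scale = s, weight = w, edge_w = edge_w, grad = grad, q = q,
       retained = retained, grid_r2 = r2, nx = nx, ny = ny)
}

## Solve for the central slice-mean target T such that the expected
## area-weighted whole-muscle mean over retained slices equals `target_mean`,
## then return the baseline muscle-component mean. The central heterogeneity
## gradient is mean-compensated by construction; only the (uncompensated)
## peripheral fat ramp biases the whole-muscle mean below T.
calibrate_mu <- function(spec, target_mean) {
  g <- slice_geometry(spec)
  f <- spec$fat_fraction
  w <- g$weight[g$retained]
  e <- (f * spec$edge_fat_boost * g$edge_w)[g$retained]
  a <- pmin(0.9 - f, f * spec$central_fat_boost * g$grad)[g$retained]
  q <- g$q[g$retained]
  gam <- spec$axial_gradient
  T <- target_mean
  for (it in 1:6) {
    mu_i <- (T + gam * q + 100 * (f + a)) / (1 - (f + a))
    m_i <- T + gam * q - e * (mu_i - FAT_MEAN)
    ## emulate the +/-3 z-score slice exclusion on the expected slice means,
    ## so the calibration targets the post-filter whole-muscle mean
    keep <- rep(TRUE, length(m_i))
    repeat {
      mm <- m_i[keep]
      if (length(mm) < 3 || stats::sd(mm) == 0) break
      z <- (m_i - mean(mm)) / stats::sd(mm)
      drop <- keep & abs(z) > 3
      if (!any(drop)) break
      keep <- keep & !drop
    }
    offset <- sum((w * (gam * q - e * (mu_i - FAT_MEAN)))[keep]) / sum(w[keep])
    T <- target_mean - offset
  }
  (T + 100 * f) / (1 - f)
}

## Default per-group specs, calibrated so that group-level whole-muscle means
## reproduce the density anchors for a subject at the group mean age.
#' Default muscle specifications per sarcopenia group
#'
#' @param group `"sarcopenic"` or `"non_sarcopenic"`.
#' @return Named list of [muscle_spec()] objects (PM, Pm, SA, 4I).
#' @export
default_muscle_specs <- function(group = c("non_sarcopenic", "sarcopenic")) {
  group <- match.arg(group)
  sarc <- group == "sarcopenic"
  geom <- list(
    PM = list(n_slices = 94, semi_axes = c(18, 11)),
    Pm = list(n_slices = 61, semi_axes = c(12, 8)),
    SA = list(n_slices = 126, semi_axes = c(16, 9)),
    `4I` = list(n_slices = 170, semi_axes = c(3.4, 2.3))
  )
  fat <- if (sarc) c(PM = 0.16, Pm = 0.13, SA = 0.18, `4I` = 0.50) else
                   c(PM = 0.08, Pm = 0.07, SA = 0.10, `4I` = 0.38)
  edge_boost <- c(PM = 2, Pm = 2, SA = 2, `4I` = 0.6)
  ## sarcopenic muscle shows coarser fatty marbling (larger texture patches)
  corr_len <- if (sarc) 2 else 1
  out <- lapply(MUSCLE_LABELS, function(lab) {
    sp <- muscle_spec(lab,
                      n_slices = geom[[lab]]$n_slices,
                      fat_fraction = unname(fat[lab]),
                      edge_fat_boost = unname(edge_boost[lab]),
                      texture_corr_len = if (lab == "4I") 0 else corr_len,
                      semi_axes = geom[[lab]]$semi_axes,
                      fat_mode = if (lab == "4I") "continuous" else "binary")
    sp$mu_muscle <- calibrate_mu(sp, .density_anchors[[lab]]$mean[[group]])
    sp
  })
  names(out) <- MUSCLE_LABELS
  out
}

#' Cohort generation configuration
#'
#' @param n_subjects Number of subjects.
#' @param sarcopenic_fraction Fraction labelled sarcopenic.
#' @param seed Integer seed; the whole bundle is deterministic given it.
#' @param specs Optional list with elements `sarcopenic` and `non_sarcopenic`,
#'   each a named list of [muscle_spec()]s; defaults to [default_muscle_specs()].
#' @param subject_sd If `TRUE` (default) add between-subject density variation
#'   (age slope plus residual) matching the group-level SD anchors; if `FALSE`
#'   every subject uses the group spec verbatim (homogeneous cohort).
#' @param fat_subject_sd Between-subject SD of the fat fraction (absolute;
#'   default 0.04). Subject-level fat infiltration is the latent axis that
#'   makes texture features vary continuously across subjects; the
#'   muscle-component mean is re-calibrated per subject so the density target
#'   is unaffected.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 30, sarcopenic_fraction = 17 / 30,
                          seed = 1L, specs = NULL, subject_sd = TRUE,
                          fat_subject_sd = 0.04) {
  assert_that(is_count(n_subjects) && n_subjects >= 0, "n_subjects must be a non-negative integer")
  assert_that(sarcopenic_fraction >= 0 && sarcopenic_fraction <= 1,
              "sarcopenic_fraction must be in [0, 1]")
  if (is.null(specs))
    specs <- list(sarcopenic = default_muscle_specs("sarcopenic"),
                  non_sarcopenic = default_muscle_specs("non_sarcopenic"))
  for (grp in names(specs)) for (sp in specs[[grp]])
    if (!inherits(sp, "muscle_spec")) stop_respiromics("specs must contain muscle_spec objects", "respiromics_config_error")
  structure(list(n_subjects = as.integer(n_subjects),
                 sarcopenic_fraction = sarcopenic_fraction,
                 seed = as.integer(seed), specs = specs,
                 subject_sd = isTRUE(subject_sd),
                 fat_subject_sd = fat_subject_sd),
            class = "cohort_config")
}

rnorm_trunc <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lower)
  }
  x
}

#' Generate one synthetic muscle volume
#'
#' Builds a CT-like HU volume and aligned binary mask for a single muscle.
#' Cross-sections are end-tapered ellipses; voxels mix a muscle and a fat
#' component with spatially clumped fat assignment and in-plane correlated
#' muscle noise. Peripheral slices (first/last 15%) get uncompensated fat
#' enrichment; slices away from the landmark get a mean-compensated fat
#' gradient so that heterogeneity, but not mean density, rises off-centre.
#'
#' @param subject A single-row subject data frame (used for provenance only).
#' @param spec A [muscle_spec()].
#' @return List with `volume` ([ct_volume()]), `mask` ([muscle_mask()]), and
#'   `landmark_true` (0-based slice index).
#' @export
generate_muscle_volume <- function(subject = NULL, spec) {
  assert_that(inherits(spec, "muscle_spec"), "spec must be a muscle_spec")
  n <- spec$n_slices
  g <- slice_geometry(spec)
  nx <- g$nx; ny <- g$ny

  f <- spec$fat_fraction
  T <- (1 - f) * spec$mu_muscle + f * FAT_MEAN
  a_slice <- pmin(0.9 - f, f * spec$central_fat_boost * g$grad)
  e_slice <- f * spec$edge_fat_boost * g$edge_w
  f_tot <- pmin(0.95, f + a_slice + e_slice)
  ## muscle-component mean compensated so the slice mean follows the axial
  ## gradient exactly, absent the (uncompensated) peripheral fat ramp
  mu_slice <- (T + spec$axial_gradient * g$q + 100 * (f + a_slice)) / (1 - (f + a_slice))

  mask <- array(rep(as.vector(g$grid_r2), n) <= rep(g$scale^2, each = nx * ny),
                dim = c(nx, ny, n))
  ## every generated slice must intersect the mask
  stopifnot(all(colSums(matrix(mask, nx * ny, n)) > 0))

  dims <- c(nx, ny, n)
  un <- correlated_noise(dims, spec$texture_corr_len) # muscle noise field
  p_arr <- array(rep(f_tot, each = nx * ny), dim = dims)
  ## per-voxel fat fraction phi with E[phi] = slice fat probability:
  ## independent fat voxels (binary marbling) or bounded partial-volume
  ## fractions (continuous mode for thin, fat-infiltrated muscles)
  phi <- if (spec$fat_mode == "binary") {
    (array(stats::runif(prod(dims)), dim = dims) < p_arr) * 1
  } else {
    j <- pmin(spec$fat_jitter, p_arr, 1 - p_arr)
    pmin(1, pmax(0, p_arr + j * array(stats::runif(prod(dims), -1, 1), dim = dims)))
  }
  mu_arr <- array(rep(mu_slice, each = nx * ny), dim = dims)
  ## muscle-lobe width broadens near the landmark (belly), where the slice
  ## distribution best resembles the pooled whole-muscle mixture
  sigma_slice <- spec$sigma_within * (1 + spec$belly_sigma_boost * exp(-(g$q / 0.15)^2))
  sig_arr <- array(rep(sigma_slice, each = nx * ny), dim = dims)
  muscle_hu <- mu_arr + sig_arr * un
  fat_hu <- array(stats::rnorm(prod(dims), FAT_MEAN, FAT_SD), dim = dims)
  vox <- (1 - phi) * muscle_hu + phi * fat_hu
  vox[!mask] <- -1024 # air/background outside the muscle

  perm <- switch(spec$plane, axial = c(1L, 2L, 3L), coronal = c(1L, 3L, 2L))
  vox <- aperm(vox, perm)
  mask <- aperm(mask, perm)
  sp <- spec$spacing[perm] # keep slice thickness on the stacking axis
  vol <- ct_volume(vox, spacing = sp)
  msk <- muscle_mask(mask, label = spec$label, plane = spec$plane)
  list(volume = vol, mask = msk, landmark_true = spec$landmark_true)
}

#' Generate a synthetic cohort
#'
#' Draws a subject table (age, sex, BMI, sarcopenia label) and, per subject,
#' four muscle volume/mask pairs plus a ground-truth landmark. Between-subject
#' density variation follows the group SD anchors via an age slope plus a
#' residual; each subject's muscle-component mean is re-calibrated so its
#' expected whole-muscle density hits the subject-level target.
#'
#' @param config A [cohort_config()].
#' @return A `cohort_bundle`: list with `subjects` (data frame), `data`
#'   (per-subject, per-muscle list of volume/mask/landmark), and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  assert_that(inherits(config, "cohort_config"), "config must be a cohort_config")
  set.seed(config$seed)
  n <- config$n_subjects
  n_sarc <- round(n * config$sarcopenic_fraction)
  sarc <- rep(c(TRUE, FALSE), c(n_sarc, n - n_sarc))
  grp <- ifelse(sarc, "sarcopenic", "non_sarcopenic")
  age <- numeric(n); bmi <- numeric(n); sex <- character(n)
  for (g in c("sarcopenic", "non_sarcopenic")) {
    idx <- which(grp == g)
    if (!length(idx)) next
    age[idx] <- rnorm_trunc(length(idx), .age_anchors[[g]]["mean"], .age_anchors[[g]]["sd"], 18)
    bmi[idx] <- rnorm_trunc(length(idx), .bmi_anchors[[g]]["mean"], .bmi_anchors[[g]]["sd"], 12)
    sex[idx] <- ifelse(stats::runif(length(idx)) < .female_prob[[g]], "F", "M")
  }
  subjects <- data.frame(id = sprintf("S%03d", seq_len(n)), age = round(age, 1),
                         sex = sex, bmi = round(bmi, 1), sarcopenic = sarc,
                         stringsAsFactors = FALSE)

  data <- vector("list", n)
  names(data) <- subjects$id
  for (i in seq_len(n)) {
    g <- grp[i]
    muscles <- list()
    for (lab in names(config$specs[[g]])) {
      sp <- config$specs[[g]][[lab]]
      if (is.null(sp)) stop_respiromics(sprintf("config lacks a spec for muscle %s", lab), "respiromics_config_error")
      ## per-subject slice count (~6% CV, floored well above the minimum span)
      ns <- max(50L, as.integer(round(stats::rnorm(1, sp$n_slices, 0.06 * sp$n_slices))))
      sp$n_slices <- ns
      sp$landmark_true <- as.integer(round(ns / 2 + stats::runif(1, -0.03, 0.03) * ns))
      anc <- .density_anchors[[lab]]
      if (config$subject_sd && !is.null(anc)) {
        beta <- anc$beta_age
        age_ref <- .age_anchors[[g]]["mean"]
        age_sd <- .age_anchors[[g]]["sd"]
        resid_sd <- sqrt(max(anc$sd[[g]]^2 - beta^2 * age_sd^2, 16))
        target <- anc$mean[[g]] + beta * (age[i] - age_ref) + stats::rnorm(1, 0, resid_sd)
        ## subject-level fat infiltration; density target preserved by
        ## re-calibrating the muscle-component mean below
        sp$fat_fraction <- min(0.85, max(0.02,
          stats::rnorm(1, sp$fat_fraction, config$fat_subject_sd)))
        sp$mu_muscle <- calibrate_mu(sp, target)
      }
      muscles[[lab]] <- generate_muscle_volume(subjects[i, ], sp)
    }
    data[[i]] <- muscles
  }
  structure(list(subjects = subjects, data = data, config = config),
            class = "cohort_bundle")
}

## Small polynomial rolling hash over a serialized object, for manifest
## provenance (not cryptographic).
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(utils::capture.output(utils::str(x, digits.d = 10)), collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write a cohort bundle to disk
#'
#' Volumes and masks are written as NIfTI (`.nii.gz`), the subject table as
#' CSV, and a JSON manifest records files, seed, and a config hash.
#'
#' @param bundle A `cohort_bundle` from [generate_cohort()].
#' @param directory Output directory (created if needed).
#' @param overwrite Overwrite an existing manifest? Default `FALSE`.
#' @return Path to the manifest file, invisibly.
#' @export
write_bundle <- function(bundle, directory, overwrite = FALSE) {
  assert_that(inherits(bundle, "cohort_bundle"), "bundle must be a cohort_bundle")
  if (nrow(bundle$subjects) == 0L)
    stop_respiromics("empty cohort: nothing to write", "respiromics_config_error")
  manifest_path <- file.path(directory, "manifest.json")
  if (file.exists(manifest_path) && !overwrite)
    stop_respiromics(sprintf("manifest already exists at %s (use overwrite = TRUE)", manifest_path),
                     "respiromics_io_error")
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  for (id in names(bundle$data)) {
    for (lab in names(bundle$data[[id]])) {
      entry <- bundle$data[[id]][[lab]]
      safe <- gsub("[^A-Za-z0-9]", "", lab)
      vpath <- file.path(directory, sprintf("%s_%s_ct.nii.gz", id, safe))
      mpath <- file.path(directory, sprintf("%s_%s_mask.nii.gz", id, safe))
      write_nifti_volume(entry$volume$voxels, entry$volume$spacing, vpath)
      write_nifti_volume(entry$mask$voxels * 1L, entry$volume$spacing, mpath)
      files[[length(files) + 1L]] <- list(subject = id, muscle = lab,
                                          volume = basename(vpath), mask = basename(mpath),
                                          plane = entry$mask$plane,
                                          landmark_true = entry$landmark_true)
    }
  }
  subj_path <- file.path(directory, "subjects.csv")
  utils::write.csv(bundle$subjects, subj_path, row.names = FALSE)
  manifest <- list(seed = bundle$config$seed,
                   n_subjects = bundle$config$n_subjects,
                   sarcopenic_fraction = bundle$config$sarcopenic_fraction,
                   config_hash = config_hash(bundle$config),
                   subjects_csv = basename(subj_path),
                   files = files)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest_path)
}

#' Read a cohort bundle written by [write_bundle()]
#'
#' @param directory Directory containing `manifest.json`.
#' @return A `cohort_bundle`.
#' @export
read_bundle <- function(directory) {
  manifest_path <- file.path(directory, "manifest.json")
  assert_that(file.exists(manifest_path), sprintf("no manifest.json in %s", directory))
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  subjects <- utils::read.csv(file.path(directory, manifest$subjects_csv),
                              stringsAsFactors = FALSE)
  data <- list()
  for (f in manifest$files) {
    pair <- load_pair(file.path(directory, f$volume), file.path(directory, f$mask),
                      label = f$muscle, plane = f$plane)
    data[[f$subject]][[f$muscle]] <- list(volume = pair$volume, mask = pair$mask,
                                          landmark_true = f$landmark_true)
  }
  structure(list(subjects = subjects, data = data,
                 config = list(seed = manifest$seed, config_hash = manifest$config_hash)),
            class = "cohort_bundle")
}
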