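## One-command pipeline: simulate (or load) a cohort, build and filter slice
## stacks, profile slices, select landmarks, sample slice sets, extract
## features, evaluate deviations, and run the biomarker analysis, with a
## reproducibility manifest.

#' Pipeline configuration
#'
#' Defaults reproduce the protocol constants: 20% pixel-count filter, +/-3
#' z-filter, set sizes 1/3/5/7 with stride 6 and offsets -2..+2, 10 CV
#' folds, alpha 0.05, correlation threshold 0.9.
#'
#' @param cohort A [cohort_config()] (simulate mode) or a directory written
#'   by [write_bundle()] (load mode).
#' @param settings [discretization_settings()].
#' @param pixel_fraction,z_threshold Slice-filter parameters.
#' @param sizes,stride,offsets Slice-set geometry.
#' @param bin_edges Histogram edges for Jensen-Shannon profiling.
#' @param landmark_mode `"auto"` (data-driven) or `"true"` (use the
#'   generator's ground-truth landmark).
#' @param feature_mode `"full"` (radiomic vectors) or `"density"` (mean
#'   density and SD only; much faster).
#' @param alpha,correction,folds,corr_threshold Statistics parameters.
#' @param seed Seed for the statistical stages (fold splits).
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(cohort = cohort_config(), settings = discretization_settings(),
                            pixel_fraction = 0.20, z_threshold = 3.0,
                            sizes = c(1, 3, 5, 7), stride = 6L, offsets = -2:2,
                            bin_edges = default_bin_edges(),
                            landmark_mode = c("auto", "true"),
                            feature_mode = c("full", "density"),
                            alpha = 0.05, correction = "holm", folds = 10,
                            corr_threshold = 0.9, seed = 1L) {
  landmark_mode <- match.arg(landmark_mode)
  feature_mode <- match.arg(feature_mode)
  structure(list(cohort = cohort, settings = settings,
                 pixel_fraction = pixel_fraction, z_threshold = z_threshold,
                 sizes = sizes, stride = as.integer(stride), offsets = as.integer(offsets),
                 bin_edges = bin_edges, landmark_mode = landmark_mode,
                 feature_mode = feature_mode, alpha = alpha, correction = correction,
                 folds = folds, corr_threshold = corr_threshold, seed = as.integer(seed)),
            class = "pipeline_config")
}

with_stage_context <- function(stage, subject, muscle, expr) {
  tryCatch(expr, error = function(e) {
    stop_respiromics(sprintf("stage '%s' failed for subject %s, muscle %s: %s",
                             stage, subject, muscle, conditionMessage(e)),
                     "respiromics_pipeline_error")
  })
}

## Density-only feature vector (pooled mean and SD over the given slices).
density_vector <- function(stack, slices) {
  vals <- unlist(slice_values(stack)[as.character(slices)], use.names = FALSE)
  make_feature_vector(c(density_mean = mean(vals),
                        density_sd = if (length(vals) > 1) stats::sd(vals) else 0))
}

## Per-slice 2D feature cache: one vector per requested slice, reused across
## the (overlapping) slice sets.
per_slice_feature_cache <- function(volume, mask, stack, settings, slices) {
  axis <- volume$axis_roles[[mask$plane]]
  in_plane <- volume$spacing[setdiff(1:3, axis)]
  out <- lapply(slices, function(s) {
    vox2 <- slice_index_matrix(volume$voxels, axis, s + 1L)
    msk2 <- slice_index_matrix(mask$voxels, axis, s + 1L)
    vals <- vox2[msk2]
    gray <- matrix(NA_integer_, nrow(vox2), ncol(vox2))
    gray[msk2] <- discretize(vals, settings)
    region_features(vals, gray, msk2, in_plane, settings)
  })
  names(out) <- as.character(slices)
  out
}

set_feature_vector <- function(stack, set, cache) {
  mat <- do.call(rbind, lapply(cache[as.character(set$indices)], `[[`, "vec"))
  avg <- colMeans(mat, na.rm = TRUE)
  avg[colSums(!is.na(mat)) == 0L] <- NA_real_
  flagged <- unique(unlist(lapply(cache[as.character(set$indices)], `[[`, "flagged")))
  dens <- density_vector(stack, set$indices)
  make_feature_vector(c(dens[c("density_mean", "density_sd")], avg),
                      union(flagged, names(avg)[is.na(avg)]))
}

#' Run the full analysis pipeline
#'
#' Stages run in fixed order (simulate/load, stack, filter, profile,
#' landmark, sets, extract, evaluate, biomarkers); any stage error aborts
#' with the stage name and subject/muscle context. Reruns with the same
#' configuration produce identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory for CSV/JSON artifacts and the manifest.
#' @return A `pipeline_result` list (see Details in the package vignette).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  assert_that(inherits(config, "pipeline_config"), "config must be a pipeline_config")
  bundle <- if (inherits(config$cohort, "cohort_config")) generate_cohort(config$cohort)
            else read_bundle(config$cohort)
  subjects <- bundle$subjects
  warnings <- character(0)

  profile_rows <- list(); landmark_rows <- list(); error_rows <- list()
  whole_vectors <- list()
  density_by_size <- list() # per muscle: subject x set-size mean density

  for (id in names(bundle$data)) {
    for (lab in names(bundle$data[[id]])) {
      entry <- bundle$data[[id]][[lab]]
      volume <- entry$volume; mask <- entry$mask
      stack <- with_stage_context("stack", id, lab, build_stack(volume, mask))
      stack <- with_stage_context("filter", id, lab,
                                  filter_slices(stack, config$pixel_fraction, config$z_threshold))
      profile <- with_stage_context("profile", id, lab, js_profile(stack, config$bin_edges))
      landmark <- with_stage_context("landmark", id, lab, {
        if (config$landmark_mode == "true" && !is.null(entry$landmark_true))
          select_landmark(profile, "fixed", fixed_index = entry$landmark_true)
        else select_landmark(profile, "auto")
      })
      sets <- with_stage_context("sets", id, lab,
                                 build_slice_sets(landmark, stack$index[stack$retained],
                                                  sizes = config$sizes, stride = config$stride,
                                                  offsets = config$offsets))
      if (config$feature_mode == "full") {
        whole <- with_stage_context("extract", id, lab,
                                    extract_features(volume, mask, "whole_3d",
                                                     settings = config$settings, stack = stack))
        needed <- sort(unique(unlist(lapply(sets, `[[`, "indices"))))
        cache <- with_stage_context("extract", id, lab,
                                    per_slice_feature_cache(volume, mask, stack,
                                                            config$settings, needed))
        set_entries <- lapply(sets, function(st) {
          fv <- set_feature_vector(stack, st, cache)
          ## per-slice 2D vectors carry 2D shape descriptors with no 3D
          ## counterpart; deviations are computed over the shared features
          shared <- intersect(names(fv), names(whole))
          list(set = st, features = make_feature_vector(
            stats::setNames(as.numeric(fv[shared]), shared),
            attr(fv, "flagged")))
        })
      } else {
        whole <- density_vector(stack, stack$index[stack$retained])
        set_entries <- lapply(sets, function(st)
          list(set = st, features = density_vector(stack, st$indices)))
      }
      rows <- with_stage_context("evaluate", id, lab, deviation_table(whole, set_entries))
      rows <- cbind(data.frame(subject = id, muscle = lab, stringsAsFactors = FALSE), rows)
      error_rows[[length(error_rows) + 1L]] <- rows
      whole_vectors[[lab]][[id]] <- whole
      profile_rows[[length(profile_rows) + 1L]] <-
        cbind(data.frame(subject = id, muscle = lab, stringsAsFactors = FALSE), profile)
      landmark_rows[[length(landmark_rows) + 1L]] <-
        data.frame(subject = id, muscle = lab, landmark = landmark,
                   landmark_true = entry$landmark_true %||% NA_integer_,
                   n_retained = sum(stack$retained), stringsAsFactors = FALSE)
      ## per-subject mean density by set size (offset-averaged) for Friedman
      dens <- vapply(config$sizes, function(sz) {
        vals <- vapply(set_entries, function(e)
          if (e$set$size == sz) e$features[["density_mean"]] else NA_real_, 0)
        mean(vals, na.rm = TRUE)
      }, 0)
      density_by_size[[lab]] <- rbind(density_by_size[[lab]], dens)
    }
  }

  errors <- do.call(rbind, error_rows)
  aggregates <- aggregate_errors(errors)
  dens_rows <- errors[errors$feature == "density_mean", , drop = FALSE]
  set_size_stats <- compare_set_sizes(errors, group_by = "set_size", alpha = config$alpha)
  offset_stats <- lapply(split(dens_rows, dens_rows$muscle), function(d)
    compare_groups(d$deviation, d$offset, alpha = config$alpha))
  friedman <- lapply(density_by_size, function(m) {
    colnames(m) <- paste0(config$sizes, "S")
    friedman_effect(m, alpha = config$alpha)
  })

  ## whole-muscle densities for the demographic analysis
  densities <- as.data.frame(lapply(whole_vectors, function(lst)
    vapply(lst[subjects$id], function(v) v[["density_mean"]], 0)),
    check.names = FALSE)
  density_stats <- density_group_stats(densities, subjects$sarcopenic,
                                       subjects$age, subjects$bmi, alpha = config$alpha)

  selection <- NULL
  if (config$feature_mode == "full") {
    selection <- lapply(whole_vectors, function(lst) {
      mat <- do.call(rbind, lapply(lst[subjects$id], as.numeric))
      colnames(mat) <- names(lst[[1]])
      rownames(mat) <- subjects$id
      tryCatch(select_biomarkers(mat, subjects$sarcopenic,
                                 corr_threshold = config$corr_threshold,
                                 folds = config$folds, seed = config$seed,
                                 alpha = config$alpha),
               error = function(e) {
                 warnings <<- c(warnings, sprintf("selection failed: %s", conditionMessage(e)))
                 NULL
               })
    })
  }

  manifest <- list(
    seed = config$seed,
    cohort = if (inherits(config$cohort, "cohort_config"))
      list(mode = "simulate", n_subjects = config$cohort$n_subjects,
           sarcopenic_fraction = config$cohort$sarcopenic_fraction,
           seed = config$cohort$seed, subject_sd = config$cohort$subject_sd)
      else list(mode = "load", path = config$cohort),
    parameters = list(bin_width = config$settings$bin_width,
                      pixel_fraction = config$pixel_fraction,
                      z_threshold = config$z_threshold,
                      sizes = config$sizes, stride = config$stride,
                      offsets = config$offsets,
                      bin_edges = range(config$bin_edges),
                      bin_step = diff(config$bin_edges)[1],
                      landmark_mode = config$landmark_mode,
                      feature_mode = config$feature_mode,
                      alpha = config$alpha, correction = config$correction,
                      folds = config$folds, corr_threshold = config$corr_threshold),
    config_hash = config_hash(config),
    warnings = warnings)

  result <- structure(list(subjects = subjects, errors = errors,
                           aggregates = aggregates, profiles = do.call(rbind, profile_rows),
                           landmarks = do.call(rbind, landmark_rows),
                           densities = densities, density_stats = density_stats,
                           set_size_stats = set_size_stats, offset_stats = offset_stats,
                           friedman = friedman, selection = selection,
                           manifest = manifest),
                      class = "pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(subjects, file.path(out_dir, "subjects.csv"), row.names = FALSE)
    utils::write.csv(errors, file.path(out_dir, "errors.csv"), row.names = FALSE)
    utils::write.csv(aggregates, file.path(out_dir, "aggregates.csv"), row.names = FALSE)
    utils::write.csv(result$profiles, file.path(out_dir, "profile.csv"), row.names = FALSE)
    utils::write.csv(result$landmarks, file.path(out_dir, "landmarks.csv"), row.names = FALSE)
    stats_out <- list(
      friedman = lapply(friedman, unclass),
      offset_density = lapply(offset_stats, function(s)
        list(omnibus = s$omnibus, p = s$omnibus_p)),
      density_group_tests = density_stats$group_tests,
      age_sarcopenia = density_stats$age_sarcopenia)
    jsonlite::write_json(stats_out, file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA, force = TRUE)
    if (!is.null(selection))
      jsonlite::write_json(lapply(selection, function(s) if (is.null(s)) NULL else unclass(s)),
                           file.path(out_dir, "selection.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA, force = TRUE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA, force = TRUE)
  }
  result
}

#' Density MAE summary per muscle and set size
#'
#' Convenience accessor: the mean absolute error of mean density (HU) per
#' muscle and slice-set size, aggregated over subjects and offsets.
#'
#' @param result A `pipeline_result`.
#' @return Data frame `muscle`, `set_size`, `mae_hu`.
#' @export
density_mae <- function(result) {
  agg <- result$aggregates
  d <- agg[agg$feature == "density_mean", c("muscle", "set_size", "error")]
  names(d)[3] <- "mae_hu"
  rownames(d) <- NULL
  d
}
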