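# Small synthetic fixtures shared across tests.

# A compact PM-like spec; knobs off by default so tests opt in to each
# heterogeneity mechanism explicitly.
small_spec <- function(n_slices = 50, fat_fraction = 0.1, edge_fat_boost = 0,
                       axial_gradient = 0, sigma_within = 12,
                       semi_axes = c(10, 7), label = "PM", ...) {
  muscle_spec(label, n_slices = n_slices, fat_fraction = fat_fraction,
              edge_fat_boost = edge_fat_boost, axial_gradient = axial_gradient,
              sigma_within = sigma_within, semi_axes = semi_axes, ...)
}

# Volume/mask pair with prescribed per-slice masked values (axial plane).
# `slice_values_list` gives the masked HU values of each slice; voxels are
# laid out along the first in-plane axis.
stack_from_values <- function(slice_values_list, spacing = c(1, 1, 1)) {
  n <- length(slice_values_list)
  npix <- max(vapply(slice_values_list, length, 0L))
  vox <- array(-1024, dim = c(npix, 1, n))
  msk <- array(FALSE, dim = c(npix, 1, n))
  for (i in seq_len(n)) {
    v <- slice_values_list[[i]]
    vox[seq_along(v), 1, i] <- v
    msk[seq_along(v), 1, i] <- TRUE
  }
  build_stack(ct_volume(vox, spacing), muscle_mask(msk, label = "PM", plane = "axial"))
}

# Feature matrix with planted group structure: `informative` columns are
# shifted by `effect` (in SDs) for the labelled group.
planted_matrix <- function(n = 120, p = 50, informative = 5, effect = 1.0,
                           balance = 0.5) {
  x <- matrix(stats::rnorm(n * p), n, p)
  colnames(x) <- c(paste0("glcm_sig", seq_len(informative)),
                   paste0("firstorder_noise", seq_len(p - informative)))
  labels <- seq_len(n) <= round(n * balance)
  x[labels, seq_len(informative)] <- x[labels, seq_len(informative)] + effect
  list(x = x, labels = labels,
       informative = colnames(x)[seq_len(informative)])
}
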