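# Shared fixtures, computed lazily and cached for the whole test run.

.gm_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.gm_cache[[key]])) .gm_cache[[key]] <- force(expr)
  .gm_cache[[key]]
}

# Reduced-grid spec: default study design (45 HC / 40 AD) on a small grid,
# fast enough to regenerate in seconds.
reduced_spec <- function(seed = 1, ...) {
  cohort_spec(grid_shape = c(24L, 24L, 12L), seed = seed, ...)
}

# Null spec: no atrophy, no group-dependent covariance.
null_spec <- function(seed = 1, grid_shape = c(20L, 20L, 10L)) {
  regs <- c("overlapped", "continuing", "STG_left", "STG_right", "caudate_left")
  cohort_spec(grid_shape = grid_shape, seed = seed,
              atrophy_effects = data.frame(name = regs, delta_t1 = 0,
                                           delta_t2 = 0),
              covariance_loadings = data.frame(group = character(0),
                                               name = character(0),
                                               loading = numeric(0)),
              progression_baseline_coupling = 0, behavior_coupling = 0)
}

default_cohort <- function() cached("default_cohort", {
  generate_cohort(cohort_spec())
})

# One full default-scale pipeline run shared by the acceptance tests
# (permutation/bootstrap counts reduced to keep the suite fast; those
# counts only sharpen p values, not the quantities asserted here).
default_report <- function() cached("default_report", {
  run_pipeline(pipeline_config(spec = cohort_spec(),
                               n_perm = 1000, n_resamples = 1000))
})

# Reduced-grid pipeline run for structural checks. On the 24^2 grid the
# planted discs hold ~29 skeleton voxels, so the cluster-extent threshold
# is scaled down along with the grid.
reduced_report <- function() cached("reduced_report", {
  run_pipeline(pipeline_config(spec = reduced_spec(),
                               min_cluster_voxels = 10,
                               n_perm = 500, n_resamples = 500))
})

# ROI means over the planted (truth) masks on the slab medial plane --
# generator-side measurement used by calibration tests, independent of the
# skeleton/voxelstats pipeline.
truth_roi_means <- function(cohort) {
  plane_vox <- lapply(cohort$truth$true_region_masks, function(m) {
    ijk <- which(m, arr.ind = TRUE)
    keep <- ijk[, 3] == cohort$truth$slab_plane
    ijk[keep, , drop = FALSE]
  })
  out <- sapply(plane_vox, function(ijk) {
    idx <- (ijk[, 3] - 1) * prod(dim(cohort$volumes[[1]]$data)[1:2]) +
           (ijk[, 2] - 1) * dim(cohort$volumes[[1]]$data)[1] + ijk[, 1]
    vapply(cohort$volumes, function(v) mean(v$data[idx]), 0)
  })
  as.data.frame(out)
}

# Minimal hand-built skeleton model: the full z = k plane of a grid.
plane_model <- function(dimv = c(8L, 8L, 5L), k = 3L, voxel_size = 2) {
  mask <- array(FALSE, dimv); mask[, , k] <- TRUE
  mm <- gm_volume(array(0.5, dimv), voxel_size)
  structure(list(mean_map = mm, skeleton_mask = mask,
                 voxel_index = sort(which(mask)), gm_threshold = 0.2,
                 smoothing_sigma_mm = 2, method = "ridge"),
            class = "skeleton_model")
}

# Brute-force Benjamini-Hochberg step-up rejection set (independent oracle).
bh_stepup_reject <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- suppressWarnings(max(which(ps <= (seq_len(m) / m) * alpha)))
  rej <- logical(m)
  if (is.finite(k) && k >= 1) rej[o[seq_len(k)]] <- TRUE
  rej
}

dice_masks <- function(vox_a, vox_b) {
  2 * length(intersect(vox_a, vox_b)) / (length(vox_a) + length(vox_b))
}

# Dice between a discovered region set's voxels and a planted mask,
# evaluated on the skeleton (planted spheres extend off the sampling
# surface; recovery is judged where measurement happens).
dice_vs_truth <- function(regions, truth_mask, model) {
  dice_masks(which(regions$labels > 0),
             intersect(which(truth_mask), model$voxel_index))
}
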