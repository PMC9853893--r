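#' Specify a synthetic longitudinal atrophy cohort
#'
#' Builds the full parameterization of the synthetic cohort generator: a
#' cross-sectional healthy-control (HC) group and an AD group scanned at
#' baseline (T1) and one-year follow-up (T2), with atrophy planted in named
#' spherical regions on a cortical slab, group-dependent inter-regional
#' covariance planted through a per-subject latent factor, and a planted
#' correlation between regional GMV change and MoCA change.
#'
#' The default design emulates a study of 45 HC (one scan each) and 40 AD
#' patients (paired scans one year apart, 38 with MoCA at both timepoints)
#' with five planted region groups:
#' \describe{
#'   \item{overlapped}{atrophic at both T1 and T2 relative to HC, little
#'     further change — recovered by intersecting the two group contrasts.}
#'   \item{continuing}{essentially intact at T1, clearly atrophic at T2 and
#'     declining within subjects — the "deficit that keeps worsening".}
#'   \item{STG_left, STG_right, caudate_left}{progressive regions: strong
#'     within-subject decline over the year with large between-subject
#'     variability, so the paired contrast detects them much more readily
#'     than the cross-sectional one. The subject-level progression rate of
#'     `STG_right` and `caudate_left` shares one latent severity factor,
#'     which also drives MoCA decline (coupling `behavior_coupling`) and is
#'     itself partly predicted by baseline GMV in the overlapped region
#'     (cross-lagged effect). `STG_left` progresses under an independent
#'     latent, so its change is uncoupled from MoCA change.}
#' }
#' A structural-covariance difference is planted on exactly one edge:
#' `STG_right`–`caudate_left` covary in HC (Pearson r about 0.7) and not in
#' AD.
#'
#' @param n_hc,n_ad,n_ad_with_moca_both group sizes; `n_ad_with_moca_both`
#'   AD subjects have MoCA at both timepoints (the rest miss it at T2).
#' @param grid_shape 3 positive integers, voxel grid.
#' @param voxel_size_mm positive voxel edge length (isotropic), mm.
#' @param region_definitions data frame with columns `name, cx, cy, cz,
#'   radius` (1-based voxel coordinates); `NULL` places the five default
#'   spheres scaled to `grid_shape` on the slab's medial plane.
#' @param atrophy_effects data frame `name, delta_t1, delta_t2`: fractional
#'   GMV loss in the AD group relative to the region's baseline amplitude,
#'   at each timepoint; both in `[0, 1)`.
#' @param covariance_loadings data frame `group, name, loading`: loading of
#'   each (group, region) on the shared per-subject latent factor. Regions
#'   absent from the table load 0.
#' @param region_sd named vector: SD of the subject-specific region
#'   intercept (idiosyncratic between-subject variability, shared across a
#'   subject's timepoints — this is what makes paired tests powerful).
#' @param progression_sd named vector: SD of the extra subject-specific T2
#'   atrophy in progressive regions (GMV units).
#' @param progression_baseline_coupling correlation between the shared
#'   progression severity latent and (low) baseline GMV in the overlapped
#'   region; this plants the cross-lagged effect.
#' @param behavior_coupling target correlation between the shared
#'   progression latent and MoCA decline, hence (up to small measurement
#'   attenuation) between regional GMV change and MoCA change.
#' @param behavior_regions regions whose progression follows the shared
#'   (MoCA-coupled) latent.
#' @param slab_amplitude GMV value at the slab's medial plane outside
#'   planted regions.
#' @param slab_half_thickness_vox half-thickness of the cortical slab in
#'   voxels (total thickness `2*h + 1`).
#' @param region_amplitude baseline GMV added at the medial plane inside a
#'   planted region (before atrophy).
#' @param noise_sd SD of i.i.d. voxel noise added to every scan.
#' @param seed integer RNG seed; the whole cohort is a deterministic
#'   function of the spec including this seed.
#' @return A validated `cohort_spec` object (list).
#' @seealso [generate_cohort()], [generate_phenotypes()]
#' @export
cohort_spec <- function(n_hc = 45, n_ad = 40, n_ad_with_moca_both = 38,
                        grid_shape = c(48L, 48L, 24L),
                        voxel_size_mm = 2,
                        region_definitions = NULL,
                        atrophy_effects = NULL,
                        covariance_loadings = NULL,
                        region_sd = NULL,
                        progression_sd = NULL,
                        progression_baseline_coupling = 0.6,
                        behavior_coupling = 0.44,
                        behavior_regions = c("STG_right", "caudate_left"),
                        slab_amplitude = 0.4,
                        slab_half_thickness_vox = 2L,
                        region_amplitude = 0.8,
                        noise_sd = 0.06,
                        seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  slab_plane <- as.integer(round(grid_shape[3] / 2))
  if (is.null(region_definitions))
    region_definitions <- default_regions(grid_shape, slab_plane)
  if (is.null(atrophy_effects))
    atrophy_effects <- data.frame(
      name     = c("overlapped", "continuing", "STG_left", "STG_right", "caudate_left"),
      delta_t1 = c(0.25, 0.02, 0.02, 0.02, 0.02),
      delta_t2 = c(0.28, 0.18, 0.17, 0.17, 0.17),
      stringsAsFactors = FALSE)
  if (is.null(covariance_loadings))
    covariance_loadings <- data.frame(
      group   = c("HC", "HC"),
      name    = c("STG_right", "caudate_left"),
      loading = c(0.31, 0.31),
      stringsAsFactors = FALSE)
  if (is.null(region_sd))
    region_sd <- c(overlapped = 0.05, continuing = 0.08,
                   STG_left = 0.20, STG_right = 0.20, caudate_left = 0.20)
  if (is.null(progression_sd))
    progression_sd <- c(continuing = 0.03, STG_left = 0.05, STG_right = 0.05,
                        caudate_left = 0.05)

  spec <- structure(list(
    n_hc = as.integer(n_hc), n_ad = as.integer(n_ad),
    n_ad_with_moca_both = as.integer(n_ad_with_moca_both),
    grid_shape = grid_shape, voxel_size_mm = as.numeric(voxel_size_mm),
    slab_plane = slab_plane,
    region_definitions = region_definitions,
    atrophy_effects = atrophy_effects,
    covariance_loadings = covariance_loadings,
    region_sd = region_sd, progression_sd = progression_sd,
    progression_baseline_coupling = progression_baseline_coupling,
    behavior_coupling = behavior_coupling,
    behavior_regions = behavior_regions,
    slab_amplitude = slab_amplitude,
    slab_half_thickness_vox = as.integer(slab_half_thickness_vox),
    region_amplitude = region_amplitude,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

# Five default spheres on the slab medial plane, scaled to the grid.
default_regions <- function(grid_shape, slab_plane) {
  nx <- grid_shape[1]; ny <- grid_shape[2]
  r <- max(3L, as.integer(round(min(nx, ny) / 12)))
  at <- function(fx, fy) c(as.integer(round(fx * nx)), as.integer(round(fy * ny)))
  ctr <- rbind(overlapped   = at(0.25, 0.25),
               continuing   = at(0.25, 0.75),
               STG_left     = at(0.75, 0.25),
               STG_right    = at(0.75, 0.75),
               caudate_left = at(0.50, 0.50))
  data.frame(name = rownames(ctr), cx = ctr[, 1], cy = ctr[, 2],
             cz = slab_plane, radius = r, stringsAsFactors = FALSE,
             row.names = NULL)
}

validate_cohort_spec <- function(spec) {
  fail <- function(field, why)
    stop_gm("invalid cohort_spec: field '", field, "' ", why,
            class = "gmprog_validation_error")
  if (is.na(spec$n_hc) || spec$n_hc < 1) fail("n_hc", "must be a positive count")
  if (is.na(spec$n_ad) || spec$n_ad < 1) fail("n_ad", "must be a positive count")
  if (spec$n_ad_with_moca_both > spec$n_ad || spec$n_ad_with_moca_both < 0)
    fail("n_ad_with_moca_both", "must lie in [0, n_ad]")
  if (length(spec$grid_shape) != 3 || any(spec$grid_shape < 1))
    fail("grid_shape", "must be 3 positive integers")
  if (!is.finite(spec$voxel_size_mm) || spec$voxel_size_mm <= 0)
    fail("voxel_size_mm", "must be a positive real")
  rd <- spec$region_definitions
  if (!all(c("name", "cx", "cy", "cz", "radius") %in% names(rd)))
    fail("region_definitions", "needs columns name, cx, cy, cz, radius")
  if (anyDuplicated(rd$name)) fail("region_definitions", "has duplicate names")
  if (any(rd$radius <= 0)) fail("region_definitions", "has non-positive radius")
  inside <- rd$cx - rd$radius >= 1 & rd$cx + rd$radius <= spec$grid_shape[1] &
            rd$cy - rd$radius >= 1 & rd$cy + rd$radius <= spec$grid_shape[2] &
            rd$cz - rd$radius >= 1 & rd$cz + rd$radius <= spec$grid_shape[3]
  if (!all(inside))
    fail("region_definitions",
         paste0("spheres outside grid: ", paste(rd$name[!inside], collapse = ", ")))
  ae <- spec$atrophy_effects
  if (!all(c("name", "delta_t1", "delta_t2") %in% names(ae)))
    fail("atrophy_effects", "needs columns name, delta_t1, delta_t2")
  if (!all(ae$name %in% rd$name))
    fail("atrophy_effects", "names not in region_definitions")
  if (any(ae$delta_t1 < 0 | ae$delta_t1 >= 1 | ae$delta_t2 < 0 | ae$delta_t2 >= 1))
    fail("atrophy_effects", "deltas must lie in [0, 1)")
  cl <- spec$covariance_loadings
  if (nrow(cl) && !all(c("group", "name", "loading") %in% names(cl)))
    fail("covariance_loadings", "needs columns group, name, loading")
  if (nrow(cl) && !all(cl$name %in% rd$name))
    fail("covariance_loadings", "names not in region_definitions")
  if (nrow(cl) && !all(cl$group %in% c("HC", "AD")))
    fail("covariance_loadings", "group must be HC or AD")
  if (!all(names(spec$region_sd) %in% rd$name))
    fail("region_sd", "names not in region_definitions")
  if (!all(names(spec$progression_sd) %in% rd$name))
    fail("progression_sd", "names not in region_definitions")
  if (any(spec$region_sd < 0)) fail("region_sd", "must be non-negative")
  if (any(spec$progression_sd < 0)) fail("progression_sd", "must be non-negative")
  if (abs(spec$progression_baseline_coupling) > 1)
    fail("progression_baseline_coupling", "must lie in [-1, 1]")
  if (abs(spec$behavior_coupling) > 1)
    fail("behavior_coupling", "must lie in [-1, 1]")
  if (!all(spec$behavior_regions %in% rd$name))
    fail("behavior_regions", "names not in region_definitions")
  if (!is.finite(spec$noise_sd) || spec$noise_sd <= 0)
    fail("noise_sd", "must be a positive real")
  if (spec$slab_amplitude <= 0) fail("slab_amplitude", "must be positive")
  h <- spec$slab_half_thickness_vox
  if (h < 1 || spec$slab_plane - h < 1 || spec$slab_plane + h > spec$grid_shape[3])
    fail("slab_half_thickness_vox", "slab must fit inside the grid")
  if (!is.finite(spec$seed)) fail("seed", "must be an integer")
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec> HC n=", x$n_hc, ", AD n=", x$n_ad,
      " (", x$n_ad_with_moca_both, " with MoCA at both timepoints)\n",
      "  grid ", paste(x$grid_shape, collapse = "x"), " @ ",
      x$voxel_size_mm, " mm, slab plane z=", x$slab_plane,
      ", noise sd ", x$noise_sd, ", seed ", x$seed, "\n",
      "  regions: ", paste(x$region_definitions$name, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
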