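#' Generate the synthetic longitudinal cohort
#'
#' Draws the full cohort defined by a [cohort_spec()]: one modulated-GMV
#' volume per scan (`n_hc + 2 * n_ad` volumes), a phenotype table, and a
#' planted-truth manifest for parameter-recovery testing.
#'
#' Each volume is a smooth "cortical slab" — a thick sheet whose
#' through-thickness profile is parabolic and peaks at its medial plane
#' (the analytically known skeleton) — plus spherical regions whose
#' medial-plane intensity for subject *s*, region *r*, timepoint *t* is
#'
#' \deqn{A_r (1 - \delta_{r,t}) + \lambda_{g,r} f_s + b_{s,r} -
#'   [t = T2] \, c_r \, u_{s,r} ,}
#'
#' with `f_s` a standard-normal per-subject factor (plants inter-regional
#' covariance via the loadings), `b_{s,r}` a subject-by-region intercept
#' shared across timepoints (so paired contrasts gain power), and `u` a
#' progression-severity latent scaled by `progression_sd`. Off the medial
#' plane, intensities follow the slab's parabolic profile; i.i.d. Gaussian
#' voxel noise (`noise_sd`) is added everywhere and values are clipped at
#' zero. MoCA decline in AD subjects is coupled to the shared progression
#' latent with correlation `behavior_coupling`, and that latent is itself
#' partially predicted by the subject's baseline intercept in the
#' overlapped region (`progression_baseline_coupling`), planting a
#' cross-lagged effect of baseline overlapped-region GMV on later change.
#'
#' The output is a deterministic function of the spec (including its
#' `seed`); the phenotype table equals `generate_phenotypes(spec)`.
#'
#' @param spec a [cohort_spec()].
#' @return A list of class `gm_cohort`:
#' \describe{
#'   \item{volumes}{named list of [gm_volume], one per scan, names
#'     `<subject_id>_<timepoint>`.}
#'   \item{phenotypes}{data frame: `subject_id, group, timepoint, sex,
#'     age, CDR, MMSE, MoCA` (one row per scan, aligned with `volumes`).}
#'   \item{truth}{planted-truth manifest: `true_region_masks` (named 3D
#'     logical arrays), `true_group_means` (expected medial-plane ROI mean
#'     per group/timepoint/region), `true_cov_difference_edges`,
#'     `true_behavior_r`, `slab_plane`, and the subject `latents`.}
#' }
#' @examples
#' spec <- cohort_spec(n_hc = 6, n_ad = 5, n_ad_with_moca_both = 5,
#'                     grid_shape = c(24, 24, 12), seed = 7)
#' ch <- generate_cohort(spec)
#' length(ch$volumes)   # 6 + 2*5 scans
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  set.seed(spec$seed)
  lat <- draw_latents(spec)
  phen <- draw_phenotypes(spec, lat)

  dimv <- spec$grid_shape
  z <- seq_len(dimv[3])
  prof <- pmax(0, 1 - ((z - spec$slab_plane) / (spec$slab_half_thickness_vox + 1))^2)
  prof[abs(z - spec$slab_plane) > spec$slab_half_thickness_vox] <- 0
  base <- array(rep(prof * spec$slab_amplitude, each = dimv[1] * dimv[2]), dimv)

  rd <- spec$region_definitions
  masks <- region_sphere_masks(spec)
  # per-region voxel indices and their slab-profile factor
  ridx <- lapply(masks, which)
  rprof <- lapply(ridx, function(ix) {
    k <- index_to_ijk(ix, dimv)[, "k"]
    prof[k]
  })

  scans <- scan_table(spec)
  vols <- vector("list", nrow(scans))
  names(vols) <- scans$scan_id
  nvox <- prod(dimv)
  for (i in seq_len(nrow(scans))) {
    v <- base
    si <- scans$subj_index[i]
    g <- scans$group[i]; tp <- scans$timepoint[i]
    for (r in seq_len(nrow(rd))) {
      rn <- rd$name[r]
      val <- region_plane_value(spec, lat, rn, g, tp, si)
      v[ridx[[rn]]] <- v[ridx[[rn]]] + rprof[[rn]] * val
    }
    v <- v + array(rnorm(nvox, 0, spec$noise_sd), dimv)
    v[v < 0] <- 0
    vols[[i]] <- gm_volume(v, voxel_size_mm = spec$voxel_size_mm)
  }

  truth <- planted_truth(spec, masks, lat)
  structure(list(volumes = vols, phenotypes = phen, truth = truth,
                 spec = spec),
            class = "gm_cohort")
}

#' Generate the phenotype table alone
#'
#' Demographics and cognitive scores for the cohort, without simulating
#' volumes. Ages and CDR are drawn from group-specific truncated normal
#' distributions; MMSE and MoCA are integer scores drawn from normal
#' distributions clamped to their observed ranges (clamping at the bounds
#' models the floor/ceiling behaviour of bounded instruments). Sex counts
#' are fixed (22 M / 18 F among 40 AD, 27 M / 18 F among 45 HC, scaled
#' proportionally for other group sizes). CDR is exactly 0 for all HC.
#' Follow-up scores are the baseline score plus a change drawn from the
#' longitudinal model, so AD-T2 distributions match their targets while
#' within-subject trajectories stay coherent; MoCA change is coupled to the
#' shared progression latent. MoCA is missing (NA) at T2 for
#' `n_ad - n_ad_with_moca_both` AD subjects and for 2 of 45 HC
#' (proportionally for other sizes).
#'
#' @inheritParams generate_cohort
#' @return Data frame with one row per scan: `subject_id, group ("HC" or
#'   "AD"), timepoint ("T1"/"T2"), sex ("M"/"F"), age, CDR, MMSE, MoCA`.
#' @export
generate_phenotypes <- function(spec) {
  validate_cohort_spec(spec)
  set.seed(spec$seed)
  lat <- draw_latents(spec)
  draw_phenotypes(spec, lat)
}

# ---- internals ------------------------------------------------------------

scan_table <- function(spec) {
  hc_ids <- sprintf("HC%03d", seq_len(spec$n_hc))
  ad_ids <- sprintf("AD%03d", seq_len(spec$n_ad))
  rbind(
    data.frame(scan_id = paste0(hc_ids, "_T1"), subject_id = hc_ids,
               group = "HC", timepoint = "T1",
               subj_index = seq_len(spec$n_hc), stringsAsFactors = FALSE),
    data.frame(scan_id = paste0(rep(ad_ids, each = 2), "_",
                                rep(c("T1", "T2"), spec$n_ad)),
               subject_id = rep(ad_ids, each = 2),
               group = "AD", timepoint = rep(c("T1", "T2"), spec$n_ad),
               subj_index = rep(seq_len(spec$n_ad), each = 2),
               stringsAsFactors = FALSE)
  )
}

# All subject-level random effects, drawn in one fixed order.
draw_latents <- function(spec) {
  rn <- spec$region_definitions$name
  R <- length(rn)
  sdb <- setNames(rep(0, R), rn)
  sdb[names(spec$region_sd)] <- spec$region_sd

  f_hc <- rnorm(spec$n_hc)
  b_hc <- matrix(rnorm(spec$n_hc * R), spec$n_hc, R,
                 dimnames = list(NULL, rn)) %*% diag(sdb, R)
  colnames(b_hc) <- rn
  f_ad <- rnorm(spec$n_ad)
  b_ad <- matrix(rnorm(spec$n_ad * R), spec$n_ad, R,
                 dimnames = list(NULL, rn)) %*% diag(sdb, R)
  colnames(b_ad) <- rn
  w <- rnorm(spec$n_ad)           # innovation of the shared progression latent
  eta <- rnorm(spec$n_ad)         # MoCA-specific noise
  # independent innovations for non-shared progressive regions
  own <- setdiff(names(spec$progression_sd), spec$behavior_regions)
  w_own <- matrix(rnorm(spec$n_ad * length(own)), spec$n_ad,
                  dimnames = list(NULL, own))

  # progression severity latents: higher = faster decline; all partly
  # driven by a LOW baseline intercept in the overlapped region
  # (cross-lagged effect of baseline atrophy on later change); the
  # behaviour-coupled regions share one latent, others get their own
  phi <- spec$progression_baseline_coupling
  z_ov <- if ("overlapped" %in% rn && sdb[["overlapped"]] > 0 && phi != 0) {
    b_ad[, "overlapped"] / sdb[["overlapped"]]
  } else {
    phi <- 0
    numeric(spec$n_ad)
  }
  u <- -phi * z_ov + sqrt(1 - phi^2) * w
  v_own <- if (length(own)) -phi * z_ov + sqrt(1 - phi^2) * w_own else w_own

  miss_ad <- integer(0)
  n_miss <- spec$n_ad - spec$n_ad_with_moca_both
  if (n_miss > 0) miss_ad <- sort(sample.int(spec$n_ad, n_miss))
  n_miss_hc <- max(0L, spec$n_hc - round(43 / 45 * spec$n_hc))
  miss_hc <- if (n_miss_hc > 0) sort(sample.int(spec$n_hc, n_miss_hc)) else integer(0)
  m_ad <- sort(sample.int(spec$n_ad, round(22 / 40 * spec$n_ad)))
  m_hc <- sort(sample.int(spec$n_hc, round(27 / 45 * spec$n_hc)))

  list(f_hc = f_hc, b_hc = b_hc, f_ad = f_ad, b_ad = b_ad, u = u,
       eta = eta, v_own = v_own, miss_ad = miss_ad, miss_hc = miss_hc,
       male_ad = m_ad, male_hc = m_hc, sdb = sdb)
}

# Medial-plane intensity increment of one region for one scan.
region_plane_value <- function(spec, lat, region, group, timepoint, si) {
  ae <- spec$atrophy_effects
  delta <- 0
  if (group == "AD" && region %in% ae$name) {
    row <- ae[ae$name == region, ]
    delta <- if (timepoint == "T1") row$delta_t1 else row$delta_t2
  }
  cl <- spec$covariance_loadings
  l <- 0
  if (nrow(cl)) {
    hit <- cl$group == group & cl$name == region
    if (any(hit)) l <- cl$loading[hit][1]
  }
  f <- if (group == "HC") lat$f_hc[si] else lat$f_ad[si]
  b <- if (group == "HC") lat$b_hc[si, region] else lat$b_ad[si, region]
  prog <- 0
  if (group == "AD" && timepoint == "T2" && region %in% names(spec$progression_sd)) {
    z <- if (region %in% spec$behavior_regions) lat$u[si] else lat$v_own[si, region]
    prog <- spec$progression_sd[[region]] * z
  }
  spec$region_amplitude * (1 - delta) + l * f + b - prog
}

draw_phenotypes <- function(spec, lat) {
  scans <- scan_table(spec)
  n_hc <- spec$n_hc; n_ad <- spec$n_ad

  hc_age <- rtnorm(n_hc, 74.78, 4.95, 66.6, 84.8)
  hc_mmse <- rscore(n_hc, 29.13, 1.25, 24, 30)
  hc_moca <- rscore(n_hc, 24.35, 2.46, 18, 29)
  hc_moca[lat$miss_hc] <- NA_integer_

  ad_age1 <- rtnorm(n_ad, 74.66, 7.23, 56, 88)
  ad_cdr1 <- rtnorm(n_ad, 0.76, 0.32, 0.5, 2)
  ad_cdr2 <- pmin(ad_cdr1 + rtnorm(n_ad, 0.18, 0.34, 0, Inf), 2)
  ad_mmse1 <- rscore(n_ad, 23.1, 2.06, 19, 26)
  ad_mmse2 <- pmin(pmax(round(ad_mmse1 + rnorm(n_ad, -2.1, 3.9)), 0), 30)
  ad_moca1 <- rscore(n_ad, 18.65, 4.62, 11, 27)
  rho <- spec$behavior_coupling
  dmoca <- -2.07 + 3.25 * (rho * (-lat$u) + sqrt(1 - rho^2) * lat$eta)
  ad_moca2 <- pmin(pmax(round(ad_moca1 + dmoca), 0), 30)
  ad_moca2[lat$miss_ad] <- NA_integer_

  sex_hc <- ifelse(seq_len(n_hc) %in% lat$male_hc, "M", "F")
  sex_ad <- ifelse(seq_len(n_ad) %in% lat$male_ad, "M", "F")

  is_hc <- scans$group == "HC"
  t2 <- scans$timepoint == "T2"
  si <- scans$subj_index
  data.frame(
    subject_id = scans$subject_id,
    group = scans$group,
    timepoint = scans$timepoint,
    sex = ifelse(is_hc, sex_hc[si], sex_ad[si]),
    age = ifelse(is_hc, hc_age[si], ifelse(t2, ad_age1[si] + 1.07, ad_age1[si])),
    CDR = ifelse(is_hc, 0, ifelse(t2, ad_cdr2[si], ad_cdr1[si])),
    MMSE = ifelse(is_hc, hc_mmse[si], ifelse(t2, ad_mmse2[si], ad_mmse1[si])),
    MoCA = ifelse(is_hc, hc_moca[si], ifelse(t2, ad_moca2[si], ad_moca1[si])),
    stringsAsFactors = FALSE
  )
}

region_sphere_masks <- function(spec) {
  dimv <- spec$grid_shape
  ax <- seq_len(dimv[1]); ay <- seq_len(dimv[2]); az <- seq_len(dimv[3])
  rd <- spec$region_definitions
  masks <- vector("list", nrow(rd))
  names(masks) <- rd$name
  for (r in seq_len(nrow(rd))) {
    dx2 <- (ax - rd$cx[r])^2
    dy2 <- (ay - rd$cy[r])^2
    dz2 <- (az - rd$cz[r])^2
    d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
    masks[[r]] <- d2 <= rd$radius[r]^2
  }
  masks
}

planted_truth <- function(spec, masks, lat) {
  rd <- spec$region_definitions
  ae <- spec$atrophy_effects
  gm <- do.call(rbind, lapply(rd$name, function(rn) {
    d1 <- d2 <- 0
    if (rn %in% ae$name) {
      d1 <- ae$delta_t1[ae$name == rn]; d2 <- ae$delta_t2[ae$name == rn]
    }
    A <- spec$region_amplitude; s <- spec$slab_amplitude
    data.frame(region = rn,
               group = c("HC", "AD", "AD"),
               timepoint = c("T1", "T1", "T2"),
               mean = c(s + A, s + A * (1 - d1), s + A * (1 - d2)),
               stringsAsFactors = FALSE)
  }))
  # implied inter-regional correlation per group from loadings/intercept SDs
  implied_r <- function(group, r1, r2) {
    cl <- spec$covariance_loadings
    l <- function(rn) {
      if (!nrow(cl)) return(0)
      hit <- cl$group == group & cl$name == rn
      if (any(hit)) cl$loading[hit][1] else 0
    }
    sb <- function(rn) lat$sdb[[rn]]
    num <- l(r1) * l(r2)
    num / sqrt((l(r1)^2 + sb(r1)^2) * (l(r2)^2 + sb(r2)^2))
  }
  pairs <- utils::combn(rd$name, 2)
  edges <- data.frame(region1 = pairs[1, ], region2 = pairs[2, ],
                      r_HC = NA_real_, r_AD = NA_real_,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(edges))) {
    edges$r_HC[i] <- implied_r("HC", edges$region1[i], edges$region2[i])
    edges$r_AD[i] <- implied_r("AD", edges$region1[i], edges$region2[i])
  }
  diff_edges <- edges[abs(edges$r_HC - edges$r_AD) > 0.2, , drop = FALSE]
  rownames(diff_edges) <- NULL
  list(true_region_masks = masks,
       region_table = rd,
       true_group_means = gm,
       true_cov_difference_edges = diff_edges,
       true_behavior_r = spec$behavior_coupling,
       slab_plane = spec$slab_plane,
       latents = lat)
}

#' Write a generated cohort to disk
#'
#' Writes volumes as NIfTI-1 (`.nii.gz`) under `dir/volumes/`, phenotypes
#' as `dir/phenotypes.csv` (missing MoCA as empty field), the planted
#' region masks as an integer label image `dir/truth_labels.nii.gz`, and a
#' JSON manifest `dir/truth.json` (region table, group means, covariance
#' edges, behaviour coupling, slab plane).
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "gm_cohort"))
  vdir <- file.path(dir, "volumes")
  dir.create(vdir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(cohort$volumes))
    write_volume(cohort$volumes[[nm]], file.path(vdir, paste0(nm, ".nii.gz")))
  utils::write.csv(cohort$phenotypes, file.path(dir, "phenotypes.csv"),
                   row.names = FALSE, na = "")
  tr <- cohort$truth
  lab <- array(0L, dim(tr$true_region_masks[[1]]))
  for (i in seq_along(tr$true_region_masks))
    lab[tr$true_region_masks[[i]]] <- i
  attr(lab, "pixdim") <- rep(cohort$spec$voxel_size_mm, 3)
  RNifti::writeNifti(RNifti::asNifti(lab, datatype = "int16"),
                     file.path(dir, "truth_labels.nii.gz"))
  manifest <- list(
    regions = tr$region_table,
    label_order = names(tr$true_region_masks),
    true_group_means = tr$true_group_means,
    true_cov_difference_edges = tr$true_cov_difference_edges,
    true_behavior_r = tr$true_behavior_r,
    slab_plane = tr$slab_plane,
    seed = cohort$spec$seed
  )
  jsonlite::write_json(manifest, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' @export
print.gm_cohort <- function(x, ...) {
  cat("<gm_cohort> ", length(x$volumes), " scans (",
      x$spec$n_hc, " HC, ", x$spec$n_ad, " AD x 2 timepoints), grid ",
      paste(x$spec$grid_shape, collapse = "x"), "\n", sep = "")
  invisible(x)
}
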