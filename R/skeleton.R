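#' Voxelwise mean image across scans
#'
#' Arithmetic mean of all supplied volumes (the whole cohort: HC and both
#' AD timepoints), the substrate for skeletonization.
#'
#' @param volumes list of [gm_volume] on one grid.
#' @return A [gm_volume] of voxelwise means.
#' @export
mean_image <- function(volumes) {
  if (length(volumes) < 1)
    stop_gm("mean_image: need at least one volume", class = "gmprog_validation_error")
  check_same_grid(lapply(volumes, function(v) dim(v$data)))
  acc <- Reduce(`+`, lapply(volumes, `[[`, "data"))
  gm_volume(acc / length(volumes), voxel_size_mm = volumes[[1]]$voxel_size_mm)
}

# Separable 3D Gaussian smoothing with reflection padding; sigma in voxels
# per axis (zeros skip the axis).
gaussian_smooth_3d <- function(arr, sigma_vox) {
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2)); k <- k / sum(k)
    perm <- c(ax, setdiff(1:3, ax))
    m <- aperm(arr, perm)
    dm <- dim(m)
    m <- matrix(m, dm[1])
    n <- dm[1]
    # reflected row indices for padding
    pidx <- c(rev(seq_len(min(r, n - 1)) + 1L), seq_len(n),
              n - seq_len(min(r, n - 1)))
    if (length(pidx) < n + 2 * r)   # tiny axis: clamp-pad
      pidx <- c(rep(1L, n + 2 * r - length(pidx)), pidx)
    mp <- m[pidx, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k))
      out <- out + k[j] * mp[j:(j + n - 1L), , drop = FALSE]
    arr <- aperm(array(out, dm), order(perm))
  }
  arr
}

# Central-difference second derivatives of a 3D array (unit voxel spacing).
hessian_components <- function(a) {
  d <- dim(a)
  sh <- function(di) {
    # shift array by di (vector of 3), clamp at borders
    ix <- pmin(pmax(seq_len(d[1]) + di[1], 1L), d[1])
    iy <- pmin(pmax(seq_len(d[2]) + di[2], 1L), d[2])
    iz <- pmin(pmax(seq_len(d[3]) + di[3], 1L), d[3])
    a[ix, iy, iz, drop = FALSE]
  }
  list(
    xx = sh(c(1, 0, 0)) + sh(c(-1, 0, 0)) - 2 * a,
    yy = sh(c(0, 1, 0)) + sh(c(0, -1, 0)) - 2 * a,
    zz = sh(c(0, 0, 1)) + sh(c(0, 0, -1)) - 2 * a,
    xy = (sh(c(1, 1, 0)) + sh(c(-1, -1, 0)) - sh(c(1, -1, 0)) - sh(c(-1, 1, 0))) / 4,
    xz = (sh(c(1, 0, 1)) + sh(c(-1, 0, -1)) - sh(c(1, 0, -1)) - sh(c(-1, 0, 1))) / 4,
    yz = (sh(c(0, 1, 1)) + sh(c(0, -1, -1)) - sh(c(0, 1, -1)) - sh(c(0, -1, 1))) / 4
  )
}

# Trilinear interpolation of a at points (n x 3, 1-based voxel coords).
trilinear <- function(a, pts) {
  d <- dim(a)
  px <- pmin(pmax(pts[, 1], 1), d[1])
  py <- pmin(pmax(pts[, 2], 1), d[2])
  pz <- pmin(pmax(pts[, 3], 1), d[3])
  x0 <- pmin(floor(px), d[1] - 1); y0 <- pmin(floor(py), d[2] - 1)
  z0 <- pmin(floor(pz), d[3] - 1)
  fx <- px - x0; fy <- py - y0; fz <- pz - z0
  gidx <- function(x, y, z) (z - 1) * d[1] * d[2] + (y - 1) * d[1] + x
  v000 <- a[gidx(x0, y0, z0)];     v100 <- a[gidx(x0 + 1, y0, z0)]
  v010 <- a[gidx(x0, y0 + 1, z0)]; v110 <- a[gidx(x0 + 1, y0 + 1, z0)]
  v001 <- a[gidx(x0, y0, z0 + 1)]; v101 <- a[gidx(x0 + 1, y0, z0 + 1)]
  v011 <- a[gidx(x0, y0 + 1, z0 + 1)]; v111 <- a[gidx(x0 + 1, y0 + 1, z0 + 1)]
  (v000 * (1 - fx) + v100 * fx) * (1 - fy) * (1 - fz) +
  (v010 * (1 - fx) + v110 * fx) * fy * (1 - fz) +
  (v001 * (1 - fx) + v101 * fx) * (1 - fy) * fz +
  (v011 * (1 - fx) + v111 * fx) * fy * fz
}

#' Build the cortical skeleton from a mean GM map
#'
#' Extracts a one-voxel-thick medial surface ("cortical skeleton") from the
#' cohort-mean grey-matter map. The map is smoothed with an isotropic
#' Gaussian; a voxel is kept if it exceeds `gm_threshold` on the raw mean
#' map and is a local maximum of the smoothed map along the direction of
#' strongest negative curvature (the unit eigenvector of the local Hessian
#' belonging to its most negative eigenvalue). On a plate-like structure
#' that direction is the through-thickness axis, so the criterion selects
#' the centre of the cortical plate.
#'
#' `method = "thinning"` applies the same ridge criterion to a chamfer
#' distance transform of the thresholded mask instead of the smoothed
#' intensities (a classical medial-axis construction), useful for maps
#' whose intensity profile carries no through-thickness gradient.
#'
#' @param mean_map [gm_volume], the cohort mean (see [mean_image()]).
#' @param gm_threshold grey-matter inclusion threshold in (0, 1);
#'   default 0.2.
#' @param smoothing_sigma_mm Gaussian sigma in mm; default 2.
#' @param method `"ridge"` (default) or `"thinning"`.
#' @return A `skeleton_model`: list with `mean_map`, `skeleton_mask`
#'   (logical 3D array), `voxel_index` (sorted linear indices fixing the
#'   sampling order shared by all subjects), `gm_threshold`,
#'   `smoothing_sigma_mm`, `method`.
#' @export
skeletonize <- function(mean_map, gm_threshold = 0.2, smoothing_sigma_mm = 2,
                        method = c("ridge", "thinning")) {
  method <- match.arg(method)
  stopifnot(inherits(mean_map, "gm_volume"))
  if (gm_threshold <= 0 || gm_threshold >= 1)
    stop_gm("skeletonize: gm_threshold must lie in (0, 1)",
            class = "gmprog_validation_error")
  a <- mean_map$data
  mask <- a >= gm_threshold
  if (!any(mask))
    stop_gm("skeletonize: thresholded mask is empty (degenerate input)",
            class = "gmprog_degenerate_error")
  sigma_vox <- smoothing_sigma_mm / mean_map$voxel_size_mm
  field <- if (method == "ridge") {
    gaussian_smooth_3d(a, sigma_vox)
  } else {
    gaussian_smooth_3d(chamfer_distance(mask), pmin(sigma_vox, 1))
  }
  keep <- ridge_voxels(field, mask)
  skel <- array(FALSE, dim(a))
  skel[keep] <- TRUE
  structure(list(mean_map = mean_map, skeleton_mask = skel,
                 voxel_index = sort(keep),
                 gm_threshold = gm_threshold,
                 smoothing_sigma_mm = smoothing_sigma_mm,
                 method = method),
            class = "skeleton_model")
}

# Voxels in `mask` that are local maxima of `field` along the dominant
# negative-curvature eigendirection of the local Hessian.
ridge_voxels <- function(field, mask) {
  d <- dim(field)
  H <- hessian_components(field)
  idx <- which(mask)
  ijk <- index_to_ijk(idx, d)
  n <- length(idx)
  dirs <- matrix(0, n, 3)
  lam <- numeric(n)
  for (i in seq_len(n)) {
    v <- idx[i]
    Hm <- matrix(c(H$xx[v], H$xy[v], H$xz[v],
                   H$xy[v], H$yy[v], H$yz[v],
                   H$xz[v], H$yz[v], H$zz[v]), 3, 3)
    e <- eigen(Hm, symmetric = TRUE)
    lam[i] <- e$values[3]          # most negative eigenvalue
    dirs[i, ] <- e$vectors[, 3]
  }
  curved <- lam < -1e-10
  ctr <- field[idx]
  up <- trilinear(field, ijk + dirs)
  dn <- trilinear(field, ijk - dirs)
  tol <- 1e-12
  idx[curved & ctr >= up - tol & ctr >= dn - tol]
}

# City-block chamfer distance to the mask complement (0 outside the mask).
chamfer_distance <- function(mask) {
  d <- dim(mask)
  if (all(mask)) return(array(1, d))   # no boundary: flat field
  dist <- array(0, d)
  dist[mask] <- Inf
  shift1 <- function(a, ax, by) {
    ix <- lapply(d, seq_len)
    src <- ix
    src[[ax]] <- pmin(pmax(src[[ax]] + by, 1L), d[ax])
    a[src[[1]], src[[2]], src[[3]], drop = FALSE]
  }
  repeat {
    nb <- pmin(pmin(shift1(dist, 1, 1L), shift1(dist, 1, -1L)),
               pmin(pmin(shift1(dist, 2, 1L), shift1(dist, 2, -1L)),
                    pmin(shift1(dist, 3, 1L), shift1(dist, 3, -1L))))
    new <- pmin(dist, nb + 1)
    new[!mask] <- 0
    if (identical(new, dist)) break
    dist <- new
  }
  dist
}

#' Sample a subject volume on the skeleton
#'
#' Extracts per-skeleton-voxel GMV values in the model's fixed voxel order
#' (sorted linear index), identical for every subject, yielding comparable
#' voxelwise vectors.
#'
#' @param volume [gm_volume] on the model's grid.
#' @param model a `skeleton_model` from [skeletonize()].
#' @return Numeric vector, one value per skeleton voxel.
#' @export
sample_on_skeleton <- function(volume, model) {
  stopifnot(inherits(volume, "gm_volume"), inherits(model, "skeleton_model"))
  check_same_grid(list(dim(volume$data), dim(model$skeleton_mask)),
                  "volume vs skeleton")
  volume$data[model$voxel_index]
}

#' @export
print.skeleton_model <- function(x, ...) {
  cat("<skeleton_model> ", length(x$voxel_index), " skeleton voxels (method ",
      x$method, ", threshold ", x$gm_threshold, ", sigma ",
      x$smoothing_sigma_mm, " mm)\n", sep = "")
  invisible(x)
}
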