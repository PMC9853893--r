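#' Total GMV on the skeleton
#'
#' Sum of a subject's GMV over all skeleton voxels, times the voxel volume
#' — a global atrophy summary in mm^3.
#'
#' @param volume [gm_volume].
#' @param model `skeleton_model`.
#' @return Total skeleton GMV in mm^3.
#' @export
total_gmv <- function(volume, model) {
  sum(sample_on_skeleton(volume, model)) * voxel_volume_mm3(volume)
}

new_statmap <- function(statistic, p, df, contrast, model, n_zero_variance) {
  structure(list(statistic = statistic, p = p, q = fdr_bh(p), df = df,
                 contrast = contrast, voxel_index = model$voxel_index,
                 dim = dim(model$skeleton_mask),
                 n_zero_variance = n_zero_variance),
            class = "gm_statmap")
}

#' Voxelwise two-sample t map on the skeleton
#'
#' Student t test with pooled variance at every skeleton voxel; `t` is
#' signed as `mean(A) - mean(B)`, so atrophy in A relative to B appears as
#' negative t. Two-tailed p values; Benjamini-Hochberg q values are
#' attached. Voxels with zero pooled variance get `t = 0, p = 1` and are
#' counted in `n_zero_variance` (reported with a warning).
#'
#' @param groupA,groupB numeric matrices, skeleton voxels x subjects (see
#'   [sample_on_skeleton()]), at least 3 subjects each.
#' @param model the `skeleton_model` the vectors were sampled on.
#' @param contrast label stored in the result (e.g. `"ADT1_vs_HC"`).
#' @return A `gm_statmap`: `statistic`, `p`, `q`, `df`, `contrast`, the
#'   skeleton voxel index, and `n_zero_variance`.
#' @export
two_sample_t_map <- function(groupA, groupB, model, contrast = "A_vs_B") {
  groupA <- as.matrix(groupA); groupB <- as.matrix(groupB)
  n1 <- ncol(groupA); n2 <- ncol(groupB)
  if (n1 < 3 || n2 < 3)
    stop_gm("two_sample_t_map: each group needs >= 3 subjects (got ",
            n1, ", ", n2, ")", class = "gmprog_insufficient_data_error")
  if (nrow(groupA) != nrow(groupB))
    stop_gm("two_sample_t_map: voxel vector lengths differ",
            class = "gmprog_shape_error")
  m1 <- rowMeans(groupA); m2 <- rowMeans(groupB)
  v1 <- rowSums((groupA - m1)^2) / (n1 - 1)
  v2 <- rowSums((groupB - m2)^2) / (n2 - 1)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  zero <- se == 0
  tt <- ifelse(zero, 0, (m1 - m2) / se)
  p <- ifelse(zero, 1, 2 * pt(-abs(tt), df))
  if (any(zero))
    warning(sum(zero), " voxel(s) with zero pooled variance set to p = 1 [",
            contrast, "]")
  new_statmap(tt, p, df, contrast, model, sum(zero))
}

#' Voxelwise paired t map on the skeleton
#'
#' Paired t test on within-subject differences T2 - T1 at every skeleton
#' voxel. Columns are matched by subject id; a broken pairing (subjects
#' present at only one timepoint) is an error listing the offenders.
#' Zero-variance differences get `p = 1` with a warning.
#'
#' @param vectors_t1,vectors_t2 matrices, skeleton voxels x subjects.
#' @param subjects_t1,subjects_t2 subject ids for the columns.
#' @inheritParams two_sample_t_map
#' @return A `gm_statmap` with `df = n_pairs - 1` and t signed as T2 - T1.
#' @export
paired_t_map <- function(vectors_t1, vectors_t2, subjects_t1, subjects_t2,
                         model, contrast = "T2_vs_T1_paired") {
  vectors_t1 <- as.matrix(vectors_t1); vectors_t2 <- as.matrix(vectors_t2)
  bad <- c(setdiff(subjects_t1, subjects_t2), setdiff(subjects_t2, subjects_t1))
  if (length(bad) || anyDuplicated(subjects_t1) || anyDuplicated(subjects_t2))
    stop_gm("paired_t_map: broken pairing for subjects: ",
            paste(unique(c(bad, subjects_t1[duplicated(subjects_t1)],
                           subjects_t2[duplicated(subjects_t2)])),
                  collapse = ", "),
            class = "gmprog_pairing_error")
  n <- length(subjects_t1)
  if (n < 3)
    stop_gm("paired_t_map: need >= 3 pairs", class = "gmprog_insufficient_data_error")
  vectors_t2 <- vectors_t2[, match(subjects_t1, subjects_t2), drop = FALSE]
  D <- vectors_t2 - vectors_t1
  md <- rowMeans(D)
  sd_d <- sqrt(rowSums((D - md)^2) / (n - 1))
  zero <- sd_d == 0
  tt <- ifelse(zero, 0, md / (sd_d / sqrt(n)))
  p <- ifelse(zero, 1, 2 * pt(-abs(tt), n - 1))
  if (any(zero))
    warning(sum(zero), " voxel(s) with zero difference variance set to p = 1 [",
            contrast, "]")
  new_statmap(tt, p, n - 1, contrast, model, sum(zero))
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity;
#' thresholding the returned q values at a level alpha reproduces the
#' classic BH step-up rejection set exactly.
#'
#' @param p numeric vector of p values in \[0, 1\].
#' @return Vector of adjusted (q) values, same order as `p`.
#' @export
fdr_bh <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop_gm("fdr_bh: p values must lie in [0, 1]",
            class = "gmprog_validation_error")
  p.adjust(p, method = "BH")
}

#' @export
print.gm_statmap <- function(x, ...) {
  cat("<gm_statmap> ", x$contrast, ": ", length(x$statistic),
      " skeleton voxels, df = ", x$df,
      ", min q = ", signif(min(x$q), 3), "\n", sep = "")
  invisible(x)
}

# Connected-component labels (26-connectivity) for a set of voxel linear
# indices on a 3D grid; returns an integer label per input index.
label_components_26 <- function(idx, dim) {
  n <- length(idx)
  if (n == 0) return(integer(0))
  ijk <- index_to_ijk(idx, dim)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[offs$dx != 0 | offs$dy != 0 | offs$dz != 0, ]
  offs <- offs[1:13, ]                      # half the offsets: undirected edges
  from <- integer(0); to <- integer(0)
  for (o in seq_len(nrow(offs))) {
    nijk <- cbind(ijk[, 1] + offs$dx[o], ijk[, 2] + offs$dy[o],
                  ijk[, 3] + offs$dz[o])
    ok <- nijk[, 1] >= 1 & nijk[, 1] <= dim[1] &
          nijk[, 2] >= 1 & nijk[, 2] <= dim[2] &
          nijk[, 3] >= 1 & nijk[, 3] <= dim[3]
    nidx <- ijk_to_index(nijk[ok, , drop = FALSE], dim)
    m <- match(nidx, idx)
    hit <- !is.na(m)
    from <- c(from, which(ok)[hit]); to <- c(to, m[hit])
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  as.integer(igraph::components(g)$membership)
}

new_region_set <- function(voxel_sets, category, dim, statmap = NULL,
                           names = NULL) {
  labels <- array(0L, dim)
  tab <- data.frame(cluster_id = integer(0), name = character(0),
                    size = integer(0), peak_index = integer(0),
                    category = character(0), stringsAsFactors = FALSE)
  for (i in seq_along(voxel_sets)) {
    vx <- voxel_sets[[i]]
    labels[vx] <- i
    peak <- if (!is.null(statmap)) {
      pos <- match(vx, statmap$voxel_index)
      vx[which.max(abs(statmap$statistic[pos]))]
    } else vx[1]
    nm <- if (!is.null(names)) names[i] else paste0(category, "_", i)
    tab <- rbind(tab, data.frame(cluster_id = i, name = nm,
                                 size = length(vx), peak_index = peak,
                                 category = category,
                                 stringsAsFactors = FALSE))
  }
  structure(list(labels = labels, table = tab, category = category,
                 connectivity = 26L), class = "gm_regions")
}

#' @export
print.gm_regions <- function(x, ...) {
  cat("<gm_regions> category '", x$category, "': ", nrow(x$table),
      " cluster(s)\n", sep = "")
  if (nrow(x$table)) print(x$table, row.names = FALSE)
  invisible(x)
}

region_voxels <- function(regions) which(regions$labels > 0)

# Significant voxel indices of a stat map at FDR alpha with the given sign.
significant_voxels <- function(map, alpha, sign = c("neg", "pos", "both")) {
  sign <- match.arg(sign)
  keep <- map$q < alpha
  keep <- switch(sign, neg = keep & map$statistic < 0,
                 pos = keep & map$statistic > 0, both = keep)
  map$voxel_index[keep]
}

cluster_filter <- function(vox, dim, min_cluster_voxels, category,
                           statmap = NULL) {
  lab <- label_components_26(vox, dim)
  sets <- split(vox, lab)
  sets <- sets[vapply(sets, length, 1L) > min_cluster_voxels]  # strict >
  sets <- sets[order(-vapply(sets, length, 1L))]
  new_region_set(unname(sets), category, dim, statmap = statmap)
}

#' Threshold a stat map and extract clusters
#'
#' Keeps skeleton voxels significant at FDR level `alpha` with the
#' requested sign of t, labels 26-connected components, and drops clusters
#' of `min_cluster_voxels` or fewer voxels (strictly greater sizes
#' survive: the default 30 keeps clusters of at least 31 voxels).
#'
#' @param map `gm_statmap`.
#' @param alpha FDR significance level (on q values), default 0.05.
#' @param min_cluster_voxels cluster-extent threshold, default 30.
#' @param sign which tail defines a "hit": `"neg"` (decrease, default),
#'   `"pos"`, or `"both"`.
#' @param category category label stored on the clusters.
#' @return A `gm_regions`: integer label image plus a cluster table
#'   (id, name, size, peak voxel, category).
#' @export
threshold_and_cluster <- function(map, alpha = 0.05, min_cluster_voxels = 30,
                                  sign = c("neg", "pos", "both"),
                                  category = "progressive") {
  stopifnot(inherits(map, "gm_statmap"))
  vox <- significant_voxels(map, alpha, sign)
  cluster_filter(vox, map$dim, min_cluster_voxels, category, statmap = map)
}

#' Overlapped decrease areas
#'
#' Voxels showing significant GMV decrease in *both* the AD-T1 vs HC and
#' AD-T2 vs HC maps (voxelwise intersection of the two thresholded
#' decrease maps), cluster-filtered. These are deficits present at both
#' timepoints.
#'
#' @param map_t1_hc,map_t2_hc `gm_statmap`s of AD-T1 minus HC and AD-T2
#'   minus HC on one skeleton.
#' @inheritParams threshold_and_cluster
#' @return A `gm_regions` with category `"overlapped"`.
#' @export
overlapped_regions <- function(map_t1_hc, map_t2_hc, alpha = 0.05,
                               min_cluster_voxels = 30) {
  if (!identical(map_t1_hc$voxel_index, map_t2_hc$voxel_index))
    stop_gm("overlapped_regions: maps are on different skeletons",
            class = "gmprog_shape_error")
  vox <- intersect(significant_voxels(map_t1_hc, alpha, "neg"),
                   significant_voxels(map_t2_hc, alpha, "neg"))
  cluster_filter(vox, map_t1_hc$dim, min_cluster_voxels, "overlapped",
                 statmap = map_t2_hc)
}

#' Continuing decrease areas
#'
#' Operationalizes "a deficit relative to HC that keeps worsening". Under
#' the default `rule = "worsening"`, a voxel is continuing if it shows a
#' significant decrease in AD-T2 vs HC *and* a significant within-subject
#' decline in the paired AD-T2 vs AD-T1 map, and is not already part of an
#' overlapped cluster. `rule = "t2_only"` instead takes voxels significant
#' at T2 vs HC but not at T1 vs HC. Results are cluster-filtered and
#' always disjoint from the overlapped set.
#'
#' @param paired_map paired AD-T2 vs AD-T1 `gm_statmap`.
#' @param rule `"worsening"` (default) or `"t2_only"`.
#' @inheritParams overlapped_regions
#' @return A `gm_regions` with category `"continuing"`.
#' @export
continuing_regions <- function(map_t1_hc, map_t2_hc, paired_map,
                               alpha = 0.05, min_cluster_voxels = 30,
                               rule = c("worsening", "t2_only")) {
  rule <- match.arg(rule)
  if (!identical(map_t1_hc$voxel_index, map_t2_hc$voxel_index) ||
      !identical(map_t1_hc$voxel_index, paired_map$voxel_index))
    stop_gm("continuing_regions: maps are on different skeletons",
            class = "gmprog_shape_error")
  t2 <- significant_voxels(map_t2_hc, alpha, "neg")
  vox <- if (rule == "worsening") {
    intersect(t2, significant_voxels(paired_map, alpha, "neg"))
  } else {
    setdiff(t2, significant_voxels(map_t1_hc, alpha, "neg"))
  }
  ov <- overlapped_regions(map_t1_hc, map_t2_hc, alpha, min_cluster_voxels)
  vox <- setdiff(vox, region_voxels(ov))
  cluster_filter(vox, map_t2_hc$dim, min_cluster_voxels, "continuing",
                 statmap = map_t2_hc)
}
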