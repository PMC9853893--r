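#' Mean GMV per region group and scan
#'
#' For every scan, the mean GMV over the skeleton voxels of each labeled
#' cluster group in one or more `gm_regions` objects — the ROI table that
#' feeds the covariance-network, brain-behaviour and classification
#' stages.
#'
#' @param volumes named list of [gm_volume] (names = scan ids).
#' @param regions a `gm_regions` or a named list of them; each entry
#'   contributes one column per cluster (single-cluster sets contribute a
#'   column named after the list entry; multi-cluster sets append the
#'   cluster name).
#' @param model `skeleton_model`.
#' @return Data frame, rows = scans (rownames = scan ids), columns =
#'   region groups, cells = mean GMV over the region's skeleton voxels.
#' @export
roi_mean_gmv <- function(volumes, regions, model) {
  if (inherits(regions, "gm_regions")) regions <- list(regions)
  if (is.null(names(regions)))
    names(regions) <- vapply(regions, function(r) r$category, "")
  cols <- list()
  for (nm in names(regions)) {
    rg <- regions[[nm]]
    stopifnot(inherits(rg, "gm_regions"))
    if (nrow(rg$table) == 0)
      stop_gm("roi_mean_gmv: region set '", nm, "' is empty",
              class = "gmprog_validation_error")
    check_same_grid(list(dim(rg$labels), dim(model$skeleton_mask)),
                    "regions vs skeleton")
    for (ci in rg$table$cluster_id) {
      vox <- intersect(which(rg$labels == ci), model$voxel_index)
      if (length(vox) == 0)
        stop_gm("roi_mean_gmv: region '", rg$table$name[ci],
                "' has no skeleton voxels", class = "gmprog_validation_error")
      cname <- if (nrow(rg$table) == 1) nm else paste0(nm, ".", rg$table$name[ci])
      cols[[cname]] <- vox
    }
  }
  out <- matrix(NA_real_, length(volumes), length(cols),
                dimnames = list(names(volumes), names(cols)))
  for (i in seq_along(volumes)) {
    check_same_grid(list(dim(volumes[[i]]$data), dim(model$skeleton_mask)))
    for (j in seq_along(cols))
      out[i, j] <- mean(volumes[[i]]$data[cols[[j]]])
  }
  as.data.frame(out)
}

#' Longitudinal change scores for AD subjects
#'
#' One record per AD subject: per-region GMV change (T2 - T1) from the ROI
#' table and MoCA change from the phenotypes; MoCA change is NA when the
#' score is missing at either timepoint. An AD subject lacking either scan
#' is a pairing error.
#'
#' @param roitable ROI table from [roi_mean_gmv()] (rownames
#'   `<subject>_<timepoint>`).
#' @param phenotypes phenotype table.
#' @return Data frame: `subject_id`, `delta_<region>` per ROI column,
#'   `delta_moca`.
#' @export
change_scores <- function(roitable, phenotypes) {
  ad <- phenotypes[phenotypes$group == "AD", , drop = FALSE]
  subj <- unique(ad$subject_id)
  bad <- subj[vapply(subj, function(s) {
    tps <- ad$timepoint[ad$subject_id == s]
    !("T1" %in% tps && "T2" %in% tps)
  }, TRUE)]
  if (length(bad))
    stop_gm("change_scores: AD subjects without paired scans: ",
            paste(bad, collapse = ", "), class = "gmprog_pairing_error")
  id1 <- paste0(subj, "_T1"); id2 <- paste0(subj, "_T2")
  missing_rows <- setdiff(c(id1, id2), rownames(roitable))
  if (length(missing_rows))
    stop_gm("change_scores: ROI table lacks scans: ",
            paste(missing_rows, collapse = ", "), class = "gmprog_pairing_error")
  dg <- as.matrix(roitable[id2, , drop = FALSE]) -
        as.matrix(roitable[id1, , drop = FALSE])
  colnames(dg) <- paste0("delta_", colnames(roitable))
  moca <- function(tp) ad$MoCA[match(paste0(subj, tp), paste0(ad$subject_id, ad$timepoint))]
  out <- data.frame(subject_id = subj, dg, delta_moca = moca("T2") - moca("T1"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' Brain-behaviour correlation
#'
#' Pearson correlation between per-subject GMV change in one region and
#' MoCA change, on complete cases; the two-tailed p value comes from the t
#' transform with `df = n - 2`.
#'
#' @param records change-score table from [change_scores()].
#' @param region ROI column name (without the `delta_` prefix).
#' @return List `r`, `p`, `n`, `df`.
#' @export
brain_behavior_correlation <- function(records, region) {
  col <- paste0("delta_", region)
  if (!col %in% names(records))
    stop_gm("brain_behavior_correlation: no region column '", region, "'",
            class = "gmprog_validation_error")
  ok <- !is.na(records[[col]]) & !is.na(records$delta_moca)
  n <- sum(ok)
  if (n < 4)
    stop_gm("brain_behavior_correlation: need >= 4 complete pairs (got ",
            n, ")", class = "gmprog_insufficient_data_error")
  r <- stats::cor(records[[col]][ok], records$delta_moca[ok])
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tt), n - 2), n = n, df = n - 2)
}

#' Match discovered clusters to named ground-truth regions
#'
#' Splits a multi-cluster `gm_regions` into single-cluster sets named
#' after the planted region each cluster best overlaps (Dice against the
#' truth masks restricted to the skeleton). Used to give synthetic
#' clusters their anatomical names; clusters matching no truth mask keep
#' their generic name.
#'
#' @param regions `gm_regions`.
#' @param truth_masks named list of 3D logical arrays.
#' @param model `skeleton_model` (masks are compared on the skeleton).
#' @param min_dice minimum Dice to accept a match (default 0.1).
#' @return Named list of single-cluster `gm_regions`.
#' @export
match_regions_to_truth <- function(regions, truth_masks, model,
                                   min_dice = 0.1) {
  out <- list()
  for (ci in regions$table$cluster_id) {
    vox <- which(regions$labels == ci)
    best <- NA_character_; bestd <- min_dice
    for (nm in names(truth_masks)) {
      tv <- intersect(which(truth_masks[[nm]]), model$voxel_index)
      d <- 2 * length(intersect(vox, tv)) / (length(vox) + length(tv))
      if (!is.na(d) && d >= bestd) { best <- nm; bestd <- d }
    }
    nm_out <- if (is.na(best)) regions$table$name[ci] else best
    rs <- new_region_set(list(vox), regions$category, dim(regions$labels),
                         names = nm_out)
    out[[nm_out]] <- rs
  }
  out
}
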