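#' Configure an end-to-end pipeline run
#'
#' Collects every tunable of the analysis in one validated object. In
#' synthetic mode (`spec` given) the cohort is generated; otherwise
#' `volume_dir` + `phenotype_csv` are loaded with [load_cohort()].
#'
#' @param spec a [cohort_spec()] for synthetic mode, or `NULL`.
#' @param volume_dir,phenotype_csv input paths for data mode.
#' @param alpha voxelwise FDR level (default 0.05).
#' @param min_cluster_voxels cluster-extent threshold (default 30; strict,
#'   so surviving clusters have >= 31 voxels).
#' @param n_perm SCN permutation count (default 10000).
#' @param n_resamples causal bootstrap count (default 10000).
#' @param svm_cost linear-SVM cost C (default 1).
#' @param gm_threshold,smoothing_sigma_mm,skeleton_method passed to
#'   [skeletonize()].
#' @param continuing_rule passed to [continuing_regions()].
#' @param seed_covnet,seed_causal per-stage RNG seeds.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(spec = NULL, volume_dir = NULL,
                            phenotype_csv = NULL,
                            alpha = 0.05, min_cluster_voxels = 30,
                            n_perm = 10000, n_resamples = 10000,
                            svm_cost = 1,
                            gm_threshold = 0.2, smoothing_sigma_mm = 2,
                            skeleton_method = "ridge",
                            continuing_rule = "worsening",
                            seed_covnet = 1001, seed_causal = 2001) {
  if (is.null(spec) && (is.null(volume_dir) || is.null(phenotype_csv)))
    stop_gm("pipeline_config: give either 'spec' or 'volume_dir' + 'phenotype_csv'",
            class = "gmprog_validation_error")
  if (alpha <= 0 || alpha >= 1)
    stop_gm("pipeline_config: alpha must lie in (0, 1)",
            class = "gmprog_validation_error")
  for (nm in c("min_cluster_voxels", "n_perm", "n_resamples", "svm_cost")) {
    v <- get(nm)
    if (!is.finite(v) || v <= 0)
      stop_gm("pipeline_config: ", nm, " must be positive",
              class = "gmprog_validation_error")
  }
  structure(list(spec = spec, volume_dir = volume_dir,
                 phenotype_csv = phenotype_csv, alpha = alpha,
                 min_cluster_voxels = min_cluster_voxels, n_perm = n_perm,
                 n_resamples = n_resamples, svm_cost = svm_cost,
                 gm_threshold = gm_threshold,
                 smoothing_sigma_mm = smoothing_sigma_mm,
                 skeleton_method = skeleton_method,
                 continuing_rule = continuing_rule,
                 seed_covnet = seed_covnet, seed_causal = seed_causal),
            class = "pipeline_config")
}

#' Combine region sets into one disjoint label image
#'
#' Merges several `gm_regions` into a single label image in which every
#' voxel carries at most one category; earlier sets take precedence, later
#' sets lose any voxels already claimed.
#'
#' @param region_sets named list of `gm_regions`, in precedence order.
#' @return A `gm_regions` whose table keeps the source category per
#'   cluster; categories are mutually disjoint voxel sets.
#' @export
combine_region_sets <- function(region_sets) {
  stopifnot(length(region_sets) >= 1)
  dimv <- dim(region_sets[[1]]$labels)
  claimed <- integer(0)
  sets <- list(); cats <- character(0); nms <- character(0)
  for (nm in names(region_sets)) {
    rg <- region_sets[[nm]]
    for (ci in rg$table$cluster_id) {
      vox <- setdiff(which(rg$labels == ci), claimed)
      if (length(vox) == 0) next
      claimed <- c(claimed, vox)
      sets[[length(sets) + 1]] <- vox
      cats <- c(cats, rg$table$category[rg$table$cluster_id == ci])
      nms <- c(nms, paste0(nm, ".", rg$table$name[rg$table$cluster_id == ci]))
    }
  }
  out <- new_region_set(sets, "combined", dimv, names = nms)
  out$table$category <- cats
  out
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_gm("pipeline stage '", name, "' failed: ", conditionMessage(e),
            class = "gmprog_stage_error")
  })
}

#' Run the full progressive-atrophy pipeline
#'
#' Executes all stages in order — cohort, skeleton, voxelwise group
#' statistics, region derivation, ROI extraction, brain-behaviour
#' correlation, structural covariance network, cross-lagged causal
#' effects, and LOOCV linear-SVM classification — and returns one classed
#' report object. A rerun with the same config (and seeds) reproduces all
#' numbers exactly; any stage failure aborts with the stage name.
#'
#' @param config a [pipeline_config()].
#' @return A `gmprog_report` with components `demographics`, `total_gmv`,
#'   `statmaps`, `regions`, `seed_regions`, `combined_regions`,
#'   `roitable`, `changes`, `behavior`, `edges`, `causal`,
#'   `classification`, `config`, `seeds`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))

  cohort <- run_stage("cohort", {
    if (!is.null(config$spec)) generate_cohort(config$spec)
    else {
      lc <- load_cohort(config$volume_dir, config$phenotype_csv)
      structure(list(volumes = lc$volumes, phenotypes = lc$phenotypes,
                     truth = NULL, spec = NULL), class = "gm_cohort")
    }
  })
  phen <- cohort$phenotypes
  scan_id <- paste0(phen$subject_id, "_", phen$timepoint)
  grp_ids <- list(HC   = scan_id[phen$group == "HC"],
                  ADT1 = scan_id[phen$group == "AD" & phen$timepoint == "T1"],
                  ADT2 = scan_id[phen$group == "AD" & phen$timepoint == "T2"])

  demographics <- run_stage("demographics", cohort_demographic_tests(phen))

  model <- run_stage("skeleton", {
    skeletonize(mean_image(cohort$volumes),
                gm_threshold = config$gm_threshold,
                smoothing_sigma_mm = config$smoothing_sigma_mm,
                method = config$skeleton_method)
  })

  samp <- run_stage("sampling", {
    m <- vapply(cohort$volumes, sample_on_skeleton,
                numeric(length(model$voxel_index)), model = model)
    colnames(m) <- names(cohort$volumes)
    m
  })

  tot <- run_stage("total_gmv", {
    tg <- vapply(cohort$volumes, total_gmv, 0, model = model)
    per_scan <- data.frame(scan_id = names(tg), group = phen$group,
                           timepoint = phen$timepoint, total_gmv_mm3 = unname(tg),
                           stringsAsFactors = FALSE)
    hc <- tg[grp_ids$HC]; a1 <- tg[grp_ids$ADT1]; a2 <- tg[grp_ids$ADT2]
    tests <- data.frame(
      comparison = c("HC_vs_ADT1", "HC_vs_ADT2", "ADT1_vs_ADT2_paired"),
      p = c(stats::t.test(hc, a1)$p.value,
            stats::t.test(hc, a2)$p.value,
            stats::t.test(a1, a2, paired = TRUE)$p.value),
      stringsAsFactors = FALSE)
    list(per_scan = per_scan, tests = tests,
         group_means = c(HC = mean(hc), ADT1 = mean(a1), ADT2 = mean(a2)))
  })

  maps <- run_stage("voxelstats", {
    ad_subj <- sub("_T1$", "", grp_ids$ADT1)
    list(
      t1_hc = two_sample_t_map(samp[, grp_ids$ADT1], samp[, grp_ids$HC],
                               model, "ADT1_vs_HC"),
      t2_hc = two_sample_t_map(samp[, grp_ids$ADT2], samp[, grp_ids$HC],
                               model, "ADT2_vs_HC"),
      paired = paired_t_map(samp[, grp_ids$ADT1], samp[, grp_ids$ADT2],
                            ad_subj, sub("_T2$", "", grp_ids$ADT2),
                            model, "ADT2_vs_ADT1_paired")
    )
  })

  regions <- run_stage("regions", {
    ov <- overlapped_regions(maps$t1_hc, maps$t2_hc, config$alpha,
                             config$min_cluster_voxels)
    co <- continuing_regions(maps$t1_hc, maps$t2_hc, maps$paired,
                             config$alpha, config$min_cluster_voxels,
                             rule = config$continuing_rule)
    pr <- threshold_and_cluster(maps$paired, config$alpha,
                                config$min_cluster_voxels, "neg",
                                category = "progressive")
    list(overlapped = ov, continuing = co, progressive = pr)
  })

  seed_regions <- run_stage("seed_regions", {
    # overlapped / continuing areas each enter as ONE seed (union of their
    # clusters); progressive clusters enter individually, named after the
    # planted region they recover when ground truth is available
    merge_clusters <- function(rg, nm) {
      new_region_set(list(region_voxels(rg)), rg$category, dim(rg$labels),
                     names = nm)
    }
    sr <- list()
    if (nrow(regions$overlapped$table))
      sr$overlapped <- merge_clusters(regions$overlapped, "overlapped")
    if (nrow(regions$continuing$table))
      sr$continuing <- merge_clusters(regions$continuing, "continuing")
    if (nrow(regions$progressive$table)) {
      pr_named <- if (!is.null(cohort$truth)) {
        match_regions_to_truth(regions$progressive,
                               cohort$truth$true_region_masks, model)
      } else {
        ids <- regions$progressive$table$cluster_id
        setNames(lapply(ids, function(ci) {
          new_region_set(list(which(regions$progressive$labels == ci)),
                         "progressive", dim(regions$progressive$labels),
                         names = regions$progressive$table$name[ci])
        }), regions$progressive$table$name)
      }
      pr_named <- pr_named[setdiff(names(pr_named), names(sr))]
      sr <- c(sr, pr_named)
    }
    sr
  })

  combined <- run_stage("combine_regions", {
    keep <- regions[vapply(regions, function(r) nrow(r$table) > 0, TRUE)]
    if (length(keep)) combine_region_sets(keep) else NULL
  })

  roitable <- run_stage("roi", roi_mean_gmv(cohort$volumes, seed_regions, model))

  changes <- run_stage("change_scores", change_scores(roitable, phen))

  behavior <- run_stage("behavior", {
    regs <- intersect(c("STG_left", "STG_right", "caudate_left"),
                      colnames(roitable))
    do.call(rbind, lapply(regs, function(rn) {
      bb <- brain_behavior_correlation(changes, rn)
      data.frame(region = rn, r = bb$r, p = bb$p, n = bb$n, df = bb$df,
                 stringsAsFactors = FALSE)
    }))
  })

  edges <- run_stage("covnet", {
    rbind(
      cbind(comparison = "HC_vs_ADT1",
            scn_edge_tests(roitable, grp_ids$HC, grp_ids$ADT1,
                           n_perm = config$n_perm, seed = config$seed_covnet)),
      cbind(comparison = "HC_vs_ADT2",
            scn_edge_tests(roitable, grp_ids$HC, grp_ids$ADT2,
                           n_perm = config$n_perm,
                           seed = config$seed_covnet + 1000))
    )
  })

  causal <- run_stage("causal", {
    if (!"overlapped" %in% colnames(roitable)) return(NULL)
    targets <- intersect(c("continuing", "STG_left", "STG_right", "caudate_left"),
                         colnames(roitable))
    x1 <- roitable[grp_ids$ADT1, "overlapped"]
    res <- lapply(seq_along(targets), function(i) {
      tn <- targets[i]
      causal_effect_resampled(x1, roitable[grp_ids$ADT1, tn],
                              roitable[grp_ids$ADT2, tn],
                              n_resamples = config$n_resamples,
                              seed = config$seed_causal + i - 1)
    })
    names(res) <- targets
    res
  })

  classification <- run_stage("classify", {
    res <- lapply(c("HC_vs_ADT1", "HC_vs_ADT2", "ADT1_vs_ADT2"), function(ct) {
      loocv_linear_svm(build_feature_matrix(roitable, phen, ct),
                       cost = config$svm_cost)
    })
    names(res) <- c("HC_vs_ADT1", "HC_vs_ADT2", "ADT1_vs_ADT2")
    res
  })

  structure(list(
    n_scans = length(cohort$volumes),
    phenotypes = phen,
    demographics = demographics, total_gmv = tot, skeleton = model,
    statmaps = maps, regions = regions, seed_regions = seed_regions,
    combined_regions = combined, roitable = roitable, changes = changes,
    behavior = behavior, edges = edges, causal = causal,
    classification = classification, truth = cohort$truth,
    config = config,
    seeds = list(cohort = if (!is.null(config$spec)) config$spec$seed else NA,
                 covnet = config$seed_covnet, causal = config$seed_causal)
  ), class = "gmprog_report")
}

#' @export
print.gmprog_report <- function(x, ...) {
  cat("<gmprog_report> ", x$n_scans, " scans, ",
      length(x$skeleton$voxel_index), " skeleton voxels\n", sep = "")
  cat("  total GMV means (mm^3): ",
      paste(names(x$total_gmv$group_means),
            sprintf("%.0f", x$total_gmv$group_means),
            sep = "=", collapse = ", "), "\n", sep = "")
  cat("  regions: overlapped ", nrow(x$regions$overlapped$table),
      ", continuing ", nrow(x$regions$continuing$table),
      ", progressive ", nrow(x$regions$progressive$table), "\n", sep = "")
  for (ct in names(x$classification))
    cat("  ", ct, ": accuracy ",
        sprintf("%.1f%%", 100 * x$classification[[ct]]$accuracy), "\n",
        sep = "")
  invisible(x)
}

#' @export
summary.gmprog_report <- function(object, ...) {
  print(object)
  cat("\nDemographic tests:\n")
  print(object$demographics, row.names = FALSE)
  cat("\nTotal-GMV group tests:\n")
  print(object$total_gmv$tests, row.names = FALSE)
  if (!is.null(object$behavior)) {
    cat("\nBrain-behaviour correlations (AD change scores):\n")
    print(object$behavior, row.names = FALSE)
  }
  sig <- object$edges[object$edges$significant, , drop = FALSE]
  cat("\nSCN edges flagged by permutation test: ", nrow(sig), "\n")
  if (nrow(sig)) print(sig, row.names = FALSE)
  if (!is.null(object$causal)) {
    cat("\nCross-lagged effects of overlapped areas at T1:\n")
    for (tn in names(object$causal)) {
      ce <- object$causal[[tn]]
      cat("  -> ", tn, ": coef ", signif(ce$coefficient, 3),
          ", p = ", signif(ce$p, 3), "\n", sep = "")
    }
  }
  invisible(object)
}

#' Write a pipeline report to disk
#'
#' Writes the machine-readable report (`report.json`: config echo, seeds,
#' demographic and total-GMV tests, cluster tables, behaviour
#' correlations, SCN edges, causal effects, classification metrics), the
#' ROI table and change scores as CSV, the t/p/q stat maps and region
#' label images as NIfTI.
#'
#' @param report `gmprog_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "gmprog_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vx <- report$skeleton$voxel_index
  dimv <- dim(report$skeleton$skeleton_mask)
  vs <- report$skeleton$mean_map$voxel_size_mm
  put_nii <- function(vals, path, datatype = "double") {
    a <- array(0, dimv); a[vx] <- vals
    attr(a, "pixdim") <- vs
    RNifti::writeNifti(RNifti::asNifti(a, datatype = datatype),
                       file.path(dir, path))
  }
  for (nm in names(report$statmaps)) {
    m <- report$statmaps[[nm]]
    put_nii(m$statistic, paste0("tmap_", nm, ".nii.gz"))
    put_nii(m$q, paste0("qmap_", nm, ".nii.gz"))
  }
  for (nm in names(report$regions)) {
    rg <- report$regions[[nm]]
    lab <- rg$labels
    attr(lab, "pixdim") <- vs
    RNifti::writeNifti(RNifti::asNifti(lab, datatype = "int16"),
                       file.path(dir, paste0("labels_", nm, ".nii.gz")))
  }
  utils::write.csv(report$roitable, file.path(dir, "roi_table.csv"))
  utils::write.csv(report$changes, file.path(dir, "change_scores.csv"),
                   row.names = FALSE, na = "")
  cluster_tables <- do.call(rbind, lapply(report$regions, `[[`, "table"))
  classif <- lapply(report$classification, function(cl)
    list(accuracy = cl$accuracy, sensitivity = cl$sensitivity,
         specificity = cl$specificity, positive_class = cl$positive_class,
         paired = cl$paired))
  causal <- lapply(report$causal %||% list(), function(ce)
    list(coefficient = ce$coefficient, boot_mean = ce$boot_mean,
         ci = ce$ci, p = ce$p, n_resamples = ce$n_resamples, seed = ce$seed))
  cfg <- report$config
  cfg_echo <- cfg[setdiff(names(cfg), "spec")]
  jsonlite::write_json(list(
    n_scans = report$n_scans,
    config = cfg_echo,
    cohort_seed = report$seeds$cohort,
    seeds = report$seeds,
    demographics = report$demographics,
    total_gmv_tests = report$total_gmv$tests,
    total_gmv_group_means = as.list(report$total_gmv$group_means),
    clusters = cluster_tables,
    behavior = report$behavior,
    edges = report$edges,
    causal = causal,
    classification = classif
  ), file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
     dataframe = "rows")
  invisible(dir)
}
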