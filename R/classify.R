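#' Build the classification feature matrix
#'
#' Rows are the scans belonging to the contrast's two classes; columns are
#' exactly the five region-group features: mean GMV in the overlapped
#' areas, the continuing areas, left STG, right STG, and left caudate.
#' Row order is deterministic (scan id).
#'
#' @param roitable ROI table ([roi_mean_gmv()]) whose columns include the
#'   five feature regions.
#' @param phenotypes phenotype table.
#' @param contrast one of `"HC_vs_ADT1"`, `"HC_vs_ADT2"`,
#'   `"ADT1_vs_ADT2"`.
#' @param features the five feature column names, in order.
#' @return A `gm_features`: list with `x` (matrix, scans x 5), `label`
#'   (factor; positive class = AD, or T2 within AD), `subject_id`,
#'   `contrast`.
#' @export
build_feature_matrix <- function(roitable, phenotypes,
                                 contrast = c("HC_vs_ADT1", "HC_vs_ADT2",
                                              "ADT1_vs_ADT2"),
                                 features = c("overlapped", "continuing",
                                              "STG_left", "STG_right",
                                              "caudate_left")) {
  contrast <- match.arg(contrast)
  missing_f <- setdiff(features, colnames(roitable))
  if (length(missing_f))
    stop_gm("build_feature_matrix: missing region group(s): ",
            paste(missing_f, collapse = ", "),
            class = "gmprog_construction_error")
  scan_id <- paste0(phenotypes$subject_id, "_", phenotypes$timepoint)
  sel <- switch(contrast,
    HC_vs_ADT1 = phenotypes$group == "HC" |
                 (phenotypes$group == "AD" & phenotypes$timepoint == "T1"),
    HC_vs_ADT2 = phenotypes$group == "HC" |
                 (phenotypes$group == "AD" & phenotypes$timepoint == "T2"),
    ADT1_vs_ADT2 = phenotypes$group == "AD")
  ids <- sort(scan_id[sel])
  miss_scan <- setdiff(ids, rownames(roitable))
  if (length(miss_scan))
    stop_gm("build_feature_matrix: ROI table lacks scans: ",
            paste(miss_scan, collapse = ", "),
            class = "gmprog_construction_error")
  x <- as.matrix(roitable[ids, features, drop = FALSE])
  if (any(is.na(x)))
    stop_gm("build_feature_matrix: missing feature values",
            class = "gmprog_construction_error")
  ph <- phenotypes[match(ids, scan_id), ]
  label <- if (contrast == "ADT1_vs_ADT2") {
    factor(ph$timepoint, levels = c("T1", "T2"))
  } else {
    factor(ph$group, levels = c("HC", "AD"))
  }
  structure(list(x = x, label = label, subject_id = ph$subject_id,
                 contrast = contrast,
                 positive_class = levels(label)[2]),
            class = "gm_features")
}

#' @export
print.gm_features <- function(x, ...) {
  cat("<gm_features> ", x$contrast, ": ", nrow(x$x), " scans x ",
      ncol(x$x), " features (", paste(levels(x$label), collapse = " vs "),
      "; positive = ", x$positive_class, ")\n", sep = "")
  invisible(x)
}

#' Leave-one-out cross-validated linear SVM
#'
#' Linear support-vector classification of the two classes in a feature
#' matrix under leave-one-out cross-validation. In each fold the held-out
#' unit is removed, features are standardized on the training rows only
#' (leakage-safe), a linear SVM with cost `cost` is trained, and the
#' held-out unit predicted. With `paired = TRUE` (for the within-subject
#' T1 vs T2 contrast) the fold unit is the *subject*: both of a subject's
#' scans are held out together, so no fold's training set contains the
#' test subject at either timepoint.
#'
#' @param features `gm_features` from [build_feature_matrix()].
#' @param cost SVM cost parameter C (default 1).
#' @param paired hold out subjects (both timepoints) instead of single
#'   scans; defaults to `TRUE` for the `ADT1_vs_ADT2` contrast.
#' @return A `gm_classification`: `accuracy`, `sensitivity`,
#'   `specificity` (positive class = AD, or T2), `confusion`,
#'   `predictions` (per-fold), `positive_class`, `contrast`.
#' @export
loocv_linear_svm <- function(features, cost = 1,
                             paired = features$contrast == "ADT1_vs_ADT2") {
  stopifnot(inherits(features, "gm_features"))
  x <- features$x; y <- features$label
  if (min(table(y)) < 2)
    stop_gm("loocv_linear_svm: each class needs >= 2 members",
            class = "gmprog_insufficient_data_error")
  folds <- if (paired) {
    split(seq_len(nrow(x)), features$subject_id)
  } else {
    as.list(seq_len(nrow(x)))
  }
  pred <- factor(rep(NA, nrow(x)), levels = levels(y))
  for (fold in folds) {
    tr_x <- x[-fold, , drop = FALSE]; tr_y <- y[-fold]
    mu <- colMeans(tr_x); sg <- apply(tr_x, 2, stats::sd)
    sg[sg == 0] <- 1
    tr_s <- sweep(sweep(tr_x, 2, mu), 2, sg, "/")
    te_s <- sweep(sweep(x[fold, , drop = FALSE], 2, mu), 2, sg, "/")
    fit <- e1071::svm(tr_s, tr_y, kernel = "linear", cost = cost,
                      scale = FALSE)
    pred[fold] <- stats::predict(fit, te_s)
  }
  pos <- features$positive_class
  neg <- setdiff(levels(y), pos)
  tp <- sum(pred == pos & y == pos); fn <- sum(pred == neg & y == pos)
  tn <- sum(pred == neg & y == neg); fp <- sum(pred == pos & y == neg)
  structure(list(
    accuracy = (tp + tn) / length(y),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    confusion = matrix(c(tp, fp, fn, tn), 2, 2,
                       dimnames = list(truth = c(pos, neg),
                                       predicted = c(pos, neg))),
    predictions = data.frame(subject_id = features$subject_id,
                             truth = y, predicted = pred,
                             stringsAsFactors = FALSE),
    positive_class = pos, contrast = features$contrast,
    cost = cost, paired = paired
  ), class = "gm_classification")
}

#' @export
print.gm_classification <- function(x, ...) {
  cat("<gm_classification> ", x$contrast, " (LOOCV",
      if (x$paired) ", subject-level folds", "): accuracy ",
      sprintf("%.1f%%", 100 * x$accuracy), ", sensitivity ",
      sprintf("%.1f%%", 100 * x$sensitivity), ", specificity ",
      sprintf("%.1f%%", 100 * x$specificity), "\n", sep = "")
  invisible(x)
}
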