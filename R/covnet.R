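#' Structural covariance edge
#'
#' Pearson correlation across subjects between the mean GMVs of two
#' regions within one group — the strength of one structural covariance
#' network (SCN) edge.
#'
#' @param values1,values2 per-subject mean GMV of the two regions.
#' @return Pearson r.
#' @export
covariance_edge <- function(values1, values2) {
  if (length(values1) != length(values2))
    stop_gm("covariance_edge: length mismatch", class = "gmprog_shape_error")
  if (length(values1) < 4)
    stop_gm("covariance_edge: need >= 4 subjects",
            class = "gmprog_insufficient_data_error")
  if (any(!is.finite(values1)) || any(!is.finite(values2)))
    stop_gm("covariance_edge: non-finite values", class = "gmprog_validation_error")
  if (stats::sd(values1) == 0 || stats::sd(values2) == 0)
    stop_gm("covariance_edge: zero variance in a region",
            class = "gmprog_degenerate_error")
  stats::cor(values1, values2)
}

#' Permutation test of a group difference in SCN edge strength
#'
#' Tests whether an edge's covariance strength differs between two groups.
#' Subjects are pooled and group labels randomly reassigned (preserving
#' group sizes) `n_perm` times; each permutation recomputes
#' `r_A - r_B`. The observed difference is called significant when it
#' falls outside the central 95% of the permutation null (two-tailed), and
#' a permutation p value is reported with the add-one estimator
#' `p = (1 + #(|null| >= |observed|)) / (n_perm + 1)`, which is never
#' exactly zero.
#'
#' @param groupA,groupB two-column matrices (subjects x 2 regions) of mean
#'   GMV per group.
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed recorded in the result.
#' @return A `cov_edge_test`: `r_A`, `r_B`, `observed_diff`,
#'   `null_quantiles` (2.5% / 97.5%), `significant`, `p`, `n_perm`,
#'   `seed`.
#' @export
edge_group_difference <- function(groupA, groupB, n_perm = 10000, seed = 1) {
  groupA <- as.matrix(groupA); groupB <- as.matrix(groupB)
  stopifnot(ncol(groupA) == 2, ncol(groupB) == 2)
  nA <- nrow(groupA); nB <- nrow(groupB)
  if (nA < 4 || nB < 4)
    stop_gm("edge_group_difference: both groups need >= 4 subjects",
            class = "gmprog_insufficient_data_error")
  r_A <- covariance_edge(groupA[, 1], groupA[, 2])
  r_B <- covariance_edge(groupB[, 1], groupB[, 2])
  obs <- r_A - r_B
  pooled <- rbind(groupA, groupB)
  if (stats::sd(pooled[, 1]) == 0 || stats::sd(pooled[, 2]) == 0)
    stop_gm("edge_group_difference: degenerate pooled variance",
            class = "gmprog_degenerate_error")
  set.seed(seed)
  null <- numeric(n_perm)
  n <- nA + nB
  for (i in seq_len(n_perm)) {
    pick <- sample.int(n, nA)
    null[i] <- stats::cor(pooled[pick, 1], pooled[pick, 2]) -
               stats::cor(pooled[-pick, 1], pooled[-pick, 2])
  }
  qs <- stats::quantile(null, c(0.025, 0.975), names = FALSE)
  structure(list(r_A = r_A, r_B = r_B, observed_diff = obs,
                 null_quantiles = qs,
                 significant = obs < qs[1] | obs > qs[2],
                 p = (1 + sum(abs(null) >= abs(obs))) / (n_perm + 1),
                 n_perm = n_perm, seed = seed),
            class = "cov_edge_test")
}

#' @export
print.cov_edge_test <- function(x, ...) {
  cat("<cov_edge_test> r_A = ", signif(x$r_A, 3), ", r_B = ",
      signif(x$r_B, 3), ", diff = ", signif(x$observed_diff, 3),
      ", p = ", signif(x$p, 3),
      if (x$significant) " (outside central 95% of null)" else "",
      " [", x$n_perm, " permutations, seed ", x$seed, "]\n", sep = "")
  invisible(x)
}

#' Cross-lagged causal covariance coefficient
#'
#' The two-timepoint analogue of Granger causality for structural data:
#' the standardized coefficient of the source region's baseline GMV
#' (`x_T1`) in the regression of the target's follow-up GMV (`y_T2`) on
#' the target's own baseline (`y_T1`) and `x_T1`, across paired subjects.
#' A nonzero value means the source's earlier state explains the target's
#' later state beyond the target's own earlier state.
#'
#' @param x_t1 source region mean GMV at baseline, per subject.
#' @param y_t1,y_t2 target region mean GMV at the two timepoints, same
#'   subjects and order.
#' @return Standardized cross-lagged coefficient (real).
#' @export
causal_coefficient <- function(x_t1, y_t1, y_t2) {
  n <- length(x_t1)
  if (length(y_t1) != n || length(y_t2) != n)
    stop_gm("causal_coefficient: length mismatch", class = "gmprog_shape_error")
  if (n < 5)
    stop_gm("causal_coefficient: need >= 5 paired subjects",
            class = "gmprog_insufficient_data_error")
  if (stats::sd(x_t1) == 0 || stats::sd(y_t1) == 0)
    stop_gm("causal_coefficient: zero predictor variance",
            class = "gmprog_degenerate_error")
  if (abs(stats::cor(x_t1, y_t1)) > 0.999)
    stop_gm("causal_coefficient: x_T1 and y_T1 are collinear",
            class = "gmprog_collinearity_error")
  zx <- as.numeric(scale(x_t1)); zy1 <- as.numeric(scale(y_t1))
  if (stats::sd(y_t2) == 0) return(0)
  zy2 <- as.numeric(scale(y_t2))
  X <- cbind(1, zy1, zx)
  beta <- solve(crossprod(X), crossprod(X, zy2))
  unname(beta[3, 1])
}

#' Bootstrap stability of the cross-lagged effect
#'
#' Resamples subjects with replacement `n_resamples` times, recomputing
#' the cross-lagged coefficient each time, and summarizes the resampled
#' distribution: its mean, central 95% interval, and a two-tailed p value
#' against zero, `p = 2 * min(frac <= 0, frac >= 0)` (add-one form, never
#' zero). Resamples in which the regression is degenerate (e.g. collinear
#' after resampling) are redrawn.
#'
#' @inheritParams causal_coefficient
#' @param n_resamples bootstrap draws (default 10000).
#' @param seed RNG seed recorded in the result.
#' @return A `causal_effect`: `coefficient` (full-sample), `boot_mean`,
#'   `ci` (2.5% / 97.5%), `p`, `n_resamples`, `seed`.
#' @export
causal_effect_resampled <- function(x_t1, y_t1, y_t2, n_resamples = 10000,
                                    seed = 1) {
  obs <- causal_coefficient(x_t1, y_t1, y_t2)
  n <- length(x_t1)
  set.seed(seed)
  boot <- numeric(n_resamples)
  for (i in seq_len(n_resamples)) {
    repeat {
      pick <- sample.int(n, n, replace = TRUE)
      b <- tryCatch(causal_coefficient(x_t1[pick], y_t1[pick], y_t2[pick]),
                    gmprog_error = function(e) NULL)
      if (!is.null(b)) break
    }
    boot[i] <- b
  }
  ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE)
  p_le <- (1 + sum(boot <= 0)) / (n_resamples + 1)
  p_ge <- (1 + sum(boot >= 0)) / (n_resamples + 1)
  structure(list(coefficient = obs, boot_mean = mean(boot), ci = ci,
                 p = min(1, 2 * min(p_le, p_ge)),
                 n_resamples = n_resamples, seed = seed),
            class = "causal_effect")
}

#' @export
print.causal_effect <- function(x, ...) {
  cat("<causal_effect> coefficient = ", signif(x$coefficient, 3),
      ", bootstrap mean = ", signif(x$boot_mean, 3),
      ", 95% CI [", signif(x$ci[1], 3), ", ", signif(x$ci[2], 3),
      "], p = ", signif(x$p, 3), " [", x$n_resamples,
      " resamples, seed ", x$seed, "]\n", sep = "")
  invisible(x)
}

#' All SCN edge group-difference tests over a set of regions
#'
#' Convenience wrapper running [edge_group_difference()] for every pair of
#' ROI columns between two groups of scans.
#'
#' @param roitable ROI table ([roi_mean_gmv()]).
#' @param idsA,idsB row names (scan ids) of the two groups.
#' @param n_perm,seed passed to [edge_group_difference()]; the seed is
#'   advanced per edge for independent permutation streams.
#' @return Data frame: `region1, region2, r_A, r_B, diff, p, significant`.
#' @export
scn_edge_tests <- function(roitable, idsA, idsB, n_perm = 10000, seed = 1) {
  cols <- colnames(roitable)
  prs <- utils::combn(cols, 2)
  out <- vector("list", ncol(prs))
  for (i in seq_len(ncol(prs))) {
    a <- as.matrix(roitable[idsA, prs[, i], drop = FALSE])
    b <- as.matrix(roitable[idsB, prs[, i], drop = FALSE])
    et <- edge_group_difference(a, b, n_perm = n_perm, seed = seed + i - 1)
    out[[i]] <- data.frame(region1 = prs[1, i], region2 = prs[2, i],
                           r_A = et$r_A, r_B = et$r_B,
                           diff = et$observed_diff, p = et$p,
                           significant = et$significant,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
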