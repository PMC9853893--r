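# one-voxel skeleton model for scalar t-test checks
voxel_model <- function() plane_model(c(1L, 1L, 1L), 1L)

test_that("total skeleton GMV is sum times voxel volume", {
  mod <- plane_model(c(10L, 10L, 5L), 3L, voxel_size = 2)  # 100-voxel plane
  ones <- gm_volume(array(1, c(10, 10, 5)), 2)
  expect_equal(total_gmv(ones, mod), 100 * 8)
  expect_equal(total_gmv(gm_volume(array(0, c(10, 10, 5)), 2), mod), 0)
})

test_that("pooled two-sample t map matches hand-computed values", {
  mod <- voxel_model()
  A <- matrix(c(1, 2, 3, 4), 1); B <- matrix(c(3, 4, 5, 6), 1)
  m <- two_sample_t_map(A, B, mod)
  # oracle: pooled-variance Student t; s_p^2 = 5/3, se = sqrt(5/6),
  # t = -2/sqrt(5/6) = -2.1909, p = 2*pt(t, 6) = 0.0713
  expect_equal(m$statistic, -2 / sqrt(5 / 6), tolerance = 1e-12)
  expect_equal(m$p, 2 * pt(-2 / sqrt(5 / 6), 6), tolerance = 1e-12)
  expect_equal(m$df, 6)
  # cross-check against the standard implementation
  tt <- t.test(c(1, 2, 3, 4), c(3, 4, 5, 6), var.equal = TRUE)
  expect_equal(m$statistic, unname(tt$statistic))
  expect_equal(m$p, tt$p.value)
  # identical groups: t = 0, p = 1
  m0 <- two_sample_t_map(A, A, mod)
  expect_equal(m0$statistic, 0)
  expect_equal(m0$p, 1)
  # zero pooled variance is flagged, not NaN
  C <- matrix(c(1, 1, 1), 1)
  expect_warning(mz <- two_sample_t_map(C, C, mod), "zero pooled variance")
  expect_equal(mz$p, 1)
  expect_equal(mz$n_zero_variance, 1L)
  expect_error(two_sample_t_map(matrix(1:2, 1), B, mod),
               class = "gmprog_insufficient_data_error")
})

test_that("two-sample t map is antisymmetric in the groups", {
  mod <- plane_model(c(4L, 4L, 1L), 1L)
  set.seed(1)
  A <- matrix(rnorm(16 * 5), 16); B <- matrix(rnorm(16 * 6), 16)
  m1 <- two_sample_t_map(A, B, mod)
  m2 <- two_sample_t_map(B, A, mod)
  expect_equal(m1$statistic, -m2$statistic)
  expect_equal(m1$p, m2$p)
  expect_equal(m1$q, m2$q)
})

test_that("paired t map matches hand computation and validates pairing", {
  mod <- voxel_model()
  t1 <- matrix(c(5, 6, 7), 1); t2 <- t1 + matrix(c(-1, -2, -3), 1)
  subj <- c("a", "b", "c")
  m <- paired_t_map(t1, t2, subj, subj, mod)
  expect_equal(m$statistic, -3.464, tolerance = 1e-3)
  expect_equal(m$p, 0.0742, tolerance = 1e-2)
  expect_equal(m$df, 2)
  # column order follows the pairing, not position
  m2 <- paired_t_map(t1, t2[, c(3, 1, 2), drop = FALSE], subj,
                     c("c", "a", "b"), mod)
  expect_equal(m2$statistic, m$statistic)
  expect_warning(mz <- paired_t_map(t1, t1, subj, subj, mod),
                 "zero difference variance")
  expect_equal(mz$p, 1)
  expect_error(paired_t_map(t1, t2, subj, c("a", "b", "d"), mod), "d",
               class = "gmprog_pairing_error")
})

test_that("BH adjustment equals the brute-force step-up rule", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(1), 1)
  expect_error(fdr_bh(c(0.5, 1.2)), class = "gmprog_validation_error")
  set.seed(7)
  for (i in 1:200) {
    p <- runif(sample(1:12, 1))
    q <- fdr_bh(p)
    expect_true(all(diff(q[order(p)]) >= -1e-12))
    expect_true(all(q >= p - 1e-12))
    for (alpha in c(0.01, 0.05, 0.1, 0.3, 0.7))
      expect_identical(q <= alpha, bh_stepup_reject(p, alpha))
  }
})

# build a stat map by hand: given q values + t signs on a plane model
fake_map <- function(mod, q, tt, contrast = "fake") {
  structure(list(statistic = tt, p = q, q = q, df = 10, contrast = contrast,
                 voxel_index = mod$voxel_index, dim = dim(mod$skeleton_mask),
                 n_zero_variance = 0L), class = "gm_statmap")
}

test_that("cluster extent threshold is strict and uses 26-connectivity", {
  mod <- plane_model(c(20L, 20L, 1L), 1L)
  n <- length(mod$voxel_index)
  q <- rep(1, n); tt <- rep(0, n)
  ijk <- which(mod$skeleton_mask, arr.ind = TRUE)
  # blob A: 31 voxels; blob B: 29 voxels, far apart
  blobA <- which(ijk[, 1] <= 5 & ijk[, 2] <= 7)[1:31]
  blobB <- which(ijk[, 1] >= 14 & ijk[, 2] >= 14)[1:29]
  q[c(blobA, blobB)] <- 0.01; tt[c(blobA, blobB)] <- -5
  rs <- threshold_and_cluster(fake_map(mod, q, tt), alpha = 0.05,
                              min_cluster_voxels = 30)
  expect_equal(nrow(rs$table), 1)
  expect_equal(rs$table$size, 31)
  # no significant voxels -> empty set
  rs0 <- threshold_and_cluster(fake_map(mod, rep(1, n), tt))
  expect_equal(nrow(rs0$table), 0)
  # two blobs touching only at a corner merge under 26-connectivity
  mod3 <- plane_model(c(8L, 8L, 2L), 1L)
  mod3$skeleton_mask[, , 2] <- TRUE
  mod3$voxel_index <- sort(which(mod3$skeleton_mask))
  n3 <- length(mod3$voxel_index)
  q3 <- rep(1, n3); t3 <- rep(-1, n3)
  ijk3 <- index_coords <- which(mod3$skeleton_mask, arr.ind = TRUE)
  corner <- (ijk3[, 1] <= 2 & ijk3[, 2] <= 2 & ijk3[, 3] == 1) |
            (ijk3[, 1] %in% 3:4 & ijk3[, 2] %in% 3:4 & ijk3[, 3] == 2)
  q3[corner] <- 0.001
  rs3 <- threshold_and_cluster(fake_map(mod3, q3, t3), min_cluster_voxels = 1)
  expect_equal(nrow(rs3$table), 1)
  expect_equal(rs3$table$size, 8)
})

test_that("overlapped and continuing region rules behave as defined", {
  mod <- plane_model(c(20L, 20L, 1L), 1L)
  n <- length(mod$voxel_index)
  ijk <- which(mod$skeleton_mask, arr.ind = TRUE)
  left <- ijk[, 1] <= 8            # 160 voxels
  right <- ijk[, 1] >= 12
  both <- ijk[, 2] <= 6            # crosses left and right
  mk <- function(sig) fake_map(mod, ifelse(sig, 0.01, 1),
                               ifelse(sig, -4, 0))
  # disjoint significant sets -> empty overlap
  expect_equal(nrow(overlapped_regions(mk(left), mk(right),
                                       min_cluster_voxels = 1)$table), 0)
  # identical sets -> the set itself
  ov <- overlapped_regions(mk(left), mk(left), min_cluster_voxels = 1)
  expect_setequal(which(ov$labels > 0), mod$voxel_index[left])
  # continuing: worsening rule = T2-sig AND paired-sig minus overlapped
  co <- continuing_regions(mk(left), mk(left | both), mk(both),
                           min_cluster_voxels = 1)
  expect_setequal(which(co$labels > 0), mod$voxel_index[both & !left])
  # paired map empty -> continuing empty
  co0 <- continuing_regions(mk(left), mk(left), mk(rep(FALSE, n)),
                            min_cluster_voxels = 1)
  expect_equal(nrow(co0$table), 0)
  # always disjoint from the overlapped set
  ov2 <- overlapped_regions(mk(left), mk(left | both), min_cluster_voxels = 1)
  expect_length(intersect(which(co$labels > 0), which(ov2$labels > 0)), 0)
  # alternative rule: significant at T2 but not at T1
  co2 <- continuing_regions(mk(left), mk(left | both), mk(rep(FALSE, n)),
                            min_cluster_voxels = 1, rule = "t2_only")
  expect_setequal(which(co2$labels > 0), mod$voxel_index[both & !left])
})

test_that("demographic tests reproduce printed table statistics", {
  phen <- generate_phenotypes(reduced_spec(seed = 21))
  res <- cohort_demographic_tests(phen)
  sex1 <- res[res$variable == "sex" & res$comparison == "HC_vs_ADT1", ]
  expect_equal(round(sex1$p, 2), 0.81)
  expect_equal(round(sex1$statistic, 2), 0.06)
  # Welch from summary statistics reproduces the printed age p value
  w <- welch_from_summary(75.73, 7.25, 40, 74.78, 4.95, 45)
  expect_equal(round(w$p, 2), 0.49)
  # identical groups give p = 1
  w0 <- welch_from_summary(10, 2, 20, 10, 2, 20)
  expect_equal(w0$p, 1)
  expect_error(welch_from_summary(1, 1, 1, 2, 1, 10),
               class = "gmprog_insufficient_data_error")
})

test_that("null cohorts rarely yield any surviving cluster", {
  # voxelwise FDR + cluster-extent calibration under the global null
  n_seeds <- 100
  hits <- vapply(seq_len(n_seeds), function(s) {
    ch <- generate_cohort(null_spec(seed = 1000 + s))
    mod <- skeletonize(mean_image(ch$volumes))
    samp <- vapply(ch$volumes, sample_on_skeleton,
                   numeric(length(mod$voxel_index)), model = mod)
    phen <- ch$phenotypes
    ids <- paste0(phen$subject_id, "_", phen$timepoint)
    hc <- samp[, phen$group == "HC", drop = FALSE]
    a1 <- samp[, phen$group == "AD" & phen$timepoint == "T1", drop = FALSE]
    m <- two_sample_t_map(a1, hc, mod)
    nrow(threshold_and_cluster(m, 0.05, 30, sign = "both")$table) > 0
  }, TRUE)
  expect_lte(mean(hits), 0.05)
})
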