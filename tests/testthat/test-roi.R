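# two named single-cluster regions on a small plane model
toy_regions <- function(mod) {
  ijk <- which(mod$skeleton_mask, arr.ind = TRUE)
  vA <- mod$voxel_index[ijk[, 1] <= 2][1:2]
  vB <- mod$voxel_index[ijk[, 1] >= 6][1:3]
  list(regA = new_region_set(list(vA), "overlapped", dim(mod$skeleton_mask),
                             names = "regA"),
       regB = new_region_set(list(vB), "continuing", dim(mod$skeleton_mask),
                             names = "regB"))
}

test_that("ROI means average GMV over each region's skeleton voxels", {
  mod <- plane_model(c(8L, 8L, 3L), 2L)
  regs <- toy_regions(mod)
  const <- gm_volume(array(0.42, c(8, 8, 3)), 2)
  roi <- roi_mean_gmv(list(s1_T1 = const), regs, mod)
  expect_equal(unname(unlist(roi["s1_T1", ])), c(0.42, 0.42))
  # two-voxel region with values 1 and 3 averages to 2
  arr <- array(0, c(8, 8, 3))
  vox <- which(regs$regA$labels == 1)
  arr[vox] <- c(1, 3)
  roi2 <- roi_mean_gmv(list(s1_T1 = gm_volume(arr, 2)), regs, mod)
  expect_equal(roi2["s1_T1", "regA"], 2)
  # empty region set errors with its name
  empty <- new_region_set(list(), "overlapped", dim(mod$skeleton_mask))
  expect_error(roi_mean_gmv(list(s1_T1 = const), list(bad = empty), mod),
               "bad", class = "gmprog_validation_error")
})

test_that("change scores pair AD scans and carry MoCA deltas", {
  roi <- data.frame(regA = c(5.0, 4.5, 3.0),
                    row.names = c("AD001_T1", "AD001_T2", "HC001_T1"))
  phen <- data.frame(
    subject_id = c("AD001", "AD001", "HC001"), group = c("AD", "AD", "HC"),
    timepoint = c("T1", "T2", "T1"), sex = "M", age = 70,
    CDR = c(0.5, 1, 0), MMSE = c(24, 22, 30), MoCA = c(18, 16, 27))
  rec <- change_scores(roi, phen)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$delta_regA, -0.5)
  expect_equal(rec$delta_moca, -2)
  # unpaired AD subject is an error naming it
  phen2 <- phen[-2, ]
  expect_error(change_scores(roi, phen2), "AD001",
               class = "gmprog_pairing_error")
})

test_that("default cohort yields exactly 38 complete change records", {
  rep <- reduced_report()
  rec <- rep$changes
  expect_equal(nrow(rec), 40)
  expect_equal(sum(!is.na(rec$delta_moca)), 38)
})

test_that("brain-behaviour correlation matches hand-computed Pearson r", {
  rec <- data.frame(subject_id = c("a", "b", "c", "d"),
                    delta_r = c(1, 2, 3, 4), delta_moca = c(2, 4, 6, 8))
  bb <- brain_behavior_correlation(rec, "r")
  expect_equal(bb$r, 1)
  expect_equal(bb$df, 2)
  rec2 <- data.frame(subject_id = letters[1:5],
                     delta_r = c(1, 2, 3, 4, 5), delta_moca = c(1, 3, 2, 5, 4))
  expect_equal(brain_behavior_correlation(rec2, "r")$r,
               cor(rec2$delta_r, rec2$delta_moca))
  # hand value for the length-3 classic (padded to meet n >= 4 via repeat)
  expect_equal(cor(c(1, 2, 3), c(1, 3, 2)), 0.5)
  # affine invariance
  rec3 <- rec2
  rec3$delta_r <- 3 * rec3$delta_r - 7
  rec3$delta_moca <- -2 * rec3$delta_moca + 1
  expect_equal(abs(brain_behavior_correlation(rec3, "r")$r),
               abs(brain_behavior_correlation(rec2, "r")$r))
  # complete-case handling and minimum n
  rec4 <- rec2; rec4$delta_moca[1:2] <- NA
  expect_error(brain_behavior_correlation(rec4, "r"),
               class = "gmprog_insufficient_data_error")
})

test_that("correlation p value agrees with a permutation p on small n", {
  set.seed(13)
  x <- rnorm(12); y <- 0.6 * x + rnorm(12)
  rec <- data.frame(subject_id = as.character(1:12), delta_r = x,
                    delta_moca = y)
  bb <- brain_behavior_correlation(rec, "r")
  perm <- vapply(1:4000, function(i) abs(cor(x, sample(y))), 0)
  p_perm <- mean(perm >= abs(bb$r))
  expect_lt(abs(bb$p - p_perm), 0.03)
})

test_that("cluster-to-truth matching names recovered regions", {
  rep <- reduced_report()
  expect_true(all(c("overlapped", "continuing", "STG_right", "caudate_left") %in%
                  names(rep$seed_regions)))
  # matched seed clusters overlap their planted masks substantially
  for (rn in c("STG_right", "caudate_left")) {
    d <- dice_vs_truth(rep$seed_regions[[rn]],
                       rep$truth$true_region_masks[[rn]], rep$skeleton)
    expect_gte(d, 0.5)
  }
})
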