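test_that("cohort spec validation names the offending field", {
  expect_error(cohort_spec(n_hc = 0), "n_hc", class = "gmprog_validation_error")
  expect_error(cohort_spec(n_ad_with_moca_both = 99), "n_ad_with_moca_both",
               class = "gmprog_validation_error")
  expect_error(cohort_spec(noise_sd = 0), "noise_sd",
               class = "gmprog_validation_error")
  expect_error(
    cohort_spec(atrophy_effects = data.frame(name = "overlapped",
                                             delta_t1 = 1.2, delta_t2 = 0)),
    "atrophy_effects", class = "gmprog_validation_error")
  expect_error(
    cohort_spec(region_definitions = data.frame(name = "x", cx = 2, cy = 2,
                                                cz = 2, radius = 9)),
    "region_definitions", class = "gmprog_validation_error")
})

test_that("generated cohort matches the study design counts", {
  ch <- generate_cohort(reduced_spec())
  phen <- ch$phenotypes
  expect_length(ch$volumes, 45 + 2 * 40)
  expect_equal(sum(phen$group == "HC"), 45)
  expect_equal(sum(phen$group == "AD" & phen$timepoint == "T1"), 40)
  expect_equal(sum(phen$group == "AD" & phen$timepoint == "T2"), 40)
  # HC are cross-sectional; every AD subject has exactly one scan per timepoint
  expect_true(all(phen$timepoint[phen$group == "HC"] == "T1"))
  ad <- phen[phen$group == "AD", ]
  expect_true(all(table(ad$subject_id, ad$timepoint) == 1))
  # volumes all live on the declared grid
  expect_true(all(vapply(ch$volumes, function(v)
    identical(dim(v$data), c(24L, 24L, 12L)), TRUE)))
})

test_that("phenotypes reproduce the fixed demographic structure", {
  phen <- generate_phenotypes(reduced_spec(seed = 11))
  ad1 <- phen[phen$group == "AD" & phen$timepoint == "T1", ]
  hc <- phen[phen$group == "HC", ]
  expect_equal(sum(ad1$sex == "M"), 22)
  expect_equal(sum(ad1$sex == "F"), 18)
  expect_equal(sum(hc$sex == "M"), 27)
  expect_true(all(hc$CDR == 0))
  # MoCA present at both timepoints for exactly 38 AD subjects
  ad <- phen[phen$group == "AD", ]
  both <- tapply(!is.na(ad$MoCA), ad$subject_id, all)
  expect_equal(sum(both), 38)
  # scores stay inside instrument ranges
  expect_true(all(phen$MMSE >= 0 & phen$MMSE <= 30))
  expect_true(all(is.na(phen$MoCA) | (phen$MoCA >= 0 & phen$MoCA <= 30)))
})

test_that("HC MMSE sample means concentrate on the target mean", {
  # law-of-large-numbers check on the score generator across seeds
  means <- vapply(1:200, function(s) {
    phen <- generate_phenotypes(reduced_spec(seed = s))
    mean(phen$MMSE[phen$group == "HC"])
  }, 0)
  expect_lt(abs(mean(means) - 29.13), 0.5)
})

test_that("cohort generation is seed-deterministic", {
  a <- generate_cohort(reduced_spec(seed = 5))
  b <- generate_cohort(reduced_spec(seed = 5))
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$volumes, b$volumes)
  c <- generate_cohort(reduced_spec(seed = 6))
  expect_false(identical(a$volumes[[1]]$data, c$volumes[[1]]$data))
})

test_that("planted behaviour coupling is realised at the planted strength", {
  # oracle: 95% sampling interval of Pearson r for a bivariate normal with
  # rho = 0.8 at n = 38 (Fisher z approximation)
  z <- atanh(0.8); se <- 1 / sqrt(38 - 3)
  ci <- tanh(z + c(-1.96, 1.96) * se)
  spec <- reduced_spec(seed = 3, behavior_coupling = 0.8,
                       n_ad = 38, n_ad_with_moca_both = 38)
  ch <- generate_cohort(spec)
  roi <- truth_roi_means(ch)
  phen <- ch$phenotypes
  ad <- sprintf("AD%03d", 1:38)
  dgmv <- roi[paste0(ad, "_T2"), "STG_right"] - roi[paste0(ad, "_T1"), "STG_right"]
  moca <- function(tp) phen$MoCA[match(paste0(ad, "_", tp),
                                       paste0(phen$subject_id, "_", phen$timepoint))]
  r <- cor(dgmv, moca("T2") - moca("T1"))
  expect_gt(r, ci[1])
  expect_lt(r, ci[2])
})

test_that("planted group means are realised in the volumes", {
  ch <- generate_cohort(reduced_spec(seed = 9))
  roi <- truth_roi_means(ch)
  phen <- ch$phenotypes
  gm <- ch$truth$true_group_means
  ids <- paste0(phen$subject_id, "_", phen$timepoint)
  for (i in seq_len(nrow(gm))) {
    sel <- phen$group == gm$group[i] & phen$timepoint == gm$timepoint[i]
    obs <- mean(roi[ids[sel], gm$region[i]])
    # region means vary across subjects by the intercept SD; allow 3 SE
    n <- sum(sel)
    tol <- 3 * 0.35 / sqrt(n)
    expect_lt(abs(obs - gm$mean[i]), tol)
  }
})

test_that("written cohort round-trips through the loader", {
  dir <- withr::local_tempdir()
  ch <- generate_cohort(reduced_spec(seed = 2, n_hc = 4, n_ad = 3,
                                     n_ad_with_moca_both = 3))
  write_cohort(ch, dir)
  lc <- load_cohort(file.path(dir, "volumes"), file.path(dir, "phenotypes.csv"))
  expect_length(lc$volumes, 10)
  expect_identical(lc$ids, sort(paste0(ch$phenotypes$subject_id, "_",
                                       ch$phenotypes$timepoint)))
  # volume data survive the NIfTI round trip
  nm <- lc$ids[1]
  expect_equal(lc$volumes[[nm]]$data, ch$volumes[[nm]]$data,
               tolerance = 1e-12)
  expect_true(file.exists(file.path(dir, "truth.json")))
  expect_true(file.exists(file.path(dir, "truth_labels.nii.gz")))
})
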