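test_that("covariance edge is Pearson r with guards", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(covariance_edge(x, 2 * x), 1)
  expect_equal(covariance_edge(x, -x), -1)
  expect_error(covariance_edge(x, rep(1, 5)), class = "gmprog_degenerate_error")
  expect_error(covariance_edge(1:3, 1:3), class = "gmprog_insufficient_data_error")
  # Fisher-consistent at moderate n: mean sample r near the population value
  set.seed(5)
  rs <- vapply(1:1000, function(i) {
    z <- rnorm(45); e <- rnorm(45)
    a <- z; b <- 0.6 * z + sqrt(1 - 0.36) * e
    covariance_edge(a, b)
  }, 0)
  expect_lt(abs(mean(rs) - 0.59), 0.02)
})

test_that("edge permutation test: null behaviour, symmetry, determinism", {
  set.seed(2)
  g <- cbind(rnorm(20), rnorm(20))
  same <- edge_group_difference(g, g, n_perm = 400, seed = 3)
  expect_equal(same$observed_diff, 0)
  expect_false(same$significant)
  expect_gt(same$p, 0.5)
  # add-one p can never be zero
  expect_gt(same$p, 0)
  # swapping groups negates the difference and preserves p
  h <- cbind(rnorm(15), rnorm(15))
  e1 <- edge_group_difference(g, h, n_perm = 400, seed = 7)
  e2 <- edge_group_difference(h, g, n_perm = 400, seed = 7)
  expect_equal(e1$observed_diff, -e2$observed_diff)
  expect_equal(e1$p, e2$p, tolerance = 0.05)
  # identical seeds reproduce the full result
  e3 <- edge_group_difference(g, h, n_perm = 400, seed = 7)
  expect_identical(e1[c("p", "null_quantiles", "significant")],
                   e3[c("p", "null_quantiles", "significant")])
})

test_that("planted covariance difference is detected on the planted edge only", {
  # cohorts isolating the covariance manipulation (no atrophy), so label
  # exchangeability holds on every unplanted edge
  n_seeds <- 25
  flagged <- matrix(FALSE, n_seeds, 10)
  for (s in seq_len(n_seeds)) {
    regs <- c("overlapped", "continuing", "STG_left", "STG_right", "caudate_left")
    sp <- cohort_spec(grid_shape = c(20L, 20L, 10L), seed = 3000 + s,
                      atrophy_effects = data.frame(name = regs, delta_t1 = 0,
                                                   delta_t2 = 0),
                      progression_baseline_coupling = 0)
    ch <- generate_cohort(sp)
    roi <- truth_roi_means(ch)
    phen <- ch$phenotypes
    ids <- paste0(phen$subject_id, "_", phen$timepoint)
    hc <- ids[phen$group == "HC"]
    a1 <- ids[phen$group == "AD" & phen$timepoint == "T1"]
    et <- scn_edge_tests(roi, hc, a1, n_perm = 500, seed = s)
    flagged[s, ] <- et$significant
    if (s == 1) {
      planted <- which(et$region1 == "STG_right" & et$region2 == "caudate_left" |
                       et$region1 == "caudate_left" & et$region2 == "STG_right")
    }
  }
  # the planted edge is flagged in the majority of seeds ...
  expect_gt(mean(flagged[, planted]), 0.5)
  # ... and every other edge only rarely
  expect_lt(mean(flagged[, -planted]), 0.15)
})

test_that("cross-lagged coefficient has the stated closed-form behaviour", {
  set.seed(9)
  n <- 200
  y1 <- rnorm(n); x <- rnorm(n)
  # target's future depends only on its own past: coefficient 0
  expect_equal(causal_coefficient(x, y1, y1), 0, tolerance = 1e-12)
  # independent source: coefficient ~ 0 in the mean over seeds
  cc0 <- vapply(1:200, function(i) {
    y1 <- rnorm(40); x <- rnorm(40); y2 <- y1 + rnorm(40)
    causal_coefficient(x, y1, y2)
  }, 0)
  expect_lt(abs(mean(cc0)), 2 * sd(cc0) / sqrt(200))
  # planted effect: y2 = 0.5 x + noise with x independent of y1;
  # standardized coefficient = 0.5 sd(x) / sd(y2) (OLS closed form)
  cc <- vapply(1:500, function(i) {
    y1 <- rnorm(40); x <- rnorm(40)
    y2 <- 0.5 * x + rnorm(40, sd = 0.5)
    causal_coefficient(x, y1, y2) - 0.5 * sd(x) / sd(y2)
  }, 0)
  expect_lt(abs(mean(cc)), 2 * sd(cc) / sqrt(500))
  # collinear regressors are rejected
  expect_error(causal_coefficient(y1, y1 + 1e-9 * rnorm(n), y1),
               class = "gmprog_collinearity_error")
})

test_that("bootstrap causal effect: determinism, power, calibration", {
  set.seed(4)
  n <- 40
  y1 <- rnorm(n); x <- rnorm(n)
  y2 <- 0.6 * y1 + 0.5 * x + rnorm(n, sd = 0.6)
  a <- causal_effect_resampled(x, y1, y2, n_resamples = 500, seed = 11)
  b <- causal_effect_resampled(x, y1, y2, n_resamples = 500, seed = 11)
  expect_identical(a, b)
  expect_true(a$ci[1] <= a$boot_mean && a$boot_mean <= a$ci[2])
  expect_lt(a$p, 0.05)
  # strong standardized effect (0.5) in a cohort-like model, where the
  # target's follow-up tracks its own baseline: detected in most cohorts
  hits <- vapply(1:60, function(i) {
    y1 <- rnorm(n); x <- rnorm(n)
    y2 <- 0.7 * y1 + 0.5 * x + rnorm(n, sd = sqrt(1 - 0.49 - 0.25))
    causal_effect_resampled(x, y1, y2, n_resamples = 300, seed = i)$p < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.9)
  # null effect rejects at close to the nominal rate
  null_hits <- vapply(1:200, function(i) {
    y1 <- rnorm(n); x <- rnorm(n); y2 <- y1 + rnorm(n)
    causal_effect_resampled(x, y1, y2, n_resamples = 300, seed = i)$p < 0.05
  }, TRUE)
  expect_lt(abs(mean(null_hits) - 0.05), 0.05)
})
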