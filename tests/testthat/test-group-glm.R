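test_that("second-level t without covariates equals the closed-form one-sample t", {
  # worked example: values 1..5 at one voxel
  maps <- map_set_from_matrix(matrix(c(1, 2, 3, 4, 5), ncol = 1))
  tm <- fit_second_level(maps)
  expect_equal(tm$t, 3 / (sd(1:5) / sqrt(5)), tolerance = 1e-12)
  expect_equal(tm$t, 4.242640687, tolerance = 1e-8)
  expect_equal(tm$df, 4)
  # values symmetric about zero
  tm0 <- fit_second_level(map_set_from_matrix(matrix(c(-2, -1, 0, 1, 2), ncol = 1)))
  expect_equal(tm0$t, 0)
  # 100 random small datasets, 1e-10 agreement
  set.seed(42)
  for (k in 1:100) {
    n <- sample(3:12, 1)
    y <- matrix(rnorm(n * 3), nrow = n)
    tm <- fit_second_level(map_set_from_matrix(y))
    expect_equal(tm$t, apply(y, 2, oracle_one_sample_t), tolerance = 1e-10)
    expect_equal(tm$df, n - 1)
  }
})

test_that("covariate designs agree with a brute-force lm() fit", {
  set.seed(7)
  for (k in 1:25) {
    n <- sample(6:15, 1)
    y <- matrix(rnorm(n * 2), nrow = n)
    covs <- data.frame(age = rnorm(n), ehi = rnorm(n))
    maps <- map_set_from_matrix(y, covariates = covs)
    tm <- fit_second_level(maps, covariate_names = c("age", "ehi"))
    expect_equal(tm$df, n - 3)
    for (v in 1:2) {
      fit <- summary(lm(y[, v] ~ scale(covs$age, scale = FALSE) +
                                 scale(covs$ehi, scale = FALSE)))
      expect_equal(tm$t[v], fit$coefficients["(Intercept)", "t value"],
                   tolerance = 1e-10)
    }
  }
})

test_that("covariates are re-centered within the analyzed subset", {
  set.seed(8)
  y <- matrix(rnorm(10 * 2), nrow = 10)
  covs <- data.frame(age = 1:10)
  maps <- map_set_from_matrix(y, covariates = covs)
  sub <- c(1, 3, 5, 7, 9)
  tm <- fit_second_level(maps, subset = sub, covariate_names = "age")
  for (v in 1:2) {
    fit <- summary(lm(y[sub, v] ~ scale(covs$age[sub], scale = FALSE)))
    expect_equal(tm$t[v], fit$coefficients["(Intercept)", "t value"],
                 tolerance = 1e-10)
  }
})

test_that("degenerate designs are rejected", {
  maps <- map_set_from_matrix(matrix(rnorm(12), nrow = 6),
                              covariates = data.frame(a = 1:6, b = 2 * (1:6)))
  expect_error(fit_second_level(maps, covariate_names = c("a", "b")),
               "rank-deficient.*b")
  expect_error(fit_second_level(maps, subset = c(1, 1, 2)), "duplicate")
  expect_error(fit_second_level(maps, contrast = c(1, 0)), "contrast length")
  expect_error(fit_second_level(maps, covariate_names = "zzz"), "zzz")
})

test_that("one-sided p-values follow the Student-t upper tail", {
  maps <- map_set_from_matrix(matrix(c(1, 2, 3, 4, 5), ncol = 1))
  tm <- fit_second_level(maps)
  # quadrature oracle: integrate the t density over the upper tail
  quad <- integrate(function(x) dt(x, df = 4), lower = tm$t, upper = Inf,
                    rel.tol = 1e-12)$value
  expect_equal(p_values(tm), quad, tolerance = 1e-8)

  tm$t <- 0
  expect_equal(p_values(tm), 0.5)
  tm$t <- 1e6
  expect_lt(p_values(tm), 1e-12)
  tm$t <- -1e6
  expect_gt(p_values(tm), 1 - 1e-12)
})

test_that("zero-residual-variance voxels get p = 1 with a warning", {
  y <- cbind(rep(2, 5), rnorm(5))
  tm <- fit_second_level(map_set_from_matrix(y))
  expect_identical(tm$zero_var, c(TRUE, FALSE))
  expect_warning(p <- p_values(tm), "zero residual variance")
  expect_equal(p[1], 1)
})

test_that("thresholding implements uncorrected, Bonferroni and BH conventions", {
  p <- c(.001, .02, .03, .04)
  # Bonferroni cutoff .0125: only the first survives
  bon <- threshold_map(p, "fwe_bonferroni", alpha = .05)
  expect_identical(bon$significant, c(TRUE, FALSE, FALSE, FALSE))
  # BH step-up: k* = 4 since p_(4) = .04 <= 4 * .05/4, all significant
  bh <- threshold_map(p, "fdr_bh", alpha = .05)
  expect_identical(bh$significant, rep(TRUE, 4))
  expect_identical(bh$significant, oracle_bh(p, .05))
  # alpha = 1 uncorrected keeps every voxel
  unc <- threshold_map(runif(10), "uncorrected", alpha = 1)
  expect_true(all(unc$significant))
  expect_error(threshold_map(p, "fdr_bh", alpha = 0), "alpha")
})

test_that("BH agrees with the brute-force step-up on random fields (m <= 50)", {
  set.seed(11)
  for (k in 1:60) {
    m <- sample(1:50, 1)
    p <- round(runif(m)^sample(1:3, 1), sample(2:6, 1))  # induce ties
    alpha <- sample(c(.01, .05, .1, .2), 1)
    got <- threshold_map(p, "fdr_bh", alpha = alpha)$significant
    expect_identical(got, oracle_bh(p, alpha))
  }
})

test_that("significant sets nest: Bonferroni within BH within uncorrected", {
  set.seed(12)
  for (k in 1:30) {
    p <- runif(sample(5:200, 1))^2
    alpha <- .05
    bon <- threshold_map(p, "fwe_bonferroni", alpha)$significant
    bh <- threshold_map(p, "fdr_bh", alpha)$significant
    unc <- threshold_map(p, "uncorrected", alpha)$significant
    expect_true(all(!bon | bh))   # bon subset of bh
    expect_true(all(!bh | unc))   # bh subset of uncorrected
  }
})

test_that("sign-flip max-t permutation threshold controls family-wise error", {
  # pure-noise cohorts: the fraction of replicates with any significant
  # voxel should sit near the nominal alpha = .05
  dims <- c(6, 6, 6)
  n <- 12
  fwer_hits <- vapply(1:200, function(k) {
    maps <- simulate_cohort(cohort_spec(grid_shape = dims, n_subjects = n,
                                        blobs = list(), noise_sd = 1,
                                        seed = 5000 + k))
    tm <- fit_second_level(maps)
    thr <- threshold_map(p_values(tm), "fwe_permutation", alpha = .05,
                         tmap = tm, maps = maps, n_perm = 199L,
                         seed = 100 + k)
    any(thr$significant)
  }, logical(1))
  expect_gte(mean(fwer_hits), 0.01)
  expect_lte(mean(fwer_hits), 0.11)
})

test_that("permutation threshold requires the fitted t-map and data", {
  expect_error(threshold_map(runif(5), "fwe_permutation", alpha = .05),
               "requires")
})
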