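# hand-built power_map: 1-D row of voxels, full control over detection
fake_power_map <- function(min_n, full_sig, tvals, sizes, frac = NULL,
                           safe = 100) {
  nv <- length(min_n)
  dims <- c(nv, 1L, 1L)
  structure(list(
    min_n = array(min_n, dims), sizes = sizes,
    detection_fractions = frac %||%
      matrix(100, nrow = nv, ncol = length(sizes), dimnames = list(NULL, sizes)),
    full_significant = full_sig,
    full_tmap = list(t = tvals),
    floor = min(sizes), safe_threshold = safe, n = max(sizes) + 1L,
    mask = array(TRUE, dims), dim = dims, affine = diag(4)
  ), class = "power_map")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("cluster labelling respects the chosen connectivity", {
  v <- array(FALSE, c(5, 5, 5))
  v[1, 1, 1] <- TRUE; v[2, 2, 2] <- TRUE        # touch only at a corner
  expect_equal(max(label_clusters(v, 26)), 1)
  expect_equal(max(label_clusters(v, 18)), 2)
  expect_equal(max(label_clusters(v, 6)), 2)
  e <- array(FALSE, c(5, 5, 5))
  e[1, 1, 1] <- TRUE; e[2, 2, 1] <- TRUE        # touch along an edge
  expect_equal(max(label_clusters(e, 18)), 1)
  expect_equal(max(label_clusters(e, 6)), 2)
  # two blobs separated by more than one voxel of background
  w <- array(FALSE, c(7, 7, 7)); w[1:2, 1:2, 1:2] <- TRUE; w[5:6, 5:6, 5:6] <- TRUE
  expect_equal(max(label_clusters(w, 26)), 2)
  # single isolated voxel
  s <- array(FALSE, c(3, 3, 3)); s[2, 2, 2] <- TRUE
  labs <- label_clusters(s)
  expect_equal(sum(labs > 0), 1)
  expect_equal(max(labs), 1)
  # labels ordered by decreasing size
  big <- array(FALSE, c(9, 3, 3)); big[1:2, 1, 1] <- TRUE; big[5:9, 1, 1] <- TRUE
  labs2 <- label_clusters(big, 6)
  expect_equal(labs2[5, 1, 1], 1L)  # larger cluster gets label 1
  expect_equal(labs2[1, 1, 1], 2L)
  expect_equal(max(label_clusters(array(FALSE, c(3, 3, 3)))), 0)
})

test_that("cluster min-n aggregates member voxels per the chosen rule", {
  sizes <- seq(21L, 12L)
  # one cluster of three voxels with min_n 14, 18, 22 (22 > scan: use 21..12)
  pm <- fake_power_map(min_n = c(14L, 18L, 21L, NA),
                       full_sig = c(TRUE, TRUE, TRUE, FALSE),
                       tvals = c(5, 9, 7, 1), sizes = sizes)
  tab <- cluster_power_table(pm, rule = "min")
  expect_equal(nrow(tab), 1)
  expect_equal(tab$min_n, 14L)                       # any member voxel
  expect_equal(tab$peak_t, 9)
  expect_equal(tab$peak_x, 1L)                       # 0-based voxel index
  tab_all <- cluster_power_table(pm, rule = "all")
  expect_equal(tab_all$min_n, 21L)                   # every member voxel
  tab_peak <- cluster_power_table(pm, rule = "peak")
  expect_equal(tab_peak$min_n, 18L)                  # the peak voxel's min_n
  # every-voxel-min_n-12 cluster has cluster min-n 12
  pm12 <- fake_power_map(min_n = rep(12L, 3), full_sig = rep(TRUE, 3),
                         tvals = c(3, 4, 5), sizes = sizes)
  expect_equal(cluster_power_table(pm12)$min_n, 12L)
})

test_that("peak world coordinates follow the affine", {
  pm <- fake_power_map(min_n = c(14L, NA, NA), full_sig = c(TRUE, FALSE, FALSE),
                       tvals = c(5, 0, 0), sizes = seq(15L, 12L))
  aff <- diag(c(3, 3, 3, 1)); aff[1:3, 4] <- c(-10, -20, -30)
  pm$affine <- aff
  tab <- cluster_power_table(pm)
  expect_equal(c(tab$peak_mm_x, tab$peak_mm_y, tab$peak_mm_z), c(-10, -20, -30))
})

test_that("power scan assigns min_n only to full-map-significant voxels", {
  maps <- simulate_cohort(cohort_spec(n_subjects = 16, seed = 17))
  pm <- power_scan(maps, method = "fdr_bh", alpha = .05, floor = 12, seed = 9)
  full_vol <- array(FALSE, pm$dim); full_vol[pm$mask] <- pm$full_significant
  expect_true(all(is.na(pm$min_n[!full_vol])))
  defined <- pm$min_n[!is.na(pm$min_n)]
  expect_true(all(defined >= 12 & defined <= 16))
  # determinism
  pm2 <- power_scan(maps, method = "fdr_bh", alpha = .05, floor = 12, seed = 9)
  expect_identical(pm$min_n, pm2$min_n)
  expect_error(power_scan(maps, floor = 1), "design error")
  expect_error(power_scan(maps, floor = 17), "design error")
})

test_that("near-noise-free blobs are safely detected down to the floor", {
  spec <- cohort_spec(grid_shape = c(10, 10, 10), n_subjects = 16,
                      blobs = list(list(center = c(5, 5, 5), amplitude = 1, sd = 1.5)),
                      noise_sd = 1e-6, seed = 23)
  maps <- simulate_cohort(spec)
  pm <- power_scan(maps, method = "fwe_bonferroni", alpha = .05, floor = 12,
                   seed = 2)
  expect_equal(pm$min_n[5, 5, 5], 12L)
  # per-size counts of safely detected voxels are non-decreasing in group size
  ct <- cluster_power_table(pm)
  counts <- attr(ct, "size_counts")[1, ]       # sizes stored decreasing
  expect_true(all(diff(rev(counts)) >= 0))
})

test_that("monotone closure bridges non-monotone sampled detection", {
  sizes <- seq(15L, 12L)
  frac <- matrix(c(100, 100, 98, 100), nrow = 1, dimnames = list(NULL, sizes))
  pm <- fake_power_map(min_n = NA_integer_, full_sig = TRUE, tvals = 5,
                       sizes = sizes, frac = frac)
  safe <- jackmap:::matrixStats_cumand(pm$detection_fractions >= pm$safe_threshold)
  # detection dips at size 13, so sizes 13 and 12 are not safe
  expect_identical(as.logical(safe), c(TRUE, TRUE, FALSE, FALSE))
})

test_that("a stricter threshold never needs fewer subjects than a lenient one", {
  maps <- simulate_cohort(cohort_spec(n_subjects = 18, seed = 41))
  pm_fwe <- power_scan(maps, method = "fwe_bonferroni", alpha = .05,
                       floor = 12, seed = 4)
  pm_fdr <- power_scan(maps, method = "fdr_bh", alpha = .05,
                       floor = 12, seed = 4)
  both <- !is.na(pm_fwe$min_n) & !is.na(pm_fdr$min_n)
  expect_gt(sum(both), 0)
  expect_true(all(pm_fwe$min_n[both] >= pm_fdr$min_n[both]))
})
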