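#' Exact number of unique subject-removal combinations
#'
#' The number of distinct reduced designs obtained by removing `r` of `n`
#' subjects is the binomial coefficient n! / (r! (n - r)!), computed in the
#' overflow-safe multiplicative form. Counts are exact in double precision
#' for every n, r with C(n, r) < 2^53, far beyond any feasible group size.
#'
#' @param n Original group size.
#' @param r Number of subjects removed.
#' @return The count, as a double (exact integer value).
#' @examples
#' count_combinations(39, 1)  # 39 reduced designs
#' @export
count_combinations <- function(n, r) {
  if (length(n) != 1L || length(r) != 1L || n < 0 || r < 0 || r > n)
    stop_input("need 0 <= r <= n, got n = %s, r = %s", n, r)
  r <- min(r, n - r)
  if (r == 0) return(1)
  # multiplicative form; each partial product is itself a binomial
  # coefficient, hence integral
  out <- 1
  for (i in seq_len(r)) out <- out * (n - r + i) / i
  round(out)
}

# combination of given rank (0-based) in lexicographic order of the
# r-subsets of {1..n}; combinatorial number system unranking, so huge
# design spaces are sampled without materializing them
unrank_combination <- function(rank, n, r) {
  out <- integer(r)
  x <- 1L
  for (i in seq_len(r)) {
    repeat {
      block <- count_combinations(n - x, r - i)
      if (rank < block) break
      rank <- rank - block
      x <- x + 1L
    }
    out[i] <- x
    x <- x + 1L
  }
  out
}

#' Plan the reduced designs for one removal depth
#'
#' With `r` of `n` subjects removed there are `C(n, r)` unique reduced
#' designs. If that count is within `cap`, all of them are enumerated in
#' lexicographic order (exhaustive mode, seed-independent). Otherwise `cap`
#' distinct combinations are drawn uniformly without replacement, by
#' sampling ranks in the combinatorial number system, so every subject has
#' an even chance of being removed.
#'
#' @param n Original group size.
#' @param r Subjects to remove (1 <= r <= n - 2).
#' @param cap Maximum number of reduced designs per step (default 100).
#' @param seed Seed for the sampled mode.
#' @return Object of class `combination_plan` with fields `n`, `r`, `c_max`,
#'   `cap`, `exhaustive`, `seed`, and `subsets`: a list of retained-subject
#'   index vectors (each of size n - r); `removed`: the complementary
#'   removed-subject sets.
#' @export
plan_reduced_designs <- function(n, r, cap = 100L, seed = 1L) {
  n <- as.integer(n); r <- as.integer(r); cap <- as.integer(cap)
  if (r < 1L || r > n - 2L)
    stop_input("design error: need 1 <= r <= n - 2 (n = %d, r = %d) so reduced designs keep >= 2 subjects",
               n, r)
  if (cap < 1L) stop_input("cap must be >= 1")
  c_max <- count_combinations(n, r)
  exhaustive <- c_max <= cap

  removed <- if (exhaustive) {
    cmb <- utils::combn(n, r)
    lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
  } else {
    ranks <- numeric(0)
    draw_seed <- seed
    while (length(ranks) < cap) {   # rank collisions are vanishingly rare
      extra <- with_seed(draw_seed,
                         floor(stats::runif(cap - length(ranks) + 8L) * c_max))
      ranks <- unique(c(ranks, pmin(extra, c_max - 1)))
      draw_seed <- draw_seed + 1L
    }
    ranks <- ranks[seq_len(cap)]
    lapply(ranks, unrank_combination, n = n, r = r)
  }
  subsets <- lapply(removed, function(rm) setdiff(seq_len(n), rm))

  structure(list(n = n, r = r, c_max = c_max, cap = cap,
                 exhaustive = exhaustive, seed = as.integer(seed),
                 subsets = subsets, removed = removed),
            class = "combination_plan")
}

#' @export
print.combination_plan <- function(x, ...) {
  cat(sprintf("combination_plan: n = %d, r = %d, C(n,r) = %s, %d design(s)%s\n",
              x$n, x$r, format(x$c_max, big.mark = ","), length(x$subsets),
              if (x$exhaustive) " (exhaustive)" else " (sampled)"))
  invisible(x)
}

#' Run a third-level (L3) analysis at one removal depth
#'
#' Fits and thresholds the original full-group design and every planned
#' reduced design with identical settings, collecting the per-design
#' thresholded maps. The result is the raw material for Dice tables, group
#' percent overlap maps and reliability classes.
#'
#' @param maps A [subject_map_set()].
#' @param r Number of subjects to remove.
#' @param method,alpha Threshold settings, as in [threshold_map()].
#' @param covariate_names Nuisance covariates for every fit.
#' @param contrast Contrast vector (default: intercept / group mean).
#' @param cap Maximum reduced designs for this step (default 100).
#' @param seed Seed for design sampling (and permutation thresholds).
#' @param n_perm Permutations when `method = "fwe_permutation"`.
#' @return Object of class `l3_result`: `plan`, `original_tmap`,
#'   `original_map`, `reduced_maps` (list of `thresholded_map`), and
#'   `notation` (the descriptor `L3^{n-r}`).
#' @examples
#' maps <- simulate_cohort(cohort_spec(grid_shape = c(10, 10, 10),
#'                                     n_subjects = 12, seed = 3))
#' res <- run_l3(maps, r = 1, method = "uncorrected", alpha = 0.001)
#' length(res$reduced_maps)  # 12 leave-one-out designs
#' @export
run_l3 <- function(maps, r, method = "fwe_bonferroni", alpha = 0.05,
                   covariate_names = character(0), contrast = NULL,
                   cap = 100L, seed = 1L, n_perm = 999L) {
  n <- n_subjects(maps)
  min_size <- max(2L, length(covariate_names) + 2L)
  if (n - r < min_size)
    stop_input("design error: removing %d of %d subjects leaves %d, below the minimum %d",
               r, n, n - r, min_size)
  plan <- plan_reduced_designs(n, r, cap = cap, seed = seed)

  fit_one <- function(subset, design_seed) {
    tm <- fit_second_level(maps, subset = subset,
                           covariate_names = covariate_names, contrast = contrast)
    threshold_map(p_values(tm), method = method, alpha = alpha, tmap = tm,
                  maps = maps, subset = subset, n_perm = n_perm,
                  seed = design_seed, covariate_names = covariate_names)
  }

  original_tmap <- fit_second_level(maps, covariate_names = covariate_names,
                                    contrast = contrast)
  original <- threshold_map(p_values(original_tmap), method = method,
                            alpha = alpha, tmap = original_tmap, maps = maps,
                            subset = seq_len(n), n_perm = n_perm,
                            seed = derive_seed(seed, "original"),
                            covariate_names = covariate_names)
  reduced <- vector("list", length(plan$subsets))
  for (i in seq_along(plan$subsets)) {
    reduced[[i]] <- tryCatch(
      fit_one(plan$subsets[[i]], derive_seed(seed, paste0("design", i))),
      error = function(e) stop_input(
        "reduced design %d (retained subjects: %s) failed: %s",
        i, paste(plan$subsets[[i]], collapse = ","), conditionMessage(e)))
  }

  structure(list(plan = plan, original_tmap = original_tmap,
                 original_map = original, reduced_maps = reduced,
                 notation = sprintf("L3^%d-%d", n, r)),
            class = "l3_result")
}

#' @export
print.l3_result <- function(x, ...) {
  cat(sprintf("l3_result %s: %d reduced design(s), threshold %s (alpha = %g)\n",
              x$notation, length(x$reduced_maps), x$original_map$method,
              x$original_map$alpha))
  invisible(x)
}
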