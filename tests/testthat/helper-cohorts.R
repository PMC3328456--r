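# Shared fixtures and independent oracles, built in code at test time.

# subject_map_set straight from a subjects x voxels matrix (1-D grid padded
# to 3-D so every volume-level contract still applies)
map_set_from_matrix <- function(data, dims = c(ncol(data), 1L, 1L),
                                covariates = NULL) {
  subject_map_set(data = data, dim = dims,
                  subject_ids = sprintf("s%02d", seq_len(nrow(data))),
                  mask = array(TRUE, dims), covariates = covariates)
}

# small default cohort for pipeline-level tests
small_cohort <- function(n = 12, seed = 1, ...) {
  simulate_cohort(cohort_spec(n_subjects = n, seed = seed, ...))
}

# --- independent oracles -------------------------------------------------

# closed-form one-sample t
oracle_one_sample_t <- function(x) mean(x) / (stats::sd(x) / sqrt(length(x)))

# O(m^2) Benjamini-Hochberg step-up, straight from the definition
oracle_bh <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  kstar <- 0L
  for (k in seq_len(m)) if (ps[k] <= k * alpha / m) kstar <- k
  sig <- rep(FALSE, m)
  if (kstar > 0L) sig[p <= ps[kstar]] <- TRUE
  sig
}

# Pascal-triangle binomial coefficients, row n
oracle_pascal_row <- function(n) {
  row <- 1
  for (i in seq_len(n)) row <- c(0, row) + c(row, 0)
  row
}

# exact two-sided Mann-Whitney p by enumerating all group assignments,
# computing U by pairwise comparison (not via ranks)
oracle_mw_exact <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_of(a, b)
  picks <- utils::combn(length(pooled), n1)
  us <- apply(picks, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# match activation foci to labelled clusters: label of the significant
# voxel nearest each center, searched within `radius` voxels
match_blob_clusters <- function(labels, centers, radius = 3L) {
  dims <- dim(labels)
  vapply(centers, function(cc) {
    xs <- max(1, cc[1] - radius):min(dims[1], cc[1] + radius)
    ys <- max(1, cc[2] - radius):min(dims[2], cc[2] + radius)
    zs <- max(1, cc[3] - radius):min(dims[3], cc[3] + radius)
    sub <- labels[xs, ys, zs, drop = FALSE]
    hits <- which(sub > 0, arr.ind = TRUE)
    if (!nrow(hits)) return(NA_integer_)
    d2 <- (xs[hits[, 1]] - cc[1])^2 + (ys[hits[, 2]] - cc[2])^2 +
          (zs[hits[, 3]] - cc[3])^2
    sub[hits[which.min(d2), , drop = FALSE]]
  }, integer(1))
}

# cluster min-n for each blob center of a power scan
blob_cluster_minn <- function(pm, centers, radius = 3L) {
  full_vol <- array(FALSE, pm$dim)
  full_vol[pm$mask] <- pm$full_significant
  labels <- label_clusters(full_vol)
  ct <- cluster_power_table(pm, labels = labels)
  lab <- match_blob_clusters(labels, centers, radius)
  vapply(lab, function(l) if (is.na(l)) NA_integer_
         else as.integer(ct$min_n[ct$cluster == l]), integer(1))
}
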