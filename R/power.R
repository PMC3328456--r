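#' Post-hoc power scan: minimum detecting group size per voxel
#'
#' Sweeps group sizes m = n-1 down to `floor`, at each size drawing a capped
#' plan of size-m subsets (resampled independently per size from a per-size
#' seed), re-fitting and thresholding each, and recording the per-voxel
#' detection fraction (a per-size gPOM). A voxel is safely detected at size
#' m when its detection fraction reaches `safe_threshold` percent at m and
#' at every evaluated size above m (monotone closure, which makes the
#' minimum well-defined when sampled detection is non-monotone). The
#' minimum detecting group size min_n is the smallest such m; voxels that
#' only the full design detects get min_n = n. Following the power-approach
#' convention, min_n is computed only for voxels significant in the
#' full-group map; elsewhere it is NA.
#'
#' @param maps A [subject_map_set()].
#' @param method,alpha Threshold settings, as in [threshold_map()].
#' @param covariate_names,contrast Passed to [fit_second_level()].
#' @param floor Smallest group size scanned (default 12, the classical
#'   minimum for random-effects groups).
#' @param cap Maximum designs per size (default 100).
#' @param seed Master seed; per-size plans use seeds derived from it.
#' @param safe_threshold Required detection fraction in percent
#'   (default 100; 80 is a common power-analysis alternative).
#' @param stride Evaluate every `stride`-th size (default 1 = every integer
#'   size).
#' @param n_perm Permutations for `method = "fwe_permutation"`.
#' @return Object of class `power_map`: `min_n` (3-D array, NA where
#'   undefined), `sizes` (evaluated group sizes, decreasing),
#'   `detection_fractions` (matrix mask-voxels x sizes, percent),
#'   `full_significant` (logical over mask voxels), `floor`,
#'   `safe_threshold`, `n`, plus grid metadata.
#' @export
power_scan <- function(maps, method = "fwe_bonferroni", alpha = 0.05,
                       covariate_names = character(0), contrast = NULL,
                       floor = 12L, cap = 100L, seed = 1L,
                       safe_threshold = 100, stride = 1L, n_perm = 999L) {
  n <- n_subjects(maps)
  min_size <- max(2L, length(covariate_names) + 2L)
  if (floor < min_size)
    stop_input("design error: floor = %d is below the smallest feasible design (%d)",
               floor, min_size)
  if (floor > n) stop_input("design error: floor = %d exceeds group size n = %d", floor, n)

  full_tmap <- fit_second_level(maps, covariate_names = covariate_names,
                                contrast = contrast)
  full_thr <- threshold_map(p_values(full_tmap), method = method, alpha = alpha,
                            tmap = full_tmap, maps = maps,
                            subset = seq_len(n), n_perm = n_perm,
                            seed = derive_seed(seed, "full"),
                            covariate_names = covariate_names)
  full_sig <- full_thr$significant

  sizes <- seq(n - 1L, floor, by = -as.integer(stride))
  nv <- sum(maps$mask)
  frac <- matrix(NA_real_, nrow = nv, ncol = length(sizes),
                 dimnames = list(NULL, sizes))
  for (j in seq_along(sizes)) {
    m <- sizes[j]
    size_seed <- derive_seed(seed, paste0("size", m))
    l3 <- run_l3(maps, r = n - m, method = method, alpha = alpha,
                 covariate_names = covariate_names, contrast = contrast,
                 cap = cap, seed = size_seed, n_perm = n_perm)
    counts <- Reduce(`+`, lapply(l3$reduced_maps, function(x) x$significant * 1L))
    frac[, j] <- 100 * counts / length(l3$reduced_maps)
  }

  # monotone closure: safe at size m iff detected at m and every larger
  # evaluated size; sizes are stored in decreasing order
  safe <- frac >= safe_threshold
  run_ok <- matrixStats_cumand(safe)
  min_n_vec <- rep(NA_integer_, nv)
  det <- which(full_sig)
  for (v in det) {
    ok <- run_ok[v, ]
    min_n_vec[v] <- if (any(ok)) sizes[max(which(ok))] else n
  }

  structure(list(
    min_n = unmask(min_n_vec, maps$mask, fill = NA_integer_),
    sizes = sizes, detection_fractions = frac,
    full_significant = full_sig, full_tmap = full_tmap,
    floor = as.integer(floor), safe_threshold = safe_threshold, n = n,
    mask = maps$mask, dim = maps$dim, affine = maps$affine
  ), class = "power_map")
}

# row-wise cumulative AND along columns (no-dependency helper)
matrixStats_cumand <- function(x) {
  out <- x
  if (ncol(x) > 1L)
    for (j in 2:ncol(x)) out[, j] <- out[, j - 1L] & x[, j]
  out
}

#' @export
print.power_map <- function(x, ...) {
  def <- x$min_n[!is.na(x$min_n)]
  cat(sprintf("power_map: n = %d, sizes %d..%d, %d voxel(s) with min_n defined (range %s)\n",
              x$n, max(x$sizes), min(x$sizes), length(def),
              if (length(def)) paste(range(def), collapse = "-") else "-"))
  invisible(x)
}

# 6/18/26-neighbourhood offsets
connectivity_offsets <- function(connectivity) {
  stopifnot(connectivity %in% c(6L, 18L, 26L))
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 "6"  = nz == 1,
                 "18" = nz >= 1 & rowSums(off != 0) <= 2,
                 "26" = nz >= 1)
  off[keep, , drop = FALSE]
}

#' Label connected clusters of a binary volume
#'
#' Connected-component labelling under 6-, 18- or 26-neighbourhood
#' adjacency. Labels are assigned deterministically: clusters are numbered
#' by decreasing voxel count, ties broken by the smallest linear voxel
#' index.
#'
#' @param significant Logical 3-D array (or a `thresholded_map`).
#' @param connectivity 6, 18 or 26 (default 26).
#' @return Integer array of cluster labels; 0 is background.
#' @export
label_clusters <- function(significant, connectivity = 26L) {
  if (inherits(significant, "thresholded_map"))
    significant <- significance_volume(significant)
  dims <- dim(significant)
  vox <- which(significant)
  labels <- array(0L, dims)
  if (!length(vox)) return(labels)

  coord <- arrayInd(vox, dims)
  id_of <- array(0L, dims); id_of[vox] <- seq_along(vox)
  off <- connectivity_offsets(as.integer(connectivity))
  edges <- integer(0)
  for (k in seq_len(nrow(off))) {
    nb <- sweep(coord, 2, off[k, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
    if (!any(ok)) next
    nb_lin <- (nb[ok, 3] - 1L) * dims[1] * dims[2] +
              (nb[ok, 2] - 1L) * dims[1] + nb[ok, 1]
    nb_id <- id_of[nb_lin]
    src <- which(ok)[nb_id > 0L]
    if (length(src))
      edges <- c(edges, rbind(src, nb_id[nb_id > 0L]))
  }
  g <- igraph::make_graph(edges = edges, n = length(vox), directed = FALSE)
  comp <- igraph::components(g)$membership

  # deterministic relabel: decreasing size, then smallest linear index
  sizes <- tabulate(comp)
  first <- vapply(seq_along(sizes), function(cc) min(vox[comp == cc]), numeric(1))
  ord <- order(-sizes, first)
  relabel <- integer(length(sizes)); relabel[ord] <- seq_along(sizes)
  labels[vox] <- relabel[comp]
  labels
}

#' Cluster-level power table
#'
#' Summarises a power scan over the clusters of the full-group significant
#' set: voxel count, peak t and its location (0-based voxel indices and
#' world mm via the affine), the cluster's minimum detecting group size,
#' and per-size counts of safely detected voxels inside the cluster
#' footprint (the voxel-count-versus-group-size curves). Clusters are
#' ranked by their minimum group size: the cluster hierarchy by observable
#' effect size.
#'
#' @param powermap A `power_map` from [power_scan()].
#' @param labels Integer label array from [label_clusters()] applied to the
#'   full-group significant set (computed internally when omitted).
#' @param rule How a cluster inherits min_n from its member voxels:
#'   `"min"` (any member voxel safely detected; default), `"peak"` (the
#'   peak-t voxel's min_n), `"all"` (every member voxel, i.e. the maximum).
#' @param connectivity Used when `labels` is omitted.
#' @return Data frame, one row per cluster, ordered by `min_n` then
#'   decreasing size, with attribute `size_counts`: a cluster x size matrix
#'   of safely detected voxel counts.
#' @export
cluster_power_table <- function(powermap, labels = NULL,
                                rule = c("min", "peak", "all"),
                                connectivity = 26L) {
  rule <- match.arg(rule)
  full_vol <- unmask(powermap$full_significant, powermap$mask, fill = FALSE)
  if (is.null(labels)) labels <- label_clusters(full_vol, connectivity)
  if (!identical(dim(labels), dim(powermap$min_n)))
    stop_input("labels shape does not match the power map grid")
  if (any(labels > 0 & !full_vol))
    stop_input("labels must derive from the full-group significant set")

  tvol <- unmask(powermap$full_tmap$t, powermap$mask, fill = -Inf)
  mask_lin <- which(powermap$mask)    # mask voxel -> linear index
  n_cl <- max(labels)
  sizes <- powermap$sizes
  if (n_cl == 0L) {
    tab <- data.frame(cluster = integer(0), n_voxels = integer(0),
                      peak_t = numeric(0), peak_x = integer(0),
                      peak_y = integer(0), peak_z = integer(0),
                      peak_mm_x = numeric(0), peak_mm_y = numeric(0),
                      peak_mm_z = numeric(0), min_n = integer(0))
    attr(tab, "size_counts") <- matrix(0L, 0, length(sizes),
                                       dimnames = list(NULL, sizes))
    return(tab)
  }
  size_counts <- matrix(0L, nrow = n_cl, ncol = length(sizes),
                        dimnames = list(NULL, sizes))
  rows <- vector("list", n_cl)
  safe <- matrixStats_cumand(powermap$detection_fractions >= powermap$safe_threshold)

  for (cl in seq_len(n_cl)) {
    lin <- which(labels == cl)
    peak_lin <- lin[which.max(tvol[lin])]
    peak_ijk <- as.integer(arrayInd(peak_lin, dim(labels))) - 1L  # 0-based
    peak_mm <- as.numeric(powermap$affine %*% c(peak_ijk, 1))[1:3]
    member_minn <- powermap$min_n[lin]
    cl_minn <- switch(rule,
      min  = if (all(is.na(member_minn))) NA_integer_ else min(member_minn, na.rm = TRUE),
      all  = if (anyNA(member_minn)) NA_integer_ else max(member_minn),
      peak = powermap$min_n[peak_lin])
    mask_rows <- match(lin, mask_lin)
    size_counts[cl, ] <- colSums(safe[mask_rows, , drop = FALSE])
    rows[[cl]] <- data.frame(
      cluster = cl, n_voxels = length(lin),
      peak_t = tvol[peak_lin],
      peak_x = peak_ijk[1], peak_y = peak_ijk[2], peak_z = peak_ijk[3],
      peak_mm_x = peak_mm[1], peak_mm_y = peak_mm[2], peak_mm_z = peak_mm[3],
      min_n = cl_minn, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  ord <- order(tab$min_n, -tab$n_voxels, na.last = TRUE)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "size_counts") <- size_counts[ord, , drop = FALSE]
  tab
}
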