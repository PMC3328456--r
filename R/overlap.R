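#' Dice similarity index of two binary activation maps
#'
#' DSI = 2|A n B| / (|A| + |B|): twice the number of jointly significant
#' voxels divided by the summed sizes of the two significant sets. Ranges
#' from 1 (perfect overlap) to 0 (no overlap); 0 is also returned when
#' either map is empty, as a reduced design without significant voxels has
#' zero overlap by convention.
#'
#' @param a,b Logical arrays/vectors of equal shape, or `thresholded_map`
#'   objects.
#' @return The Dice index in [0, 1].
#' @examples
#' a <- array(FALSE, c(4, 4, 4)); a[1:2, 1, 1] <- TRUE
#' dice(a, a)  # 1
#' @export
dice <- function(a, b) {
  if (inherits(a, "thresholded_map")) a <- a$significant
  if (inherits(b, "thresholded_map")) b <- b$significant
  if (!identical(dim(a) %||% length(a), dim(b) %||% length(b)))
    stop_input("dice: maps have different shapes (%s vs %s)",
               paste(dim(a) %||% length(a), collapse = "x"),
               paste(dim(b) %||% length(b), collapse = "x"))
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0 || sa == 0 || sb == 0) return(0)
  2 * sum(a & b) / (sa + sb)
}

#' Dice similarity table for an L3 result
#'
#' One row per reduced design: the Dice index between the original
#' thresholded map and that design's map, together with the removed
#' subjects. With the default cap of 100 designs, each step yields (up to)
#' 100 DSI values.
#'
#' @param l3 An `l3_result` from [run_l3()].
#' @return Data frame with columns `step` (r), `design`, `removed_subjects`
#'   (comma-separated ids), `dsi`.
#' @export
dsi_table <- function(l3) {
  orig <- l3$original_map$significant
  vals <- vapply(l3$reduced_maps, function(m) dice(orig, m$significant), numeric(1))
  removed <- vapply(l3$plan$removed, paste, character(1), collapse = ",")
  data.frame(step = l3$plan$r, design = seq_along(vals),
             removed_subjects = removed, dsi = vals,
             stringsAsFactors = FALSE)
}

#' Summarise a DSI table per step
#'
#' @param tab A data frame from [dsi_table()] (possibly several steps
#'   row-bound together).
#' @return Data frame with `step`, `n_designs`, `median`, `q1`, `q3`.
#' @export
dsi_summary <- function(tab) {
  steps <- sort(unique(tab$step))
  do.call(rbind, lapply(steps, function(s) {
    x <- tab$dsi[tab$step == s]
    data.frame(step = s, n_designs = length(x), median = stats::median(x),
               q1 = unname(stats::quantile(x, 0.25)),
               q3 = unname(stats::quantile(x, 0.75)))
  }))
}

#' Build a group percent overlap map (gPOM)
#'
#' Combines the thresholded maps of all reduced designs of one step into a
#' single volume whose voxel value is the percentage of designs in which
#' that voxel is significant: with exactly 100 designs each reduced
#' analysis contributes 1%, and a value of 75 means the voxel was
#' significant in 75% of the reduced analyses. Percentages are rounded
#' half-up to integers; the raw per-voxel counts are kept alongside for
#' exactness.
#'
#' @param maps A list of logical volumes/vectors or `thresholded_map`
#'   objects sharing one shape, or an `l3_result` (whose reduced maps are
#'   used).
#' @param step Removal depth recorded in the result (taken from the
#'   `l3_result` when one is given).
#' @return Object of class `overlap_map` with fields `gpom` (integer
#'   percent array), `counts`, `n_designs`, `step`.
#' @export
build_gpom <- function(maps, step = NA_integer_) {
  if (inherits(maps, "l3_result")) {
    step <- maps$plan$r
    maps <- maps$reduced_maps
  }
  if (!length(maps)) stop_input("build_gpom: empty map list")
  vols <- lapply(maps, function(m) if (inherits(m, "thresholded_map"))
    significance_volume(m) else m)
  shp <- dim(vols[[1]]) %||% length(vols[[1]])
  for (v in vols[-1])
    if (!identical(dim(v) %||% length(v), shp))
      stop_input("build_gpom: maps have differing shapes")
  counts <- Reduce(`+`, lapply(vols, function(v) v * 1L))
  nd <- length(vols)
  gpom <- round_half_up(100 * counts / nd)
  storage.mode(gpom) <- "integer"
  structure(list(gpom = gpom, counts = counts, n_designs = nd,
                 step = as.integer(step)),
            class = "overlap_map")
}

#' @export
print.overlap_map <- function(x, ...) {
  cat(sprintf("overlap_map: %d designs, %d voxel(s) at 100%%, %d voxel(s) > 0%%\n",
              x$n_designs, sum(x$counts == x$n_designs), sum(x$counts > 0)))
  invisible(x)
}

#' Classify voxels of a gPOM into reliability classes
#'
#' Convention: a voxel significant in all reduced designs (100%) is "very
#' reliable" (class 3); in at least half but not all (50-99%) "reliable"
#' (class 2); in fewer than half but at least one (0-50%) "unreliable"
#' (class 1); never significant, class 0. The "very reliable" class uses
#' the exact design counts, not the rounded percentage, so 99.5% never
#' rounds up into it. The 50% boundary is classified "reliable" by default;
#' `boundary_reliable = FALSE` moves exactly-50% voxels to "unreliable"
#' (the strict majority reading).
#'
#' @param overlap An `overlap_map` from [build_gpom()].
#' @param boundary_reliable Include exactly-50% voxels in class 2
#'   (default TRUE).
#' @return Object of class `reliability_map`: `classes` (integer array with
#'   values 0-3) plus the class legend.
#' @export
classify_reliability <- function(overlap, boundary_reliable = TRUE) {
  frac <- 100 * overlap$counts / overlap$n_designs
  cls <- array(0L, dim(overlap$counts) %||% length(overlap$counts))
  at_least_half <- if (boundary_reliable) frac >= 50 else frac > 50
  cls[overlap$counts > 0] <- 1L
  cls[at_least_half & overlap$counts > 0] <- 2L
  cls[overlap$counts == overlap$n_designs] <- 3L
  structure(list(classes = cls,
                 legend = c(`0` = "not significant", `1` = "unreliable",
                            `2` = "reliable", `3` = "very reliable")),
            class = "reliability_map")
}

#' Compare DSI distributions from two sampling depths
#'
#' Two-sided Mann-Whitney U test between two sets of Dice indices (e.g.
#' runs with 100 vs 1000 reduced designs per step), with mid-rank tie
#' handling and Bonferroni correction over the number of scenario
#' comparisons performed. The exact null distribution of U is enumerated
#' when the number of group assignments is small; larger samples use the
#' normal approximation with tie correction.
#'
#' @param dsi_a,dsi_b Numeric vectors of DSI values (nonempty).
#' @param alpha Significance level (default 0.05).
#' @param n_comparisons Bonferroni multiplier (default 1).
#' @param exact_limit Enumerate the exact U distribution when
#'   `choose(n_a + n_b, n_a)` does not exceed this (default 2e5).
#' @return List with `U` (statistic for the first sample), `p` (corrected,
#'   capped at 1), `p_uncorrected`, `median_difference`
#'   (|median(a) - median(b)|), `significant` (p <= alpha), `exact`.
#' @export
compare_sampling_depth <- function(dsi_a, dsi_b, alpha = 0.05,
                                   n_comparisons = 1L, exact_limit = 2e5) {
  if (!length(dsi_a) || !length(dsi_b))
    stop_input("compare_sampling_depth: both samples must be nonempty")
  n1 <- length(dsi_a); n2 <- length(dsi_b)
  rk <- rank(c(dsi_a, dsi_b))            # mid-ranks on ties
  r1 <- sum(rk[seq_len(n1)])
  U <- r1 - n1 * (n1 + 1) / 2            # U statistic for sample a

  use_exact <- choose(n1 + n2, n1) <= exact_limit
  if (use_exact) {
    picks <- utils::combn(n1 + n2, n1)
    us <- colSums(matrix(rk[picks], nrow = n1)) - n1 * (n1 + 1) / 2
    p_lo <- mean(us <= U); p_hi <- mean(us >= U)
    p_unc <- min(1, 2 * min(p_lo, p_hi))
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(rk)
    tie_term <- sum(tie_tab^3 - tie_tab) / ((n1 + n2) * (n1 + n2 - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((n1 + n2 + 1) - tie_term))
    if (sigma == 0) {
      p_unc <- 1                         # all values tied
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sigma   # continuity correction
      p_unc <- min(1, 2 * stats::pnorm(abs(z), lower.tail = FALSE))
    }
  }
  p <- min(1, p_unc * n_comparisons)
  list(U = U, p = p, p_uncorrected = p_unc,
       median_difference = abs(stats::median(dsi_a) - stats::median(dsi_b)),
       significant = p <= alpha, exact = use_exact)
}
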