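#' Fit the second-level mass-univariate GLM on a subject subset
#'
#' Ordinary least squares of the subject contrast values on an intercept
#' plus mean-centered nuisance covariates, voxel by voxel over the analysis
#' mask. Covariates are re-centered within the subset so that every reduced
#' design is a self-contained second-level analysis. The default contrast
#' tests the intercept, i.e. the group-mean activation.
#'
#' @param maps A [subject_map_set()].
#' @param subset Integer indices of the subjects to include (default: all).
#' @param covariate_names Character vector naming numeric columns of
#'   `maps$covariates` to include as nuisance regressors (default: none).
#' @param contrast Numeric contrast vector over the design columns
#'   `(intercept, covariates...)`; default `c(1, 0, ...)`.
#' @return Object of class `tmap` with fields `t` (vector over mask voxels),
#'   `df`, `contrast`, `design_summary`, `mask`, `dim`, `affine`,
#'   `zero_var` (logical: voxels with zero residual variance, where `t` is
#'   set to 0 and flagged rather than left infinite).
#' @export
fit_second_level <- function(maps, subset = seq_len(nrow(maps$data)),
                             covariate_names = character(0),
                             contrast = NULL) {
  subset <- as.integer(subset)
  if (anyDuplicated(subset)) stop_input("subset contains duplicate subject indices")
  if (any(subset < 1L) || any(subset > nrow(maps$data)))
    stop_input("subset indices out of range 1..%d", nrow(maps$data))
  m <- length(subset)

  X <- matrix(1, nrow = m, ncol = 1, dimnames = list(NULL, "intercept"))
  if (length(covariate_names)) {
    if (is.null(maps$covariates))
      stop_input("covariates requested (%s) but the map set carries no covariate table",
                 paste(covariate_names, collapse = ", "))
    missing_cols <- setdiff(covariate_names, names(maps$covariates))
    if (length(missing_cols))
      stop_input("covariate column(s) not found: %s", paste(missing_cols, collapse = ", "))
    C <- as.matrix(maps$covariates[subset, covariate_names, drop = FALSE])
    storage.mode(C) <- "double"
    C <- scale(C, center = TRUE, scale = FALSE)    # re-centered within subset
    X <- cbind(X, C)
  }
  k <- ncol(X)
  if (is.null(contrast)) contrast <- c(1, rep(0, k - 1))
  if (length(contrast) != k)
    stop_input("contrast length %d does not match %d design columns",
               length(contrast), k)

  qrX <- qr(X)
  if (qrX$rank < k) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1):k]]
    stop_input("design error: rank-deficient design; dependent column(s): %s",
               paste(dep, collapse = ", "))
  }
  df <- m - k
  if (df <= 0)
    stop_input("design error: %d subjects leave no residual degrees of freedom for %d design columns",
               m, k)

  Y <- maps$data[subset, as.logical(maps$mask), drop = FALSE]   # m x V
  XtXinv <- chol2inv(chol(crossprod(X)))
  beta <- XtXinv %*% crossprod(X, Y)                            # k x V
  rss <- colSums((Y - X %*% beta)^2)
  rss[rss < 0] <- 0
  cAc <- as.numeric(t(contrast) %*% XtXinv %*% contrast)
  sigma2 <- rss / df
  se <- sqrt(sigma2 * cAc)
  num <- as.numeric(contrast %*% beta)
  # zero residual variance up to accumulated rounding: residual energy
  # below ~eps^2 of the data energy cannot be distinguished from exact fit
  zero_var <- rss <= 1e-24 * colSums(Y^2) | !is.finite(se)
  tval <- numeric(length(num))
  tval[!zero_var] <- num[!zero_var] / se[!zero_var]
  if (any(zero_var))
    tval[zero_var] <- 0   # flagged; p_values() assigns p = 1 there

  structure(list(
    t = tval, df = df, contrast = contrast,
    design_summary = list(n = m, covariates = covariate_names, rank = qrX$rank),
    zero_var = zero_var, effect = num,
    mask = maps$mask, dim = maps$dim, affine = maps$affine
  ), class = "tmap")
}

#' @export
print.tmap <- function(x, ...) {
  cat(sprintf("tmap: n = %d, df = %d, %d mask voxels, max t = %.3f\n",
              x$design_summary$n, x$df, length(x$t), max(x$t)))
  invisible(x)
}

#' One-sided p-values for a second-level t-map
#'
#' Upper-tail Student-t p-values (activation inference), the convention for
#' directional contrasts such as language > visuospatial. Voxels flagged as
#' zero residual variance receive p = 1 so they can never reach
#' significance.
#'
#' @param tmap A `tmap` from [fit_second_level()].
#' @param two_sided If `TRUE`, two-sided p-values instead.
#' @return Numeric vector of p-values over mask voxels.
#' @export
p_values <- function(tmap, two_sided = FALSE) {
  p <- if (two_sided) 2 * stats::pt(abs(tmap$t), df = tmap$df, lower.tail = FALSE)
       else stats::pt(tmap$t, df = tmap$df, lower.tail = FALSE)
  if (any(tmap$zero_var)) {
    warning(sprintf("%d mask voxel(s) have zero residual variance; p set to 1",
                    sum(tmap$zero_var)), call. = FALSE)
    p[tmap$zero_var] <- 1
  }
  pmin(p, 1)
}

#' Threshold a voxelwise p-map with multiple-comparison control
#'
#' Supported methods: `uncorrected` (p <= alpha), `fwe_bonferroni`
#' (p <= alpha / number of mask voxels), `fdr_bh` (Benjamini-Hochberg
#' step-up over mask voxels), and `fwe_permutation` (one-sample sign-flip
#' max-t null distribution; a voxel is significant when its t exceeds the
#' (1 - alpha) quantile of the permutation maxima). Significance is closed
#' (p <= alpha).
#'
#' @param pvals Numeric p-value vector over mask voxels (from [p_values()]).
#' @param method One of `"uncorrected"`, `"fwe_bonferroni"`, `"fdr_bh"`,
#'   `"fwe_permutation"`.
#' @param alpha Significance level in (0, 1].
#' @param tmap Required for `fwe_permutation` (supplies t-values).
#' @param maps,subset Required for `fwe_permutation`: the data the `tmap`
#'   was fitted on, to generate sign-flipped refits.
#' @param n_perm Number of sign-flip permutations (default 999).
#' @param seed Seed for the permutation draw.
#' @param covariate_names Covariates used in the original fit (permutation
#'   refits use the same design).
#' @return Object of class `thresholded_map` with fields `significant`
#'   (logical over mask voxels), `method`, `alpha`, `n_tests`, `mask`,
#'   `dim`, `affine`.
#' @export
threshold_map <- function(pvals, method = c("uncorrected", "fwe_bonferroni",
                                            "fdr_bh", "fwe_permutation"),
                          alpha = 0.05, tmap = NULL, maps = NULL,
                          subset = NULL, n_perm = 999L, seed = 1L,
                          covariate_names = character(0)) {
  method <- match.arg(method)
  if (alpha <= 0 || alpha > 1) stop_input("alpha must be in (0, 1], got %g", alpha)
  m <- length(pvals)
  sig <- switch(method,
    uncorrected    = pvals <= alpha,
    fwe_bonferroni = pvals <= alpha / m,
    fdr_bh         = stats::p.adjust(pvals, method = "BH") <= alpha,
    fwe_permutation = {
      if (is.null(tmap) || is.null(maps))
        stop_input("fwe_permutation requires the tmap and the subject data (maps)")
      subset <- subset %||% seq_len(nrow(maps$data))
      maxt <- perm_max_t(maps, subset, covariate_names, tmap$contrast, n_perm, seed)
      crit <- stats::quantile(maxt, probs = 1 - alpha, type = 1, names = FALSE)
      tmap$t >= crit & !tmap$zero_var
    })
  ref <- tmap %||% maps
  structure(list(significant = sig, method = method, alpha = alpha, n_tests = m,
                 mask = ref$mask %||% NULL, dim = ref$dim %||% NULL,
                 affine = ref$affine %||% NULL),
            class = "thresholded_map")
}

# max-t distribution under the one-sample sign-flip null
perm_max_t <- function(maps, subset, covariate_names, contrast, n_perm, seed) {
  n <- length(subset)
  flips <- with_seed(seed, matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), nrow = n))
  vapply(seq_len(n_perm), function(b) {
    flipped <- maps
    flipped$data[subset, ] <- flips[, b] * maps$data[subset, ]
    tm <- fit_second_level(flipped, subset = subset,
                           covariate_names = covariate_names, contrast = contrast)
    max(tm$t)
  }, numeric(1))
}

#' Binary significance volume of a thresholded map
#'
#' @param x A `thresholded_map`.
#' @return Logical 3-D array (FALSE outside the mask).
#' @export
significance_volume <- function(x) {
  unmask(x$significant, x$mask, fill = FALSE)
}
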