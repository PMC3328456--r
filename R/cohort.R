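#' Specify a synthetic cohort of subject-level contrast maps
#'
#' A cohort is a set of per-subject 3-D contrast volumes sharing a common
#' activation template (a sum of isotropic Gaussian blobs) to which
#' independent per-subject Gaussian noise is added. Optionally, the last
#' `n_deviants` subjects have their finished maps sign-inverted, emulating
#' a deviant (outlier) subject whose activation pattern opposes the group's.
#'
#' @param grid_shape Integer vector of length 3: volume extents in voxels.
#' @param n_subjects Number of subjects (>= 2).
#' @param blobs List of blobs, each a list with elements `center` (voxel
#'   triple, 1-based), `amplitude` (peak contrast value, arbitrary units) and
#'   `sd` (isotropic spatial standard deviation in voxels). Blob kernels are
#'   truncated at 4 standard deviations.
#' @param noise_sd Between-subject standard deviation per voxel, in the same
#'   units as the blob amplitudes. `0` yields identical subjects.
#' @param covariates Optional data frame of per-subject nuisance values
#'   (one row per subject), or a positive integer asking for that many
#'   independent standard-normal nuisance columns.
#' @param n_deviants Number of subjects whose maps are sign-inverted
#'   (placed last in subject order and flagged in the manifest).
#' @param noise_smooth_sd Optional spatial Gaussian smoothing (in voxels)
#'   applied to each subject's noise field. Off (`0`) by default so that
#'   closed-form t-statistic expectations hold exactly at each voxel.
#' @param seed Integer seed; identical specs regenerate identical cohorts.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [simulate_cohort()]
#' @export
cohort_spec <- function(grid_shape = c(20L, 24L, 20L),
                        n_subjects = 39L,
                        blobs = default_blobs(),
                        noise_sd = 1,
                        covariates = NULL,
                        n_deviants = 0L,
                        noise_smooth_sd = 0,
                        seed = 1L) {
  spec <- structure(list(
    grid_shape = as.integer(grid_shape),
    n_subjects = as.integer(n_subjects),
    blobs = blobs,
    noise_sd = as.numeric(noise_sd),
    covariates = covariates,
    n_deviants = as.integer(n_deviants),
    noise_smooth_sd = as.numeric(noise_smooth_sd),
    seed = as.integer(seed)
  ), class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

#' Default activation geometry for simulated cohorts
#'
#' Three well-separated isotropic Gaussian foci with graded peak amplitudes,
#' mimicking a strong primary activation plus two progressively weaker
#' secondary foci (so that power scans recover a cluster hierarchy).
#' Amplitudes are in units of the between-subject noise standard deviation
#' (default 1), i.e. per-subject effect sizes d = 2.4, 1.7, 1.2 at the
#' peaks — chosen so that even the weakest focus is reliably significant in
#' a full-group family-wise-corrected map at the group sizes typically
#' simulated (n around 19-39), the precondition for ranking foci by the
#' group size at which they disappear.
#'
#' @return List of blob descriptors usable as the `blobs` field of
#'   [cohort_spec()].
#' @export
default_blobs <- function() {
  list(
    list(center = c(6L, 7L, 6L),    amplitude = 2.4, sd = 1.5),
    list(center = c(14L, 12L, 10L), amplitude = 1.7, sd = 1.5),
    list(center = c(10L, 19L, 15L), amplitude = 1.2, sd = 1.5)
  )
}

validate_cohort_spec <- function(spec) {
  if (length(spec$grid_shape) != 3L || any(spec$grid_shape < 1L))
    stop_input("invalid cohort spec: grid_shape must be 3 positive extents")
  if (spec$n_subjects < 2L)
    stop_input("invalid cohort spec: n_subjects must be >= 2 (got %d)", spec$n_subjects)
  if (spec$n_deviants < 0L || spec$n_deviants >= spec$n_subjects)
    stop_input("invalid cohort spec: n_deviants must satisfy 0 <= n_deviants < n_subjects")
  if (spec$noise_sd < 0)
    stop_input("invalid cohort spec: noise_sd must be >= 0")
  for (b in spec$blobs) {
    if (!all(c("center", "amplitude", "sd") %in% names(b)))
      stop_input("invalid cohort spec: each blob needs center, amplitude, sd")
    if (any(b$center < 1) || any(b$center > spec$grid_shape))
      stop_input("invalid cohort spec: blob center (%s) outside grid_shape (%s)",
                 paste(b$center, collapse = ","), paste(spec$grid_shape, collapse = ","))
    if (b$sd <= 0) stop_input("invalid cohort spec: blob sd must be > 0")
  }
  if (is.data.frame(spec$covariates) && nrow(spec$covariates) != spec$n_subjects)
    stop_input("invalid cohort spec: covariates has %d rows, expected n_subjects = %d",
               nrow(spec$covariates), spec$n_subjects)
  invisible(spec)
}

#' Noise-free activation template implied by a cohort spec
#'
#' @param spec A [cohort_spec()].
#' @return 3-D array: the sum of the spec's Gaussian blobs.
#' @export
blob_template <- function(spec) {
  dims <- spec$grid_shape
  tmpl <- array(0, dim = dims)
  for (b in spec$blobs) {
    r <- ceiling(4 * b$sd)                      # truncate kernel at 4 sd
    xs <- max(1L, b$center[1] - r):min(dims[1], b$center[1] + r)
    ys <- max(1L, b$center[2] - r):min(dims[2], b$center[2] + r)
    zs <- max(1L, b$center[3] - r):min(dims[3], b$center[3] + r)
    dx2 <- (xs - b$center[1])^2
    dy2 <- (ys - b$center[2])^2
    dz2 <- (zs - b$center[3])^2
    d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
    tmpl[xs, ys, zs] <- tmpl[xs, ys, zs] + b$amplitude * exp(-d2 / (2 * b$sd^2))
  }
  tmpl
}

# separable Gaussian smoothing along each axis (kernel truncated at 4 sd);
# used only when noise_smooth_sd > 0
smooth_gaussian3d <- function(vol, sd) {
  if (sd <= 0) return(vol)
  r <- ceiling(4 * sd)
  k <- dnorm(-r:r, sd = sd)
  k <- k / sum(k)
  for (axis in 1:3) {
    vol <- apply(vol, setdiff(1:3, axis), function(v) {
      as.numeric(stats::filter(c(rep(0, r), v, rep(0, r)), k, sides = 2))[(r + 1):(r + length(v))]
    })
    vol <- aperm(vol, order(c(axis, setdiff(1:3, axis))))
  }
  vol
}

#' Simulate a seeded synthetic cohort
#'
#' Generates `n_subjects` volumes, each the blob template plus independent
#' Gaussian noise, then sign-inverts the complete finished maps of the last
#' `n_deviants` subjects. Inversion acts on the finished map (template plus
#' noise), so a deviant's volume is the exact negation of the volume the same
#' seed would have produced for a non-deviant subject in that position.
#'
#' @param spec A [cohort_spec()].
#' @return A [subject_map_set()] with subject ids `sub-01`, `sub-02`, ...,
#'   a covariate table carrying an `is_deviant` flag, a unit-spacing affine,
#'   and an all-true mask.
#' @examples
#' set <- simulate_cohort(cohort_spec(grid_shape = c(8, 8, 8), n_subjects = 5,
#'                                    noise_sd = 0.5, seed = 42))
#' dim(set$data)
#' @export
simulate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  dims <- spec$grid_shape
  nvox <- prod(dims)
  n <- spec$n_subjects
  tmpl <- as.numeric(blob_template(spec))

  covs <- spec$covariates
  data <- with_seed(spec$seed, {
    noise <- matrix(stats::rnorm(n * nvox, sd = spec$noise_sd), nrow = n)
    if (spec$noise_smooth_sd > 0 && spec$noise_sd > 0) {
      for (i in seq_len(n)) {
        sm <- smooth_gaussian3d(array(noise[i, ], dim = dims), spec$noise_smooth_sd)
        # rescale to preserve the marginal voxel sd after smoothing
        noise[i, ] <- as.numeric(sm) * spec$noise_sd / stats::sd(as.numeric(sm))
      }
    }
    if (is.numeric(covs) && length(covs) == 1L) {
      covs <- as.data.frame(matrix(stats::rnorm(n * covs), nrow = n,
                                   dimnames = list(NULL, paste0("cov", seq_len(covs)))))
    }
    sweep(noise, 2, tmpl, `+`)
  })

  is_deviant <- rep(FALSE, n)
  if (spec$n_deviants > 0L) {
    idx <- (n - spec$n_deviants + 1L):n        # deviants placed last
    data[idx, ] <- -data[idx, ]
    is_deviant[idx] <- TRUE
  }

  ids <- sprintf("sub-%02d", seq_len(n))
  manifest <- data.frame(subject_id = ids, is_deviant = is_deviant,
                         stringsAsFactors = FALSE)
  if (is.data.frame(covs)) manifest <- cbind(manifest, covs)

  subject_map_set(data = data, dim = dims, subject_ids = ids,
                  mask = array(TRUE, dim = dims),
                  covariates = manifest,
                  affine = default_affine(dims))
}

# unit-spacing RAS affine centered on the volume, as a plausible default
# grid for synthetic data
default_affine <- function(dims) {
  m <- diag(4)
  m[1:3, 4] <- -(dims - 1) / 2
  m
}
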