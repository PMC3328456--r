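#' Construct an aligned set of subject contrast volumes
#'
#' The container holding everything a second-level analysis needs: the
#' subject-by-voxel data matrix, the voxel grid, an analysis mask, the
#' covariate table and the affine carried from the input headers.
#'
#' @param data Numeric matrix, subjects in rows, voxels in columns
#'   (column-major voxel order of the 3-D grid).
#' @param dim Integer vector of length 3: grid extents.
#' @param subject_ids Character vector of unique subject identifiers.
#' @param mask Logical 3-D array delimiting the analysis domain.
#' @param covariates Optional data frame, one row per subject.
#' @param affine 4x4 voxel-to-world matrix.
#' @return Object of class `subject_map_set` with fields `data`, `dim`,
#'   `subject_ids`, `mask`, `covariates`, `affine`.
#' @export
subject_map_set <- function(data, dim, subject_ids, mask,
                            covariates = NULL, affine = default_affine(dim)) {
  dim <- as.integer(dim)
  if (!is.matrix(data) || ncol(data) != prod(dim))
    stop_input("data must be an n x %d matrix matching grid %s",
               prod(dim), paste(dim, collapse = "x"))
  n <- nrow(data)
  if (length(subject_ids) != n || anyDuplicated(subject_ids))
    stop_input("subject_ids must be %d unique strings", n)
  if (!identical(base::dim(mask), dim))
    stop_input("mask shape (%s) does not equal volume shape (%s)",
               paste(base::dim(mask), collapse = "x"), paste(dim, collapse = "x"))
  if (!is.null(covariates)) {
    if (nrow(covariates) != n)
      stop_input("covariate table has %d rows but there are %d subjects",
                 nrow(covariates), n)
  }
  structure(list(data = data, dim = dim, subject_ids = as.character(subject_ids),
                 mask = array(as.logical(mask), dim), covariates = covariates,
                 affine = affine),
            class = "subject_map_set")
}

#' @export
print.subject_map_set <- function(x, ...) {
  cat(sprintf("subject_map_set: %d subjects, grid %s, %d mask voxels\n",
              nrow(x$data), paste(x$dim, collapse = "x"), sum(x$mask)))
  if (!is.null(x$covariates))
    cat("covariates:", paste(setdiff(names(x$covariates), c("subject_id", "is_deviant")),
                             collapse = ", "), "\n")
  invisible(x)
}

n_subjects <- function(maps) nrow(maps$data)

read_affine <- function(img) {
  structure(RNifti::xform(img, useQuaternionFirst = FALSE), imagedim = NULL)
}

#' Load subject contrast volumes into an aligned map set
#'
#' Reads NIfTI-1 volumes (optionally gzipped), validates that all share one
#' grid and affine, and assembles a [subject_map_set()]. A single 4-D file is
#' accepted and split along the fourth axis. Without an explicit mask, the
#' analysis mask keeps voxels whose values are finite for all subjects and
#' have non-zero variance across subjects.
#'
#' @param volume_paths Character vector of NIfTI paths (>= 2 volumes in
#'   total, counting 4-D frames).
#' @param covariate_path Optional TSV/CSV path with a header row, one row per
#'   subject; matched by a `subject_id` column when present, else by row
#'   order.
#' @param mask_path Optional NIfTI path; non-zero voxels define the mask.
#' @return A validated [subject_map_set()].
#' @export
load_map_set <- function(volume_paths, covariate_path = NULL, mask_path = NULL) {
  vols <- list(); ids <- character(0)
  for (p in volume_paths) {
    img <- RNifti::readNifti(p)
    arr <- as.array(img)
    base_id <- sub("\\.nii(\\.gz)?$", "", basename(p))
    if (length(dim(arr)) == 4L) {
      for (k in seq_len(dim(arr)[4])) {
        vols[[length(vols) + 1L]] <- list(arr = arr[, , , k], affine = read_affine(img), path = p)
        ids <- c(ids, sprintf("%s_%03d", base_id, k))
      }
    } else if (length(dim(arr)) == 3L) {
      vols[[length(vols) + 1L]] <- list(arr = arr, affine = read_affine(img), path = p)
      ids <- c(ids, base_id)
    } else {
      stop_input("volume %s is %d-D; expected 3-D or 4-D", p, length(dim(arr)))
    }
  }
  if (length(vols) < 2L) stop_input("need at least 2 subject volumes, got %d", length(vols))

  ref_dim <- dim(vols[[1]]$arr); ref_aff <- vols[[1]]$affine
  for (v in vols[-1]) {
    if (!identical(dim(v$arr), ref_dim))
      stop_input("alignment error: %s has shape %s but %s has shape %s",
                 v$path, paste(dim(v$arr), collapse = "x"),
                 vols[[1]]$path, paste(ref_dim, collapse = "x"))
    if (max(abs(v$affine - ref_aff)) > 1e-4)
      stop_input("alignment error: affine of %s differs from %s by more than 1e-4",
                 v$path, vols[[1]]$path)
  }
  data <- do.call(rbind, lapply(vols, function(v) as.numeric(v$arr)))
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_")

  if (!is.null(mask_path)) {
    mimg <- RNifti::readNifti(mask_path)
    marr <- as.array(mimg)
    if (!identical(dim(marr), ref_dim))
      stop_input("alignment error: mask shape %s does not match volume shape %s",
                 paste(dim(marr), collapse = "x"), paste(ref_dim, collapse = "x"))
    mask <- array(marr != 0, ref_dim)
  } else {
    finite <- colSums(!is.finite(data)) == 0L
    v <- rep(0, ncol(data)); v[finite] <- apply(data[, finite, drop = FALSE], 2, stats::var)
    mask <- array(finite & v > 0, ref_dim)
  }

  covs <- NULL
  if (!is.null(covariate_path)) {
    covs <- read_table_auto(covariate_path)
    if (nrow(covs) != length(vols))
      stop_input("covariate table %s has %d rows but %d subject volumes were loaded",
                 covariate_path, nrow(covs), length(vols))
    if ("subject_id" %in% names(covs)) {
      if (setequal(covs$subject_id, ids)) {
        covs <- covs[match(ids, covs$subject_id), , drop = FALSE]
        rownames(covs) <- NULL
      } else {
        ids <- as.character(covs$subject_id)  # manifest order defines ids
      }
    }
  }
  subject_map_set(data = data, dim = ref_dim, subject_ids = ids,
                  mask = mask, covariates = covs, affine = ref_aff)
}

read_table_auto <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
}

#' Write a 3-D volume as NIfTI-1
#'
#' Integer-valued volumes (gPOMs, reliability classes, labels, min-n maps)
#' are stored with an integer datatype; real-valued volumes (t-maps) as
#' floating point. The reference grid's affine is written into the sform.
#'
#' @param volume 3-D numeric/integer/logical array.
#' @param reference_grid A [subject_map_set()] or a list with `dim` and
#'   `affine` fields supplying the target grid.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param datatype `"auto"` picks `int32` for integer-valued input and
#'   `float64` otherwise; any RNifti datatype string overrides.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, reference_grid, path, datatype = "auto") {
  if (is.logical(volume)) volume <- array(as.integer(volume), dim(volume))
  if (!identical(as.integer(dim(volume)), as.integer(reference_grid$dim)))
    stop_input("volume shape (%s) does not match reference grid (%s)",
               paste(dim(volume), collapse = "x"),
               paste(reference_grid$dim, collapse = "x"))
  if (datatype == "auto")
    datatype <- if (is.integer(volume)) "int32" else "float64"
  img <- RNifti::asNifti(volume)
  aff <- reference_grid$affine
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Write a simulated cohort to disk
#'
#' One NIfTI volume per subject plus a TSV manifest with columns
#' `subject_id`, `is_deviant` and any covariates; the layout [load_map_set()]
#' reads back.
#'
#' @param maps A [subject_map_set()].
#' @param dir Output directory (created if needed).
#' @param gzip Write `.nii.gz` volumes (default) or plain `.nii`.
#' @return Character vector of the volume paths, invisibly; the manifest is
#'   written as `participants.tsv`.
#' @export
write_cohort <- function(maps, dir, gzip = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (gzip) ".nii.gz" else ".nii"
  paths <- file.path(dir, paste0(maps$subject_ids, ext))
  for (i in seq_along(paths)) {
    write_volume(array(maps$data[i, ], maps$dim), maps, paths[i], datatype = "float64")
  }
  man <- maps$covariates %||% data.frame(subject_id = maps$subject_ids)
  if (!"subject_id" %in% names(man))
    man <- cbind(data.frame(subject_id = maps$subject_ids), man)
  utils::write.table(man, file.path(dir, "participants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

# logical 3-D array from mask-voxel vector
unmask <- function(values, mask, fill = 0) {
  out <- array(fill, dim(mask))
  out[mask] <- values
  out
}
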