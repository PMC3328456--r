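#' Assemble a run configuration
#'
#' Collects every knob of a reliability/power run into one serializable
#' list; the configuration is echoed verbatim into the run manifest so a
#' run can be reproduced from its outputs alone.
#'
#' @param maps Paths to subject NIfTI volumes, or a [subject_map_set()].
#' @param covariates Optional covariate table path (TSV/CSV).
#' @param mask Optional mask volume path.
#' @param covariate_names Covariate columns used as nuisance regressors.
#' @param contrast Contrast vector (NULL = group mean).
#' @param method,alpha Threshold method and level.
#' @param remove Integer vector of removal depths for the L3 stage
#'   (empty to skip).
#' @param power Run the power scan (logical).
#' @param floor,safe_threshold Power-scan floor and required detection
#'   percentage.
#' @param cap Maximum reduced designs per step.
#' @param seed Master seed.
#' @param n_perm Permutations for the permutation FWE threshold.
#' @param out Output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(maps, covariates = NULL, mask = NULL,
                       covariate_names = character(0), contrast = NULL,
                       method = "fwe_bonferroni", alpha = 0.05,
                       remove = 1L, power = FALSE, floor = 12L,
                       safe_threshold = 100, cap = 100L, seed = 1L,
                       n_perm = 999L, out = "jackmap_out") {
  structure(list(maps = maps, covariates = covariates, mask = mask,
                 covariate_names = covariate_names, contrast = contrast,
                 method = method, alpha = alpha, remove = as.integer(remove),
                 power = isTRUE(power), floor = as.integer(floor),
                 safe_threshold = safe_threshold, cap = as.integer(cap),
                 seed = as.integer(seed), n_perm = as.integer(n_perm),
                 out = out),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: %s", path)
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop_input("unknown config key(s): %s", paste(unknown, collapse = ", "))
  do.call(run_config, y)
}

# filesystem-safe L3 descriptor: caret replaced by "p"
l3_tag <- function(n, r) sprintf("L3p%d-%d", n, r)

#' Run the full jackknife reliability / power pipeline
#'
#' Loads (or accepts) the subject map set, runs the L3 stage at every
#' requested removal depth (writing per-step gPOM and reliability-class
#' volumes, DSI tables and a design manifest) and optionally the power
#' scan (min-n volume, cluster table, voxel-count-versus-size curves), and
#' writes a JSON manifest recording the configuration, seeds, per-step
#' design lists and summary statistics.
#'
#' @param config A `run_config` (or path to a YAML config).
#' @return The manifest, invisibly; all artifacts are written under
#'   `config$out`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  maps <- if (inherits(config$maps, "subject_map_set")) config$maps
          else {
            if (!is.null(config$covariates) && !file.exists(config$covariates))
              stop_input("covariate file not found: %s", config$covariates)
            load_map_set(config$maps, covariate_path = config$covariates,
                         mask_path = config$mask)
          }
  n <- n_subjects(maps)
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("jackmap")),
    config = config[setdiff(names(config), "maps")],
    n_subjects = n, subject_ids = maps$subject_ids,
    n_mask_voxels = sum(maps$mask), steps = list())

  full_tmap <- fit_second_level(maps, covariate_names = config$covariate_names,
                                contrast = config$contrast)
  write_volume(unmask(full_tmap$t, maps$mask), maps,
               file.path(config$out, "tmap_full.nii.gz"), datatype = "float64")

  dsi_all <- NULL
  for (r in config$remove) {
    l3 <- run_l3(maps, r = r, method = config$method, alpha = config$alpha,
                 covariate_names = config$covariate_names,
                 contrast = config$contrast, cap = config$cap,
                 seed = derive_seed(config$seed, paste0("l3_r", r)),
                 n_perm = config$n_perm)
    tag <- l3_tag(n, r)
    gpom <- build_gpom(l3)
    rel <- classify_reliability(gpom)
    write_volume(gpom$gpom, maps, file.path(config$out, paste0("gpom_", tag, ".nii.gz")))
    write_volume(rel$classes, maps, file.path(config$out, paste0("classes_", tag, ".nii.gz")))
    tab <- dsi_table(l3)
    dsi_all <- rbind(dsi_all, tab)
    manifest$steps[[tag]] <- list(
      r = r, notation = l3$notation, c_max = l3$plan$c_max,
      n_designs = length(l3$plan$subsets), exhaustive = l3$plan$exhaustive,
      removed_subjects = lapply(l3$plan$removed, function(i) maps$subject_ids[i]),
      dsi_median = stats::median(tab$dsi),
      n_very_reliable = sum(gpom$counts == gpom$n_designs),
      n_significant_full = sum(l3$original_map$significant))
    message(sprintf("[jackmap] %s: %d designs, median DSI %.3f",
                    l3$notation, nrow(tab), stats::median(tab$dsi)))
  }
  if (!is.null(dsi_all))
    utils::write.table(dsi_all, file.path(config$out, "dsi.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  if (config$power) {
    pm <- power_scan(maps, method = config$method, alpha = config$alpha,
                     covariate_names = config$covariate_names,
                     contrast = config$contrast, floor = config$floor,
                     cap = config$cap, seed = derive_seed(config$seed, "power"),
                     safe_threshold = config$safe_threshold,
                     n_perm = config$n_perm)
    minn_out <- pm$min_n
    minn_out[is.na(minn_out)] <- 0L   # sentinel: not significant in full design
    write_volume(minn_out, maps, file.path(config$out, "min_n.nii.gz"))
    ctab <- cluster_power_table(pm)
    utils::write.table(ctab, file.path(config$out, "clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    counts <- attr(ctab, "size_counts")
    utils::write.csv(data.frame(cluster = ctab$cluster, counts,
                                check.names = FALSE),
                     file.path(config$out, "cluster_size_counts.csv"),
                     row.names = FALSE)
    manifest$power <- list(
      floor = pm$floor, safe_threshold = pm$safe_threshold,
      sizes = pm$sizes,
      clusters = ctab[, c("cluster", "n_voxels", "peak_t", "min_n")])
  }

  jsonlite::write_json(manifest, file.path(config$out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}
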