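#' Pipeline run configuration
#'
#' Bundles paths and parameters for [run_pipeline()]. Every analysis
#' parameter defaults to the method's standard value: 20th coefficient
#' percentile for the seed, z-threshold 0.2 for strong connections, 5000
#' map permutations and 10000 outcome permutations at full scale, 100
#' lambdas in `[1e-5, 1e5]`, 95% PCA variance, alpha 0.025 / 0.01 / 0.05
#' for paired / covariate / other voxelwise tests.
#'
#' @param bold_dir directory of 4D normative runs.
#' @param brain_mask_path brain mask NIfTI.
#' @param lesion_paths character vector of lesion NIfTI paths.
#' @param atlas_dir directory of per-network template maps (optional).
#' @param behaviour_path TSV of `subject<TAB>score` (optional).
#' @param out_dir output directory.
#' @param percentile,z_threshold,n_perm_map,n_perm_outcome,lambda_n,lambda_lo,
#'   lambda_hi,variance_threshold,alpha_paired,alpha_covariate,alpha,rng_seed
#'   analysis parameters (see Description).
#' @return a `run_config` list.
#' @export
run_config <- function(bold_dir, brain_mask_path, lesion_paths,
                       atlas_dir = NULL, behaviour_path = NULL,
                       out_dir = "pcfdc_out",
                       percentile = 20, z_threshold = 0.2,
                       n_perm_map = 5000, n_perm_outcome = 10000,
                       lambda_n = 100, lambda_lo = 1e-5, lambda_hi = 1e5,
                       variance_threshold = 0.95,
                       alpha_paired = 0.025, alpha_covariate = 0.01,
                       alpha = 0.05, rng_seed = 1) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full lesion network mapping pipeline
#'
#' Executes the stages in dependency order — load normative runs, build a
#' PC-FDC seed and the whole-lesion FDC seed per lesion, compute both
#' r-maps, score atlas assignment (NCI) when an atlas is given, and run the
#' behaviour prediction when a behaviour table is given — writing NIfTI maps
#' and JSON summaries under `out_dir`. Stages whose outputs already exist
#' are skipped unless `force = TRUE`; the manifest records every artifact
#' with the parameters and seed that produced it.
#'
#' @param config a [run_config()].
#' @param force recompute up-to-date stages?
#' @return the manifest (named list of artifact paths), invisibly; also
#'   written as `manifest.json`.
#' @export
run_pipeline <- function(config, force = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(parameters = config[setdiff(names(config),
                                               c("lesion_paths"))],
                   stages = list())
  brain <- binary_mask_from_file(config$brain_mask_path)
  bold_files <- sort(list.files(config$bold_dir, pattern = "\\.nii(\\.gz)?$",
                                full.names = TRUE))
  if (length(bold_files) < 3L)
    stop("stage load: need at least 3 normative runs in ", config$bold_dir)
  runs <- lapply(bold_files, read_bold, brain_mask = brain)
  atlas <- if (!is.null(config$atlas_dir)) read_atlas(config$atlas_dir)
  lesion_maps <- list()
  for (lp in config$lesion_paths) {
    tag <- sub("\\.nii(\\.gz)?$", "", basename(lp))
    seed_path <- file.path(config$out_dir, paste0(tag, "_seed.nii.gz"))
    rmap_path <- file.path(config$out_dir, paste0(tag, "_pcfdc_rmap.nii.gz"))
    fdc_path <- file.path(config$out_dir, paste0(tag, "_fdc_rmap.nii.gz"))
    report_path <- file.path(config$out_dir, paste0(tag, "_seed.json"))
    cached <- !force && all(file.exists(seed_path, rmap_path, fdc_path))
    if (!cached) {
      lesion <- tryCatch(binary_mask_from_file(lp), error = function(e)
        stop("stage seed failed for ", lp, ": ", conditionMessage(e)))
      seed <- pcfdc_seed(runs, lesion, percentile = config$percentile)
      write_volume(seed$mask, seed_path)
      pc1 <- attr(seed, "pc1")
      jsonlite::write_json(list(
        lesion = lp, seed_voxels = mask_count(seed$mask),
        lesion_voxels = mask_count(lesion),
        percentile = config$percentile,
        excluded_subjects = pc1$excluded_subjects,
        explained_variance_ratio = pc1$explained_variance_ratio),
        report_path, auto_unbox = TRUE, digits = NA)
      write_volume(lesion_network_map(runs, seed), rmap_path)
      write_volume(lesion_network_map(runs, fdc_seed(lesion)), fdc_path)
    }
    lesion_maps[[tag]] <- rmap_path
    manifest$stages[[paste0("seed_", tag)]] <-
      list(seed = seed_path, report = report_path, pcfdc_rmap = rmap_path,
           fdc_rmap = fdc_path, cached = cached)
  }
  if (!is.null(atlas)) {
    nci_path <- file.path(config$out_dir, "nci.json")
    cached <- !force && file.exists(nci_path)
    if (!cached) {
      rows <- lapply(names(lesion_maps), function(tag) {
        m <- network_map(read_volume(lesion_maps[[tag]])$values,
                         brain$grid, "rmap", brain_mask = brain)
        res <- nci(m, atlas)
        list(lesion = tag, winner = res$winner, winner_sc = res$winner_sc,
             nci = res$nci, undefined = res$undefined)
      })
      jsonlite::write_json(rows, nci_path, auto_unbox = TRUE, digits = NA)
    }
    manifest$stages$nci <- list(path = nci_path, cached = cached)
  }
  if (!is.null(config$behaviour_path)) {
    pred_path <- file.path(config$out_dir, "prediction.json")
    cached <- !force && file.exists(pred_path)
    if (!cached) {
      beh <- utils::read.delim(config$behaviour_path, sep = "\t")
      if (nrow(beh) != length(lesion_maps))
        stop("stage predict: behaviour table has ", nrow(beh),
             " rows but ", length(lesion_maps), " lesion maps exist")
      maps <- lapply(lesion_maps, function(p)
        network_map(read_volume(p)$values, brain$grid, "rmap",
                    brain_mask = brain))
      fit <- predict_behaviour(unname(maps), beh$score,
                               variance_threshold = config$variance_threshold,
                               grid = lambda_grid(config$lambda_n,
                                                  config$lambda_lo,
                                                  config$lambda_hi),
                               n_perm = config$n_perm_outcome,
                               rng_seed = config$rng_seed)
      jsonlite::write_json(list(
        r2 = fit$r2, r2_conventional = fit$r2_conventional,
        perm_p = fit$perm_p, n = length(fit$Y),
        n_components = ncol(fit$per_fold_weights),
        median_lambda = stats::median(fit$per_fold_lambda)),
        pred_path, auto_unbox = TRUE, digits = NA)
    }
    manifest$stages$prediction <- list(path = pred_path, cached = cached)
  }
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}

binary_mask_from_file <- function(path) {
  v <- read_volume(path)
  binary_mask(v$values, v$grid, strict = FALSE)
}
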