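#' Read a 3D NIfTI volume
#'
#' Values are returned in the file's native voxel order with its affine
#' (sform preferred, per RNifti's `xform`). 4D files are rejected by this
#' entry point; use [read_bold()] for runs. No intensity normalization is
#' applied: values are treated as dimensionless.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return a [volume3d()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D volume, got ", length(d), "D: ", path)
  grid <- template_grid(d, unclass(RNifti::xform(img))[1:4, 1:4])
  volume3d(strip_nifti_attrs(img), grid)
}

#' Write a 3D volume or binary mask to NIfTI
#'
#' @param vol a [volume3d()] or [binary_mask()].
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, c("volume3d", "binary_mask")))
  write_nifti_array(vol$values, vol$grid, path)
}

strip_nifti_attrs <- function(img) {
  arr <- as.vector(img)
  dim(arr) <- dim(img)
  arr
}

write_nifti_array <- function(arr, grid, path) {
  aff <- grid$affine
  hdr <- list(srow_x = aff[1L, ], srow_y = aff[2L, ], srow_z = aff[3L, ],
              sform_code = 2L, qform_code = 0L,
              pixdim = c(-1, voxel_size(grid), rep(1, 4)))
  RNifti::writeNifti(RNifti::asNifti(arr, reference = hdr), path)
  invisible(path)
}

#' Read a 4D BOLD run
#'
#' The run must live on the same grid as `brain_mask`; a mismatch is an error
#' (no silent resampling). Non-finite values inside the brain mask raise an
#' error naming the offending voxel.
#'
#' @param path path to a 4D NIfTI file.
#' @param brain_mask a [binary_mask()] defining in-brain voxels.
#' @return a [bold_run()].
#' @export
read_bold <- function(path, brain_mask) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop("expected a 4D run, got ", length(d), "D: ", path)
  grid <- template_grid(d[1:3], unclass(RNifti::xform(img))[1:4, 1:4])
  stop_if_grid_mismatch(grid, brain_mask$grid, "BOLD file and brain mask")
  bold_run(strip_nifti_attrs(img), grid, brain_mask)
}

#' Write a BOLD run to a 4D NIfTI file
#'
#' @param run a [bold_run()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bold <- function(run, path) {
  stopifnot(inherits(run, "bold_run"))
  write_nifti_array(run$series, run$grid, path)
}

#' Nearest-neighbour resampling of a binary mask
#'
#' The only resampling utility in the package, and deliberately restricted to
#' binary masks: continuous maps and runs on mismatched grids are rejected at
#' the door so misalignment fails loudly. Each target voxel takes the value of
#' the source voxel nearest to it in world (mm) space; targets falling outside
#' the source lattice are 0.
#'
#' @param mask a [binary_mask()].
#' @param target_grid a [template_grid()] to resample onto.
#' @return a [binary_mask()] on `target_grid`.
#' @export
resample_mask_nearest <- function(mask, target_grid) {
  stopifnot(inherits(mask, "binary_mask"), inherits(target_grid, "template_grid"))
  sh <- target_grid$shape
  ijk <- as.matrix(expand.grid(i = seq_len(sh[1L]), j = seq_len(sh[2L]),
                               k = seq_len(sh[3L])))
  world <- target_grid$affine %*% rbind(t(ijk) - 1, 1)
  src <- solve(mask$grid$affine) %*% world        # 0-based source voxel coords
  src_ijk <- round(t(src[1:3, , drop = FALSE])) + 1
  inside <- src_ijk[, 1L] >= 1 & src_ijk[, 1L] <= mask$grid$shape[1L] &
    src_ijk[, 2L] >= 1 & src_ijk[, 2L] <= mask$grid$shape[2L] &
    src_ijk[, 3L] >= 1 & src_ijk[, 3L] <= mask$grid$shape[3L]
  out <- numeric(nrow(ijk))
  lin <- voxel_linear_index(src_ijk[inside, , drop = FALSE], mask$grid$shape)
  out[inside] <- mask$values[lin]
  binary_mask(array(out, dim = sh), target_grid)
}

#' Read a canonical network atlas
#'
#' Accepts either one labelled integer volume (`path` a file) plus a
#' tab-separated label file with `index<TAB>name` lines, or a directory of
#' per-network 3D maps (`path` a directory; every `.nii`/`.nii.gz` becomes one
#' network named after the file). Template maps may be binary or continuous;
#' they are used as intensities by [spatial_correlation()].
#'
#' @param path labelled volume file or directory of per-network maps.
#' @param labels path to the label file (required for a labelled volume).
#' @param exclude character vector of network names dropped from scoring
#'   (e.g. a limbic network susceptible to signal dropout).
#' @return a `canonical_atlas`: list with `networks` (named list of
#'   [volume3d()]) and `exclusions`.
#' @export
read_atlas <- function(path, labels = NULL, exclude = character()) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.nii(\\.gz)?$", full.names = TRUE))
    if (length(files) == 0L) stop("no NIfTI maps found in ", path)
    nets <- lapply(files, read_volume)
    names(nets) <- sub("\\.nii(\\.gz)?$", "", basename(files))
  } else {
    if (is.null(labels)) stop("a labelled atlas volume requires a `labels` file")
    vol <- read_volume(path)
    lab <- utils::read.delim(labels, header = FALSE, sep = "\t",
                             col.names = c("index", "name"),
                             stringsAsFactors = FALSE)
    nets <- lapply(lab$index, function(ix)
      volume3d(array(as.numeric(vol$values == ix), dim = vol$grid$shape), vol$grid))
    names(nets) <- lab$name
  }
  canonical_atlas(nets, exclude)
}

#' Construct an atlas from in-memory template maps
#'
#' @param networks named list of [volume3d()] (or [binary_mask()]) templates.
#' @param exclude names dropped from NCI scoring.
#' @return a `canonical_atlas`.
#' @export
canonical_atlas <- function(networks, exclude = character()) {
  if (is.null(names(networks)) || any(names(networks) == ""))
    stop("atlas networks must be named")
  networks <- lapply(networks, function(n) {
    if (inherits(n, "binary_mask")) volume3d(n$values, n$grid) else n
  })
  keep <- setdiff(names(networks), exclude)
  if (length(keep) < 2L)
    stop("atlas needs at least 2 networks after exclusions")
  g <- networks[[1L]]$grid
  for (n in networks) stop_if_grid_mismatch(g, n$grid, "atlas templates")
  structure(list(networks = networks, exclusions = exclude), class = "canonical_atlas")
}

#' @export
print.canonical_atlas <- function(x, ...) {
  cat("<canonical_atlas> ", length(x$networks), " networks (",
      paste(names(x$networks), collapse = ", "), ")",
      if (length(x$exclusions)) paste0("; excluded: ",
                                       paste(x$exclusions, collapse = ", ")),
      "\n", sep = "")
  invisible(x)
}

atlas_scored_networks <- function(atlas) {
  atlas$networks[setdiff(names(atlas$networks), atlas$exclusions)]
}
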