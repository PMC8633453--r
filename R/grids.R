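#' Template grid
#'
#' A `template_grid` fixes the sampling lattice shared by every volume in one
#' analysis: the number of voxels per axis and the 4x4 voxel-to-world affine.
#' All volumes, masks and BOLD runs entering a lesion network mapping analysis
#' must live on one identical grid (shape equal, affine equal within `tol`);
#' mismatching inputs are rejected rather than silently resampled, because
#' slight misalignments are a known silent failure mode of lesion seeding.
#'
#' @param shape integer vector of length 3, voxels per axis.
#' @param affine 4x4 voxel-to-world transform. Defaults to 2 mm isotropic
#'   spacing with the origin at the volume centre, the resolution at which
#'   lesions and normative runs are conventionally resampled in MNI space.
#' @return An object of class `template_grid` with fields `shape` and `affine`.
#' @seealso [voxel_size()], [same_grid()]
#' @export
template_grid <- function(shape, affine = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("`shape` must be 3 positive integers")
  if (is.null(affine)) {
    affine <- diag(c(2, 2, 2, 1))
    affine[1:3, 4] <- -(shape - 1) # centre the 2 mm lattice
  }
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)) || any(!is.finite(affine)))
    stop("`affine` must be a finite 4x4 matrix")
  structure(list(shape = shape, affine = affine), class = "template_grid")
}

#' @export
print.template_grid <- function(x, ...) {
  cat("<template_grid> ", paste(x$shape, collapse = " x "),
      " voxels, ", paste(signif(voxel_size(x), 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' Voxel size of a grid in mm
#'
#' Column norms of the rotation/scaling part of the affine.
#' @param grid a [template_grid()].
#' @return numeric length 3.
#' @export
voxel_size <- function(grid) {
  stopifnot(inherits(grid, "template_grid"))
  sqrt(colSums(grid$affine[1:3, 1:3]^2))
}

#' Test two grids for identity
#'
#' @param a,b [template_grid()] objects.
#' @param tol absolute tolerance on affine entries.
#' @return logical scalar.
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) && all(abs(a$affine - b$affine) < tol)
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop("grid mismatch between ", what,
         ": shapes ", paste(a$shape, collapse = "x"), " vs ",
         paste(b$shape, collapse = "x"),
         " or affines differ; resample explicitly if intended")
  invisible(TRUE)
}

#' Scalar 3D volume on a template grid
#'
#' @param values numeric 3D array matching `grid$shape`.
#' @param grid a [template_grid()].
#' @return object of class `volume3d` with fields `values`, `grid`.
#' @export
volume3d <- function(values, grid) {
  stopifnot(inherits(grid, "template_grid"))
  values <- as.array(values)
  if (!identical(as.integer(dim(values)), grid$shape))
    stop("value array shape ", paste(dim(values), collapse = "x"),
         " does not match grid shape ", paste(grid$shape, collapse = "x"))
  structure(list(values = values, grid = grid), class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat("<volume3d> ", paste(x$grid$shape, collapse = "x"),
      ", range [", signif(min(v), 4), ", ", signif(max(v), 4), "]\n", sep = "")
  invisible(x)
}

#' Binary mask on a template grid
#'
#' @param values array coercible to 0/1; anything nonzero becomes 1 when
#'   `strict = FALSE`, while `strict = TRUE` requires values already in
#'   \{0,1\}.
#' @param grid a [template_grid()].
#' @param strict reject values outside \{0,1\}?
#' @return object of class `binary_mask` with fields `values` (0/1 array),
#'   `grid`.
#' @export
binary_mask <- function(values, grid, strict = TRUE) {
  stopifnot(inherits(grid, "template_grid"))
  values <- as.array(values)
  if (!identical(as.integer(dim(values)), grid$shape))
    stop("mask shape does not match grid shape")
  if (any(!is.finite(values))) stop("mask contains non-finite values")
  if (strict && !all(values %in% c(0, 1)))
    stop("mask values must be 0 or 1")
  storage.mode(values) <- "double"
  values[values != 0] <- 1
  structure(list(values = values, grid = grid), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", paste(x$grid$shape, collapse = "x"), ", ",
      mask_count(x), " voxels set\n", sep = "")
  invisible(x)
}

#' Number of voxels set in a mask
#' @param mask a [binary_mask()].
#' @return integer scalar.
#' @export
mask_count <- function(mask) as.integer(sum(mask$values))

#' Canonical voxel ordering of a mask
#'
#' Returns the set voxels of a binary mask in the canonical ordering used for
#' every lesion-indexed vector and matrix in the package: lexicographic over
#' axes 1, 2, 3 (axis 3 varies fastest), i.e. C/"row-major" order over the
#' stored axes. Indices are 1-based, following R array convention. The
#' ordering is deterministic, so row k of any strength matrix or coefficient
#' vector built from this mask always refers to the same voxel.
#'
#' @param mask a [binary_mask()].
#' @return integer matrix with `mask_count(mask)` rows and columns `i,j,k`;
#'   zero rows for an empty mask.
#' @export
mask_voxel_indices <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  idx <- which(mask$values == 1, arr.ind = TRUE)
  colnames(idx) <- c("i", "j", "k")
  if (nrow(idx) == 0L) return(idx)
  idx[order(idx[, 1L], idx[, 2L], idx[, 3L]), , drop = FALSE]
}

# linear (column-major) array offsets for an i,j,k index matrix
voxel_linear_index <- function(idx, shape) {
  as.integer(idx[, 1L] + (idx[, 2L] - 1L) * shape[1L] +
               (idx[, 3L] - 1L) * shape[1L] * shape[2L])
}

#' Set operations on masks
#'
#' Elementwise intersection, union and difference of binary masks on one grid.
#' @param a,b [binary_mask()] objects on the same grid.
#' @return a [binary_mask()].
#' @export
mask_intersect <- function(a, b) {
  stop_if_grid_mismatch(a$grid, b$grid, "masks")
  binary_mask(a$values * b$values, a$grid)
}

#' @rdname mask_intersect
#' @export
mask_union <- function(a, b) {
  stop_if_grid_mismatch(a$grid, b$grid, "masks")
  binary_mask(pmin(a$values + b$values, 1), a$grid)
}

#' @rdname mask_intersect
#' @export
mask_diff <- function(a, b) {
  stop_if_grid_mismatch(a$grid, b$grid, "masks")
  binary_mask(pmax(a$values - b$values, 0), a$grid)
}

#' Build a mask from voxel indices
#'
#' @param idx integer matrix of 1-based `i,j,k` rows.
#' @param grid a [template_grid()].
#' @return a [binary_mask()].
#' @export
mask_from_indices <- function(idx, grid) {
  arr <- array(0, dim = grid$shape)
  if (NROW(idx) > 0L) arr[voxel_linear_index(as.matrix(idx), grid$shape)] <- 1
  binary_mask(arr, grid)
}

#' 4D BOLD run on a template grid
#'
#' One normative subject's resting-state run: a voxel x time series array plus
#' the brain mask inside which the series must be finite.
#'
#' @param series numeric 4D array `(i, j, k, t)`.
#' @param grid a [template_grid()].
#' @param brain_mask a [binary_mask()] on the same grid.
#' @return object of class `bold_run` with fields `series`, `grid`,
#'   `brain_mask`, `n_timepoints`.
#' @export
bold_run <- function(series, grid, brain_mask) {
  stopifnot(inherits(grid, "template_grid"), inherits(brain_mask, "binary_mask"))
  series <- as.array(series)
  if (length(dim(series)) != 4L)
    stop("BOLD series must be 4-dimensional, got ", length(dim(series)), "D")
  if (!identical(as.integer(dim(series)[1:3]), grid$shape))
    stop("BOLD spatial shape does not match grid")
  stop_if_grid_mismatch(grid, brain_mask$grid, "BOLD run and brain mask")
  nt <- dim(series)[4L]
  if (nt < 2L) stop("BOLD run must have at least 2 timepoints, got ", nt)
  idx <- mask_voxel_indices(brain_mask)
  if (nrow(idx) > 0L) {
    mat <- series_matrix_raw(series, idx)
    bad <- which(!is.finite(rowSums(mat)))
    if (length(bad) > 0L)
      stop("non-finite BOLD values inside the brain mask at voxel (",
           paste(idx[bad[1L], ], collapse = ","), ")",
           if (length(bad) > 1L) paste0(" and ", length(bad) - 1L, " more"))
  }
  structure(list(series = series, grid = grid, brain_mask = brain_mask,
                 n_timepoints = as.integer(nt)),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  cat("<bold_run> ", paste(x$grid$shape, collapse = "x"), " x ",
      x$n_timepoints, " timepoints, ", mask_count(x$brain_mask),
      " brain voxels\n", sep = "")
  invisible(x)
}

# voxels x time matrix for an index matrix, from a raw 4D array
series_matrix_raw <- function(series4d, idx) {
  d <- dim(series4d)
  flat <- series4d
  dim(flat) <- c(prod(d[1:3]), d[4L])
  flat[voxel_linear_index(idx, d[1:3]), , drop = FALSE]
}

#' Extract voxel x time series matrix for masked voxels
#'
#' Rows follow the canonical [mask_voxel_indices()] ordering of `mask`.
#' @param run a [bold_run()].
#' @param mask a [binary_mask()] on the run's grid.
#' @return numeric matrix, `mask_count(mask)` x `n_timepoints`.
#' @export
series_matrix <- function(run, mask) {
  stopifnot(inherits(run, "bold_run"))
  stop_if_grid_mismatch(run$grid, mask$grid, "run and mask")
  series_matrix_raw(run$series, mask_voxel_indices(mask))
}
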