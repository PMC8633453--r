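# shared in-code fixtures for the test suite

`%||%` <- function(a, b) if (is.null(a)) b else a

tiny_grid <- function(n = 4) template_grid(c(n, n, n))

full_mask <- function(grid) binary_mask(array(1, dim = grid$shape), grid)

# deterministic pure-noise maps on a small grid
noise_maps <- function(n_maps, grid, seed, sd = 1) {
  bm <- full_mask(grid)
  set.seed(seed)
  lapply(seq_len(n_maps), function(i)
    network_map(array(rnorm(prod(grid$shape), sd = sd), dim = grid$shape),
                grid, "rmap", brain_mask = bm))
}

# a bold_run built directly from a voxel x time matrix laid out over the
# first `nrow(mat)` voxels in canonical order, rest zeros outside brain
run_from_matrix <- function(mat, grid = NULL) {
  n <- nrow(mat); Tn <- ncol(mat)
  if (is.null(grid)) grid <- tiny_grid(max(2, ceiling(n^(1 / 3)) + 1))
  arr <- array(0, dim = c(grid$shape, Tn))
  brain <- array(0, dim = grid$shape)
  idx <- mask_voxel_indices(full_mask(grid))[seq_len(n), , drop = FALSE]
  for (v in seq_len(n)) {
    arr[idx[v, 1], idx[v, 2], idx[v, 3], ] <- mat[v, ]
    brain[idx[v, 1], idx[v, 2], idx[v, 3]] <- 1
  }
  list(run = bold_run(arr, grid, binary_mask(brain, grid)), idx = idx)
}

mask_of_indices <- function(idx, grid) mask_from_indices(idx, grid)

lin_idx <- function(idx, grid) {
  idx <- as.matrix(idx)
  as.integer(idx[, 1] + (idx[, 2] - 1) * grid$shape[1] +
               (idx[, 3] - 1) * grid$shape[1] * grid$shape[2])
}

# fraction of a mask's voxels that belong to a reference mask
mask_fraction_in <- function(mask, reference) {
  sum(mask$values * reference$values) / mask_count(mask)
}
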