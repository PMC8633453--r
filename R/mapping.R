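#' Network map container
#'
#' A whole-brain lesion network map: Fisher-z correlations (`kind = "rmap"`)
#' or t statistics (`kind = "tmap"`) per voxel, with its provenance.
#'
#' @param values 3D numeric array on `grid`.
#' @param grid a [template_grid()].
#' @param kind `"rmap"` or `"tmap"`.
#' @param seed the `seed_mask` the map was computed from (optional).
#' @param brain_mask the [binary_mask()] inside which values are defined;
#'   voxels outside are 0.
#' @param n_subjects_used number of normative subjects behind the map.
#' @return object of class `network_map`.
#' @export
network_map <- function(values, grid, kind = c("rmap", "tmap"), seed = NULL,
                        brain_mask = NULL, n_subjects_used = 1L) {
  kind <- match.arg(kind)
  v <- volume3d(values, grid)
  if (!is.null(brain_mask)) {
    stop_if_grid_mismatch(grid, brain_mask$grid, "map and brain mask")
    inb <- v$values[brain_mask$values == 1]
    if (any(!is.finite(inb)))
      stop("network map has non-finite values inside the brain mask")
  }
  structure(list(values = v$values, grid = grid, kind = kind, seed = seed,
                 brain_mask = brain_mask,
                 n_subjects_used = as.integer(n_subjects_used)),
            class = c("network_map", "volume3d"))
}

#' @export
print.network_map <- function(x, ...) {
  cat("<network_map:", x$kind, "> ", paste(x$grid$shape, collapse = "x"),
      ", ", x$n_subjects_used, " subject(s)\n", sep = "")
  invisible(x)
}

#' Mean seed time-course
#'
#' Arithmetic mean of the seed voxels' series at each timepoint; only seed
#' voxels inside the run's brain mask contribute.
#'
#' @param run a [bold_run()].
#' @param seed a `seed_mask` or [binary_mask()].
#' @return numeric vector of length `n_timepoints`.
#' @export
mean_seed_timecourse <- function(run, seed) {
  mask <- if (inherits(seed, "seed_mask")) seed$mask else seed
  use <- mask_intersect(mask, run$brain_mask)
  if (mask_count(use) == 0L)
    stop("seed has no voxels inside the brain mask")
  colMeans(series_matrix(run, use))
}

#' Single-subject seed correlation map
#'
#' Pearson r between the mean seed time-course and every brain voxel's
#' series, Fisher-z transformed. Voxels outside the brain mask are 0.
#' Zero-variance brain voxels get z = 0 with a warning (their correlation is
#' undefined, and zero keeps the map finite).
#'
#' @param run a [bold_run()].
#' @param seed a `seed_mask` or [binary_mask()].
#' @return a [network_map()] of kind `rmap` with `n_subjects_used = 1`.
#' @export
seed_correlation_map <- function(run, seed) {
  s <- mean_seed_timecourse(run, seed)
  if (stats::var(s) <= 0)
    stop("seed mean time-course has zero variance")
  idx <- mask_voxel_indices(run$brain_mask)
  M <- series_matrix_raw(run$series, idx)
  r <- row_cor(M, s)
  flat <- is.na(r)
  if (any(flat)) {
    warning(sum(flat), " zero-variance brain voxel(s) set to z = 0")
    r[flat] <- 0
  }
  z <- fisher_z(r, warn = FALSE)                  # seed voxels self-correlate
  arr <- array(0, dim = run$grid$shape)
  arr[voxel_linear_index(idx, run$grid$shape)] <- z
  network_map(arr, run$grid, "rmap",
              seed = if (inherits(seed, "seed_mask")) seed else NULL,
              brain_mask = run$brain_mask, n_subjects_used = 1L)
}

#' Average single-subject maps into an r-map
#'
#' Voxelwise arithmetic mean of Fisher-z maps across normative subjects.
#'
#' @param maps list of `network_map`s sharing grid and seed.
#' @return a [network_map()] of kind `rmap` with `n_subjects_used` set.
#' @export
average_rmap <- function(maps) {
  if (length(maps) < 1L) stop("need at least 1 map")
  g <- maps[[1L]]$grid
  for (m in maps) {
    stopifnot(inherits(m, "network_map"))
    stop_if_grid_mismatch(g, m$grid, "maps")
  }
  acc <- Reduce(`+`, lapply(maps, `[[`, "values")) / length(maps)
  network_map(acc, g, "rmap", seed = maps[[1L]]$seed,
              brain_mask = maps[[1L]]$brain_mask,
              n_subjects_used = sum(vapply(maps, `[[`, integer(1),
                                           "n_subjects_used")))
}

#' Compute a lesion network r-map across a normative cohort
#'
#' Convenience wrapper: one [seed_correlation_map()] per run, averaged.
#' @param runs list of [bold_run()]s.
#' @param seed a `seed_mask` or [binary_mask()].
#' @return a [network_map()] of kind `rmap`.
#' @export
lesion_network_map <- function(runs, seed) {
  average_rmap(lapply(runs, seed_correlation_map, seed = seed))
}

# ---- permutation engine -----------------------------------------------------

# one-sample t over columns of V x n matrix
.col_one_sample_t <- function(M, sq_sums = rowSums(M^2)) {
  n <- ncol(M)
  mu <- rowMeans(M)
  va <- pmax(sq_sums - n * mu^2, 0) / (n - 1)
  list(mu = mu, t = mu / sqrt(va / n), sd0 = va <= 0)
}

# max-statistic sign-flip null for a V x n matrix; returns t, fwe p (for |t|)
# first permutation is always the identity
signflip_fwe <- function(M, n_perm, rng_seed, sentinel = 1e10) {
  n <- ncol(M)
  sq <- rowSums(M^2)
  obs <- .col_one_sample_t(M, sq)
  t_obs <- obs$t
  # sd = 0 voxels: t 0 if mean 0 else signed sentinel; never enter the null max
  deg <- obs$sd0
  t_obs[deg] <- ifelse(abs(obs$mu[deg]) > 0, sign(obs$mu[deg]) * sentinel, 0)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(rng_seed))
  S <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), nrow = n)
  S[, 1L] <- 1                                    # identity permutation
  MU <- (M %*% S) / n                             # V x n_perm flipped means
  VA <- pmax(sq - n * MU^2, 0) / (n - 1)
  Tm <- MU / sqrt(VA / n)
  Tm[!is.finite(Tm)] <- 0
  Tm[deg, ] <- 0
  max_abs <- apply(abs(Tm), 2L, max)
  max_pos <- apply(Tm, 2L, max)
  fwe_two <- vapply(abs(t_obs), function(tt) mean(max_abs >= tt), numeric(1))
  fwe_pos <- vapply(t_obs, function(tt) mean(max_pos >= tt), numeric(1))
  fwe_neg <- vapply(-t_obs, function(tt) mean(max_pos >= tt), numeric(1))
  list(t = t_obs, fwe_two = fwe_two, fwe_pos = fwe_pos, fwe_neg = fwe_neg,
       degenerate = deg)
}

#' One-sample permutation t-map
#'
#' Voxelwise one-sample t over subject maps (`t = mean / (sd/sqrt(n))`), with
#' a sign-flipping permutation null: under the null of symmetric zero-mean
#' maps, flipping whole subject maps is exchangeable. Family-wise error is
#' controlled with the max-|t| distribution across voxels (the exact
#' voxelwise analogue of the permutation FWE in standard neuroimaging
#' nonparametric inference; no cluster enhancement is applied). The identity
#' permutation is always included in the null set, so FWE p-values are at
#' least `1/n_perm`. Voxels with zero sd across subjects get t = 0 when the
#' mean is 0, otherwise a signed sentinel excluded from the null maximum.
#'
#' @param maps list of >= 2 `network_map`s on one grid.
#' @param n_perm number of permutations (identity included).
#' @param rng_seed integer seed; results are bit-reproducible from it.
#' @param alpha significance level for the returned mask.
#' @return object of class `tmap_result`: list with `tmap` (a
#'   [network_map()] of kind `tmap`), `fwe_p` ([volume3d()] of two-sided FWE
#'   p), `significant` ([binary_mask()]), `alpha`, `n_perm`, `rng_seed`.
#' @export
one_sample_tmap <- function(maps, n_perm = 5000, rng_seed = 1, alpha = 0.05) {
  if (length(maps) < 2L) stop("need at least 2 subject maps")
  if (n_perm < 1L) stop("`n_perm` must be >= 1")
  g <- maps[[1L]]$grid
  bm <- maps[[1L]]$brain_mask
  for (m in maps) stop_if_grid_mismatch(g, m$grid, "maps")
  idx <- if (!is.null(bm)) mask_voxel_indices(bm) else
    mask_voxel_indices(binary_mask(array(1, dim = g$shape), g))
  lin <- voxel_linear_index(idx, g$shape)
  M <- vapply(maps, function(m) m$values[lin], numeric(length(lin)))
  res <- signflip_fwe(M, n_perm, rng_seed)
  to_vol <- function(v, fill = 0) {
    arr <- array(fill, dim = g$shape); arr[lin] <- v; arr
  }
  tmap <- network_map(to_vol(res$t), g, "tmap", seed = maps[[1L]]$seed,
                      brain_mask = bm, n_subjects_used = length(maps))
  structure(list(tmap = tmap,
                 fwe_p = volume3d(to_vol(res$fwe_two, fill = 1), g),
                 significant = binary_mask(
                   array(as.numeric(to_vol(res$fwe_two, fill = 1) <= alpha),
                         dim = g$shape), g),
                 alpha = alpha, n_perm = as.integer(n_perm),
                 rng_seed = as.integer(rng_seed)),
            class = "tmap_result")
}

#' @export
print.tmap_result <- function(x, ...) {
  cat("<tmap_result> ", x$tmap$n_subjects_used, " subjects, ", x$n_perm,
      " permutations, ", mask_count(x$significant),
      " voxels FWE-significant at alpha = ", x$alpha, "\n", sep = "")
  invisible(x)
}
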