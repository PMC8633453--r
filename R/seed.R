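#' Extract within-lesion time-series
#'
#' Pulls the BOLD series of every lesion voxel, in the canonical
#' [mask_voxel_indices()] ordering. Voxels outside the run's brain mask are
#' dropped and reported, as are zero-variance (flat) voxels, for which a
#' Pearson correlation is undefined.
#'
#' @param run a [bold_run()].
#' @param lesion a [binary_mask()] on the run's grid.
#' @return object of class `lesion_timeseries`: list with `voxel_order`
#'   (index matrix of surviving voxels), `series` (voxels x T matrix),
#'   `dropped_outside`, `dropped_constant` (index matrices).
#' @export
extract_lesion_timeseries <- function(run, lesion) {
  stopifnot(inherits(run, "bold_run"), inherits(lesion, "binary_mask"))
  stop_if_grid_mismatch(run$grid, lesion$grid, "run and lesion")
  idx <- mask_voxel_indices(lesion)
  if (nrow(idx) == 0L) stop("lesion mask is empty")
  inb <- run$brain_mask$values[voxel_linear_index(idx, run$grid$shape)] == 1
  if (!any(inb))
    stop("lesion has no voxels inside the brain mask; ",
         "check alignment of the lesion with the template grid")
  dropped_outside <- idx[!inb, , drop = FALSE]
  idx <- idx[inb, , drop = FALSE]
  mat <- series_matrix_raw(run$series, idx)
  v <- apply(mat, 1L, stats::var)
  flat <- v <= 0 | !is.finite(v)
  dropped_constant <- idx[flat, , drop = FALSE]
  structure(list(voxel_order = idx[!flat, , drop = FALSE],
                 series = mat[!flat, , drop = FALSE],
                 dropped_outside = dropped_outside,
                 dropped_constant = dropped_constant),
            class = "lesion_timeseries")
}

#' Within-lesion mean connectivity strength
#'
#' The per-voxel summary at the heart of the seed refinement: all pairwise
#' Pearson correlations among the lesion voxels' time-series are Fisher-z
#' transformed, and each voxel's strengths to the *other* lesion voxels are
#' averaged (the self-correlation, infinite after the z transform, is
#' excluded from its row average). Off-diagonal `|r| = 1` pairs are clipped
#' to `1 - 1e-7` with a warning.
#'
#' @param ts a `lesion_timeseries` from [extract_lesion_timeseries()], or a
#'   voxels x T numeric matrix.
#' @return numeric vector of length n (lesion voxels), aligned to the
#'   canonical voxel order.
#' @export
within_lesion_strength <- function(ts) {
  M <- if (inherits(ts, "lesion_timeseries")) ts$series else as.matrix(ts)
  n <- nrow(M)
  if (n < 2L) stop("need at least 2 lesion voxels, got ", n)
  C <- stats::cor(t(M))
  Z <- fisher_z(C * (1 - diag(n)), warn = TRUE)   # zero the diagonal first
  unname(rowSums(Z)) / (n - 1)                    # mean excluding self
}

#' Build the lesion connectivity-strength matrix across normative subjects
#'
#' For each normative run, computes [within_lesion_strength()] over the
#' lesion, giving an n (voxels) x m (subjects) matrix. Voxel validity is
#' harmonized by intersection: a voxel dropped for any subject (outside that
#' run's brain mask, or flat) is dropped for all, keeping the matrix
#' rectangular and the voxel order shared.
#'
#' @param runs list of >= 3 [bold_run()]s on one grid.
#' @param lesion a [binary_mask()].
#' @param subjects optional subject labels (defaults to `sub001`, ...).
#' @return object of class `strength_matrix`: list with `values` (n x m),
#'   `voxel_order`, `subjects`, `dropped` (index matrix of harmonized-out
#'   voxels).
#' @export
build_strength_matrix <- function(runs, lesion, subjects = NULL) {
  m <- length(runs)
  if (m < 3L) stop("need at least 3 normative subjects, got ", m)
  if (is.null(subjects)) subjects <- sprintf("sub%03d", seq_len(m))
  g <- runs[[1L]]$grid
  for (r in runs) stop_if_grid_mismatch(g, r$grid, "normative runs")
  tss <- lapply(runs, extract_lesion_timeseries, lesion = lesion)
  all_idx <- mask_voxel_indices(lesion)
  keys <- apply(all_idx, 1L, paste, collapse = ",")
  valid <- rep(TRUE, nrow(all_idx))
  for (ts in tss) {
    kept <- apply(ts$voxel_order, 1L, paste, collapse = ",")
    valid <- valid & keys %in% kept
  }
  if (sum(valid) < 2L)
    stop("fewer than 2 lesion voxels survive across all subjects")
  common <- all_idx[valid, , drop = FALSE]
  common_keys <- keys[valid]
  vals <- vapply(tss, function(ts) {
    kept <- apply(ts$voxel_order, 1L, paste, collapse = ",")
    within_lesion_strength(ts$series[match(common_keys, kept), , drop = FALSE])
  }, numeric(sum(valid)))
  vals <- matrix(vals, nrow = sum(valid), ncol = m)
  structure(list(values = vals, voxel_order = common, subjects = subjects,
                 dropped = all_idx[!valid, , drop = FALSE], grid = g,
                 lesion = lesion),
            class = "strength_matrix")
}

#' @export
print.strength_matrix <- function(x, ...) {
  cat("<strength_matrix> ", nrow(x$values), " voxels x ", ncol(x$values),
      " subjects (", nrow(x$dropped), " voxels harmonized out)\n", sep = "")
  invisible(x)
}

#' Exclude outlier normative subjects
#'
#' A subject whose global absolute lesion-connectivity strength (mean of
#' `|values|` in its column) deviates from the sample mean by more than
#' `k_sd` sample standard deviations is removed before PCA, protecting the
#' first component from single-brain outliers. With zero spread across
#' subjects nothing is excluded.
#'
#' @param sm a `strength_matrix`.
#' @param k_sd exclusion threshold in standard deviations.
#' @return a `strength_matrix` with an `excluded_subjects` field listing
#'   removed labels.
#' @export
exclude_outlier_subjects <- function(sm, k_sd = 3) {
  stopifnot(inherits(sm, "strength_matrix"))
  if (ncol(sm$values) < 3L) stop("need at least 3 subjects")
  g <- colMeans(abs(sm$values))
  s <- stats::sd(g)
  out <- if (!is.finite(s) || s == 0 || !is.finite(k_sd)) rep(FALSE, length(g))
         else abs(g - mean(g)) > k_sd * s
  if (sum(!out) < 3L)
    stop("outlier exclusion would leave fewer than 3 subjects")
  sm$excluded_subjects <- c(sm$excluded_subjects, sm$subjects[out])
  sm$subjects <- sm$subjects[!out]
  sm$values <- sm$values[, !out, drop = FALSE]
  sm
}

#' First-component coefficients of the strength matrix
#'
#' PCA of the transposed strength matrix, with subjects as observations and
#' lesion voxels as variables. Variables are centred across subjects; no
#' variance scaling is applied (covariance PCA), preserving the amplitude
#' differences that let the first component concentrate on the coherent
#' (grey-matter) compartment. The returned coefficients are the requested
#' component's loadings, one per lesion voxel, i.e. the vector that is
#' back-projected into lesion space and thresholded by [threshold_seed()].
#' PCA signs being arbitrary, the sign is fixed so the coefficients correlate
#' non-negatively with the subject-mean strength vector.
#'
#' @param sm a `strength_matrix` (optionally after
#'   [exclude_outlier_subjects()]).
#' @param component component index (1 = main within-lesion connectivity
#'   axis; 2 exposes the secondary axis).
#' @return object of class `pc1_result`: list with `coefficients` (length
#'   n), `explained_variance_ratio` (descending, sums to 1),
#'   `excluded_subjects`, `voxel_order`, `grid`, `lesion`, `component`.
#' @export
pc1_coefficients <- function(sm, component = 1L) {
  stopifnot(inherits(sm, "strength_matrix"))
  n <- nrow(sm$values); m <- ncol(sm$values)
  if (n < 2L) stop("need at least 2 lesion voxels")
  if (m < 3L) stop("need at least 3 subjects")
  X <- t(sm$values)                               # subjects x voxels
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc)
  ev <- sv$d^2
  if (sum(ev) < 1e-24)
    stop("strength matrix has rank 0 after centring (all columns identical)")
  evr <- ev / sum(ev)
  if (component > length(sv$d) || ev[component] < 1e-24)
    stop("component ", component, " is degenerate for this matrix")
  coef <- sv$v[, component]
  mean_strength <- rowMeans(sm$values)
  s <- stats::sd(mean_strength)
  flip <- if (is.finite(s) && s > 0) {
    stats::cor(coef, mean_strength) < 0
  } else sum(coef) < 0
  if (isTRUE(flip)) coef <- -coef
  structure(list(coefficients = coef, explained_variance_ratio = evr,
                 excluded_subjects = sm$excluded_subjects %||% character(),
                 voxel_order = sm$voxel_order, grid = sm$grid,
                 lesion = sm$lesion, component = as.integer(component)),
            class = "pc1_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pc1_result <- function(x, ...) {
  cat("<pc1_result> component ", x$component, ", ",
      length(x$coefficients), " voxels, PC1 variance ratio ",
      signif(x$explained_variance_ratio[1L], 3),
      if (length(x$excluded_subjects))
        paste0(", excluded: ", paste(x$excluded_subjects, collapse = ", ")),
      "\n", sep = "")
  invisible(x)
}

#' Threshold component coefficients into a refined seed mask
#'
#' The cutoff is the given percentile (linear interpolation between order
#' statistics) of the absolute coefficients; voxels with absolute coefficient
#' *strictly greater* than the cutoff are kept. The default 20th percentile
#' discards the weakest fifth of the lesion along the first-component
#' gradient; 5/10/20/50/80 are the sweep values supported for sensitivity
#' analysis.
#'
#' @param pc1 a `pc1_result`.
#' @param lesion the parent [binary_mask()] lesion (defaults to the one
#'   recorded in `pc1`).
#' @param percentile percentile of `|coefficients|` in `[0, 100)`.
#' @return object of class `seed_mask`: list with `mask` ([binary_mask()]),
#'   `parent_lesion`, `percentile_used`.
#' @export
threshold_seed <- function(pc1, lesion = NULL, percentile = 20) {
  stopifnot(inherits(pc1, "pc1_result"))
  if (percentile < 0 || percentile >= 100)
    stop("`percentile` must lie in [0, 100)")
  lesion <- lesion %||% pc1$lesion
  a <- abs(pc1$coefficients)
  cutoff <- pctl(a, percentile)
  keep <- a > cutoff
  if (!any(keep))
    stop("empty seed: no absolute coefficient strictly exceeds the ",
         percentile, "th-percentile cutoff (all-tied coefficients?)")
  structure(list(mask = mask_from_indices(pc1$voxel_order[keep, , drop = FALSE],
                                          pc1$grid),
                 parent_lesion = lesion, percentile_used = percentile),
            class = "seed_mask")
}

#' Whole-lesion (FDC baseline) seed
#'
#' The baseline method seeds the entire lesion, with no refinement.
#' @param lesion a non-empty [binary_mask()].
#' @return a `seed_mask` with `percentile_used = NA`.
#' @export
fdc_seed <- function(lesion) {
  stopifnot(inherits(lesion, "binary_mask"))
  if (mask_count(lesion) < 1L) stop("lesion mask is empty")
  structure(list(mask = lesion, parent_lesion = lesion,
                 percentile_used = NA_real_),
            class = "seed_mask")
}

#' @export
print.seed_mask <- function(x, ...) {
  cat("<seed_mask> ", mask_count(x$mask), " of ",
      mask_count(x$parent_lesion), " lesion voxels",
      if (!is.na(x$percentile_used))
        paste0(" (|coef| > P", x$percentile_used, ")") else " (whole lesion)",
      "\n", sep = "")
  invisible(x)
}

#' One-call PC-FDC seed construction
#'
#' Convenience wrapper chaining [build_strength_matrix()],
#' [exclude_outlier_subjects()], [pc1_coefficients()] and
#' [threshold_seed()].
#'
#' @param runs list of normative [bold_run()]s.
#' @param lesion a [binary_mask()].
#' @param percentile coefficient percentile cutoff.
#' @param k_sd outlier-subject exclusion threshold.
#' @param component principal component index.
#' @return a `seed_mask`; the underlying `pc1_result` is attached as
#'   attribute `pc1`.
#' @export
pcfdc_seed <- function(runs, lesion, percentile = 20, k_sd = 3,
                       component = 1L) {
  sm <- build_strength_matrix(runs, lesion)
  sm <- exclude_outlier_subjects(sm, k_sd = k_sd)
  pc1 <- pc1_coefficients(sm, component = component)
  seed <- threshold_seed(pc1, lesion, percentile = percentile)
  attr(seed, "pc1") <- pc1
  seed
}
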