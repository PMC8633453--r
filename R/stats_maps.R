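#' CDF cut-off values of a network map
#'
#' Restricts a map to its strictly positive voxels (zero and negative values
#' masked out), optionally within a domain mask (GM, WM or whole brain), and
#' returns the value of the empirical distribution at each requested
#' percentile (linear interpolation). Used to compare the whole spectrum of
#' voxel correlation values between two mapping methods.
#'
#' @param map a `network_map` or [volume3d()].
#' @param percentiles percentiles in `[0, 100]`.
#' @param domain_mask optional [binary_mask()] restricting the voxel domain.
#' @return a [tibble::tibble()] with columns `percentile`, `value`.
#' @export
cdf_cutoff_values <- function(map, percentiles = c(10, 20, 50, 80, 90, 95, 99),
                              domain_mask = NULL) {
  v <- map$values
  if (!is.null(domain_mask)) {
    stop_if_grid_mismatch(map$grid, domain_mask$grid, "map and domain mask")
    v <- v[domain_mask$values == 1]
  }
  v <- v[is.finite(v) & v > 0]
  if (length(v) == 0L) stop("no strictly positive voxels in the domain")
  tibble::tibble(percentile = percentiles,
                 value = vapply(percentiles, function(p) pctl(v, p), numeric(1)))
}

#' Mean and SD of supra-threshold map values
#'
#' Statistics over voxels strictly above `z_threshold` (default 0: all
#' positive Fisher-z values; 0.2 isolates the strongest connections).
#'
#' @param map a `network_map` or [volume3d()].
#' @param z_threshold lower threshold (strict).
#' @param domain_mask optional [binary_mask()] restriction.
#' @return named list `mean`, `sd`, `n_voxels`; `NaN` statistics when no
#'   voxel survives.
#' @export
map_mean_sd <- function(map, z_threshold = 0, domain_mask = NULL) {
  v <- map$values
  if (!is.null(domain_mask)) {
    stop_if_grid_mismatch(map$grid, domain_mask$grid, "map and domain mask")
    v <- v[domain_mask$values == 1]
  }
  v <- v[is.finite(v) & v > z_threshold]
  if (length(v) == 0L) return(list(mean = NaN, sd = NaN, n_voxels = 0L))
  list(mean = mean(v), sd = if (length(v) > 1L) stats::sd(v) else 0,
       n_voxels = length(v))
}

#' Spatial correlation between a map and a template
#'
#' Pearson correlation over the domain voxels, treating templates as
#' intensities (binary templates count as 0/1 continuous).
#'
#' @param map,template [volume3d()]-like objects on one grid.
#' @param domain_mask [binary_mask()] defining the voxels scored.
#' @return correlation coefficient.
#' @export
spatial_correlation <- function(map, template, domain_mask) {
  stop_if_grid_mismatch(map$grid, template$grid, "map and template")
  stop_if_grid_mismatch(map$grid, domain_mask$grid, "map and domain mask")
  sel <- domain_mask$values == 1
  x <- map$values[sel]; y <- template$values[sel]
  if (stats::var(x) <= 0 || stats::var(y) <= 0)
    stop("zero variance within the domain mask")
  stats::cor(x, y)
}

#' Network confidence index (winner-take-all atlas assignment)
#'
#' Correlates a lesion network map with every scored atlas template over the
#' domain mask. The winner is the template with the highest spatial
#' correlation; the NCI is the winner's correlation divided by the mean of
#' the losing templates' correlations, a proxy for how specifically the map
#' matches one canonical network rather than all of them. When the losing
#' mean is not positive the ratio is reported as `NA` with
#' `undefined = TRUE` (the winner is still returned). Winner ties are broken
#' by atlas order.
#'
#' @param map a `network_map`.
#' @param atlas a `canonical_atlas`.
#' @param domain_mask [binary_mask()]; defaults to the map's brain mask.
#' @return object of class `nci_result`: list with `winner`, `winner_sc`,
#'   `losing_scs` (named numeric), `nci`, `undefined`.
#' @export
nci <- function(map, atlas, domain_mask = NULL) {
  stopifnot(inherits(atlas, "canonical_atlas"))
  domain_mask <- domain_mask %||% map$brain_mask
  if (is.null(domain_mask)) stop("no domain mask available for NCI scoring")
  nets <- atlas_scored_networks(atlas)
  scs <- vapply(nets, function(tpl) spatial_correlation(map, tpl, domain_mask),
                numeric(1))
  w <- which.max(scs)                              # ties: first in atlas order
  losing <- scs[-w]
  lm_ <- mean(losing)
  undefined <- !is.finite(lm_) || lm_ <= 0
  structure(list(winner = names(nets)[w], winner_sc = unname(scs[w]),
                 losing_scs = losing,
                 nci = if (undefined) NA_real_ else unname(scs[w]) / lm_,
                 undefined = undefined),
            class = "nci_result")
}

#' @export
print.nci_result <- function(x, ...) {
  cat("<nci_result> winner ", x$winner, " (sc ", signif(x$winner_sc, 4),
      "), NCI ", if (x$undefined) "undefined (losing mean <= 0)"
                 else signif(x$nci, 4), "\n", sep = "")
  invisible(x)
}

#' Dice overlap coefficient
#'
#' `2|A n B| / (|A| + |B|)` between two non-empty binary masks.
#' @param a,b [binary_mask()] objects on one grid.
#' @return value in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stop_if_grid_mismatch(a$grid, b$grid, "masks")
  na <- mask_count(a); nb <- mask_count(b)
  if (na == 0L || nb == 0L) stop("dice is undefined for an empty mask")
  2 * sum(a$values * b$values) / (na + nb)
}

#' White-matter fraction of a lesion
#'
#' `|lesion n WM| / |lesion|`. A lesion is classified as pure white matter
#' when the ratio strictly exceeds 0.9.
#'
#' @param lesion a non-empty [binary_mask()].
#' @param wm the WM [binary_mask()].
#' @param pure_threshold classification threshold (strict).
#' @return list with `ratio` and logical `pure_wm`.
#' @export
wm_ratio <- function(lesion, wm, pure_threshold = 0.9) {
  stop_if_grid_mismatch(lesion$grid, wm$grid, "lesion and WM mask")
  n <- mask_count(lesion)
  if (n == 0L) stop("lesion mask is empty")
  ratio <- sum(lesion$values * wm$values) / n
  list(ratio = ratio, pure_wm = ratio > pure_threshold)
}
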