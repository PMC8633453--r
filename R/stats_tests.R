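#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided test on paired differences. Zero differences are dropped (with a
#' message of how many). For `n <= exact_limit` remaining pairs the null
#' distribution of the positive-rank sum `W+` is enumerated exactly over all
#' `2^n` sign assignments, conditional on the observed mid-ranks (so ties are
#' handled exactly); above the limit a normal approximation with the
#' standard tie correction of the variance is used, without continuity
#' correction. The two-sided p is twice the smaller tail, capped at 1.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param exact_limit maximum n for exact enumeration.
#' @return list with `statistic` (`W+`), `z` (normal deviate, `NA` for the
#'   exact branch), `p_value`, `n` (pairs used), `method`.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_limit = 12L) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  d <- x - y
  d <- d[is.finite(d)]
  nz <- d != 0
  if (!any(nz)) stop("all paired differences are zero")
  if (any(!nz)) message(sum(!nz), " zero difference(s) dropped")
  d <- d[nz]
  n <- length(d)
  if (n < 3L) stop("need at least 3 non-zero paired differences, got ", n)
  r <- rank(abs(d))                               # mid-ranks for ties
  w_pos <- sum(r[d > 0])
  if (n <= exact_limit) {
    # exact null distribution of 2*W+ by convolution over doubled mid-ranks
    r2 <- as.integer(round(2 * r))
    probs <- numeric(sum(r2) + 1L)                # index = value of 2*W+ (0-based)
    probs[1L] <- 1
    for (rr in r2) {
      shifted <- c(numeric(rr), probs[seq_len(length(probs) - rr)])
      probs <- (probs + shifted) / 2
    }
    vals <- seq_along(probs) - 1L
    w2 <- round(2 * w_pos)
    p_ge <- sum(probs[vals >= w2])
    p_le <- sum(probs[vals <= w2])
    p <- min(1, 2 * min(p_ge, p_le))
    list(statistic = w_pos, z = NA_real_, p_value = p, n = n,
         method = "exact enumeration")
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w_pos - mu) / sqrt(sig2)
    list(statistic = w_pos, z = z,
         p_value = 2 * stats::pnorm(-abs(z)), n = n,
         method = "normal approximation, tie-corrected")
  }
}

#' Paired Cohen's d
#'
#' `d = mean(x - y) / sd(x - y)` with the sample (n-1) standard deviation.
#' @param x,y paired numeric vectors.
#' @return effect size.
#' @export
cohens_d_paired <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- x - y
  s <- stats::sd(d)
  if (!is.finite(s) || s == 0) stop("zero variance of paired differences")
  mean(d) / s
}

#' Friedman rank test across repeated conditions
#'
#' Rows are subjects, columns conditions; each row is mid-ranked and
#' \deqn{\chi^2_F = \frac{12}{n k (k+1)} \sum_j R_j^2 - 3 n (k+1)}
#' is referred to a chi-square with k-1 degrees of freedom. Fully tied rows
#' contribute the mid-rank `(k+1)/2` everywhere, so an all-tied matrix gives
#' statistic 0. (No tie-correction denominator is applied; the mid-ranks
#' themselves absorb ties.)
#'
#' @param values numeric matrix, subjects x conditions.
#' @return list with `statistic`, `df`, `p_value`, `n`, `k`.
#' @export
friedman_test <- function(values) {
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  if (n < 2L || k < 2L) stop("need >= 2 subjects and >= 2 conditions")
  R <- t(apply(values, 1L, rank))
  Rj <- colSums(R)
  stat <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  stat <- max(stat, 0)                            # guard tiny negative rounding
  list(statistic = stat, df = k - 1L,
       p_value = stats::pchisq(stat, df = k - 1L, lower.tail = FALSE),
       n = n, k = k)
}

# ---- voxelwise permutation tests -------------------------------------------

map_matrix <- function(maps, domain_mask) {
  lin <- voxel_linear_index(mask_voxel_indices(domain_mask),
                            domain_mask$grid$shape)
  vapply(maps, function(m) m$values[lin], numeric(length(lin)))
}

voxelwise_result <- function(stat, p, grid, domain_mask, alpha, n_perm,
                             rng_seed, extra = list()) {
  lin <- voxel_linear_index(mask_voxel_indices(domain_mask), grid$shape)
  fill <- function(v, bg) { a <- array(bg, dim = grid$shape); a[lin] <- v; a }
  out <- c(list(stat_map = volume3d(fill(stat, 0), grid),
                fwe_p_map = volume3d(fill(p, 1), grid),
                significant = binary_mask(array(as.numeric(fill(p, 1) <= alpha),
                                                dim = grid$shape), grid),
                alpha = alpha, n_perm = as.integer(n_perm),
                rng_seed = as.integer(rng_seed)),
           extra)
  structure(out, class = "voxelwise_test")
}

#' @export
print.voxelwise_test <- function(x, ...) {
  cat("<voxelwise_test> ", x$n_perm, " permutations, ",
      mask_count(x$significant), " voxels significant at FWE alpha = ",
      x$alpha, "\n", sep = "")
  invisible(x)
}

resolve_domain <- function(maps, domain_mask) {
  dm <- domain_mask %||% maps[[1L]]$brain_mask
  if (is.null(dm))
    dm <- binary_mask(array(1, dim = maps[[1L]]$grid$shape), maps[[1L]]$grid)
  dm
}

#' Paired voxelwise permutation test
#'
#' Voxelwise paired t on map differences with a sign-flipping null and
#' max-statistic FWE correction. Both one-sided contrasts (`a > b` and
#' `b > a`) are reported, each at `alpha` (the default 0.025 per contrast
#' corresponds to a two-tailed 0.05).
#'
#' @param maps_a,maps_b paired lists of `network_map`s, equal length >= 2.
#' @param n_perm permutations (identity included).
#' @param alpha per-contrast FWE level.
#' @param rng_seed integer seed.
#' @param domain_mask optional [binary_mask()]; defaults to the brain mask.
#' @return a `voxelwise_test` whose `stat_map` is the paired t (a - b);
#'   extra fields `fwe_p_pos`/`fwe_p_neg` and `significant_pos`/
#'   `significant_neg` carry the one-sided contrasts.
#' @export
paired_voxelwise_test <- function(maps_a, maps_b, n_perm = 5000, alpha = 0.025,
                                  rng_seed = 1, domain_mask = NULL) {
  if (length(maps_a) != length(maps_b))
    stop("paired map lists must have equal length")
  if (length(maps_a) < 2L) stop("need at least 2 pairs")
  g <- maps_a[[1L]]$grid
  dm <- resolve_domain(maps_a, domain_mask)
  A <- map_matrix(maps_a, dm); B <- map_matrix(maps_b, dm)
  res <- signflip_fwe(A - B, n_perm, rng_seed)
  lin <- voxel_linear_index(mask_voxel_indices(dm), g$shape)
  fill <- function(v, bg) { a <- array(bg, dim = g$shape); a[lin] <- v; a }
  voxelwise_result(res$t, res$fwe_two, g, dm, alpha, n_perm, rng_seed,
                   extra = list(
                     fwe_p_pos = volume3d(fill(res$fwe_pos, 1), g),
                     fwe_p_neg = volume3d(fill(res$fwe_neg, 1), g),
                     significant_pos = binary_mask(
                       array(as.numeric(fill(res$fwe_pos, 1) <= alpha),
                             dim = g$shape), g),
                     significant_neg = binary_mask(
                       array(as.numeric(fill(res$fwe_neg, 1) <= alpha),
                             dim = g$shape), g)))
}

#' Two-sample voxelwise permutation test
#'
#' Voxelwise pooled-variance two-sample t with a group-label permutation
#' null and max-|t| FWE correction.
#'
#' @param group_a,group_b lists of `network_map`s (>= 2 each).
#' @param n_perm permutations (identity included).
#' @param alpha FWE level.
#' @param rng_seed integer seed.
#' @param domain_mask optional [binary_mask()].
#' @return a `voxelwise_test` (stat is t for a - b, two-sided FWE p).
#' @export
two_sample_voxelwise_test <- function(group_a, group_b, n_perm = 5000,
                                      alpha = 0.05, rng_seed = 1,
                                      domain_mask = NULL) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 maps")
  g <- group_a[[1L]]$grid
  dm <- resolve_domain(group_a, domain_mask)
  M <- cbind(map_matrix(group_a, dm), map_matrix(group_b, dm))
  n <- na + nb
  sq <- rowSums(M^2); tot <- rowSums(M)
  two_t <- function(ia) {
    s1 <- rowSums(M[, ia, drop = FALSE]); m1 <- s1 / na
    m2 <- (tot - s1) / nb
    ss <- pmax(sq - na * m1^2 - nb * m2^2, 0)
    sp2 <- ss / (n - 2)
    tt <- (m1 - m2) / sqrt(sp2 * (1 / na + 1 / nb))
    tt[!is.finite(tt)] <- 0
    tt
  }
  t_obs <- two_t(seq_len(na))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(rng_seed))
  max_abs <- numeric(n_perm)
  max_abs[1L] <- max(abs(t_obs))                  # identity permutation
  for (p in seq_len(n_perm)[-1L])
    max_abs[p] <- max(abs(two_t(sample.int(n, na))))
  fwe <- vapply(abs(t_obs), function(tt) mean(max_abs >= tt), numeric(1))
  voxelwise_result(t_obs, fwe, g, dm, alpha, n_perm, rng_seed)
}

#' Voxelwise behaviour correlation with a lesion-size covariate
#'
#' Per voxel, regresses the map value on the behaviour score with lesion
#' size as nuisance covariate (plus intercept), testing the score
#' coefficient. The permutation null follows the Freedman-Lane scheme: the
#' data are residualized against the nuisance-only model, the residuals are
#' permuted across subjects, the nuisance fit is added back, and the full
#' model is refit, building the max-|t| FWE null.
#'
#' @param maps one `network_map` per subject.
#' @param scores behaviour score per subject.
#' @param lesion_sizes lesion volume per subject (nuisance).
#' @param n_perm permutations (identity included).
#' @param alpha FWE level (default stringent 0.01).
#' @param rng_seed integer seed.
#' @param domain_mask optional [binary_mask()].
#' @return a `voxelwise_test` (stat is t for the score coefficient).
#' @export
voxelwise_behaviour_correlation <- function(maps, scores, lesion_sizes,
                                            n_perm = 5000, alpha = 0.01,
                                            rng_seed = 1, domain_mask = NULL) {
  n <- length(maps)
  if (length(scores) != n || length(lesion_sizes) != n)
    stop("need one map, one score and one lesion size per subject")
  if (n < 5L) stop("need at least 5 subjects")
  if (stats::var(scores) <= 0) stop("scores are constant")
  X <- cbind(score = scores, size = lesion_sizes, intercept = 1)
  if (qr(X)$rank < 3L) stop("score and lesion size are collinear")
  g <- maps[[1L]]$grid
  dm <- resolve_domain(maps, domain_mask)
  Y <- map_matrix(maps, dm)                       # V x n
  Z <- X[, -1L, drop = FALSE]                     # nuisance: size + intercept
  Hz <- Z %*% solve(crossprod(Z), t(Z))
  Yf <- Y %*% t(Hz)                               # nuisance fit
  E <- Y - Yf                                     # nuisance residuals
  XtXinv <- solve(crossprod(X))
  c11 <- XtXinv[1L, 1L]
  score_t <- function(Ystar) {
    B <- Ystar %*% X %*% XtXinv                   # V x 3 coefficients
    rss <- pmax(rowSums(Ystar^2) - rowSums(B * (Ystar %*% X)), 0)
    tt <- B[, 1L] / sqrt(rss / (n - 3) * c11)
    tt[!is.finite(tt)] <- 0
    tt
  }
  t_obs <- score_t(Y)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(rng_seed))
  max_abs <- numeric(n_perm)
  max_abs[1L] <- max(abs(t_obs))
  for (p in seq_len(n_perm)[-1L]) {
    perm <- sample.int(n)
    max_abs[p] <- max(abs(score_t(Yf + E[, perm, drop = FALSE])))
  }
  fwe <- vapply(abs(t_obs), function(tt) mean(max_abs >= tt), numeric(1))
  voxelwise_result(t_obs, fwe, g, dm, alpha, n_perm, rng_seed)
}
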