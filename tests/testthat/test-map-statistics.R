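test_that("CDF cut-offs use positive values with linear interpolation", {
  g <- template_grid(c(5, 5, 4))
  vals <- array(0, dim = g$shape)
  vals[1:100] <- 1:100
  m <- network_map(vals, g, "rmap")
  out <- cdf_cutoff_values(m, percentiles = 50)
  expect_equal(out$value, 50.5)

  const <- network_map(array(0.4, dim = g$shape), g, "rmap")
  res <- cdf_cutoff_values(const)
  expect_true(all(res$value == 0.4))

  res2 <- cdf_cutoff_values(m)
  expect_true(all(diff(res2$value) >= 0))

  neg <- network_map(array(-1, dim = g$shape), g, "rmap")
  expect_error(cdf_cutoff_values(neg), "positive")
})

test_that("supra-threshold mean/sd follows the strict threshold", {
  g <- template_grid(c(3, 1, 1))
  m <- network_map(array(c(0.1, 0.3, -0.2), dim = c(3, 1, 1)), g, "rmap")
  r0 <- map_mean_sd(m, 0)
  expect_equal(r0$mean, 0.2)
  expect_equal(r0$n_voxels, 2L)
  r2 <- map_mean_sd(m, 0.2)
  expect_equal(r2$mean, 0.3)
  expect_equal(r2$n_voxels, 1L)
  expect_equal(r2$sd, 0)
  r9 <- map_mean_sd(m, 0.9)
  expect_equal(r9$n_voxels, 0L)
  expect_true(is.nan(r9$mean))
})

test_that("spatial correlation matches hand-computed Pearson r", {
  g <- template_grid(c(4, 1, 1))
  mk <- function(v) volume3d(array(v, dim = c(4, 1, 1)), g)
  dm <- binary_mask(array(1, dim = c(4, 1, 1)), g)
  # map (1,2,3,4) vs template (1,0,1,0): r = -1/sqrt(5)
  expect_equal(spatial_correlation(mk(1:4), mk(c(1, 0, 1, 0)), dm),
               -1 / sqrt(5), tolerance = 1e-12)
  expect_equal(spatial_correlation(mk(1:4), mk(1:4), dm), 1)
  expect_equal(spatial_correlation(mk(1:4), mk(-(1:4)), dm), -1)
  expect_error(spatial_correlation(mk(rep(1, 4)), mk(1:4), dm),
               "zero variance")
})

test_that("NCI implements the winner-take-all ratio with its edge cases", {
  g <- template_grid(c(4, 4, 4))
  dm <- full_mask(g)
  set.seed(70)
  base <- rnorm(64)
  mk_with_cor <- function(target) {
    # template with exact sample correlation `target` to base
    v <- resid(lm(rnorm(64) ~ base))
    v <- v / sd(v) * sqrt(1 - target^2)
    z <- (base - mean(base)) / sd(base) * target + v
    volume3d(array(z, dim = g$shape), g)
  }
  map <- network_map(array(base, dim = g$shape), g, "rmap", brain_mask = dm)
  atl <- canonical_atlas(list(w = mk_with_cor(0.6), l1 = mk_with_cor(0.1),
                              l2 = mk_with_cor(0.2), l3 = mk_with_cor(0.3)))
  res <- nci(map, atl, dm)
  expect_equal(res$winner, "w")
  expect_equal(res$winner_sc, 0.6, tolerance = 1e-10)
  expect_equal(res$nci, 0.6 / 0.2, tolerance = 1e-8)

  # scale invariance of the whole result
  map2 <- network_map(array(7.3 * base, dim = g$shape), g, "rmap",
                      brain_mask = dm)
  res2 <- nci(map2, atl, dm)
  expect_equal(res2$nci, res$nci, tolerance = 1e-10)
  expect_equal(res2$winner, res$winner)

  # all equal correlations: NCI = 1 (winner by atlas order)
  tpl <- mk_with_cor(0.4)
  atl_eq <- canonical_atlas(list(a = tpl, b = tpl, c = tpl))
  expect_equal(nci(map, atl_eq, dm)$nci, 1, tolerance = 1e-10)

  # non-positive losing mean: undefined flag, winner still reported
  atl_neg <- canonical_atlas(list(w = mk_with_cor(0.6),
                                  l1 = mk_with_cor(-0.3),
                                  l2 = mk_with_cor(-0.1)))
  res3 <- nci(map, atl_neg, dm)
  expect_true(res3$undefined)
  expect_true(is.na(res3$nci))
  expect_equal(res3$winner, "w")
  expect_equal(nrow(tidy(res3)), 3L)
})

test_that("dice coefficient is symmetric with the textbook formula", {
  g <- tiny_grid()
  idx <- mask_voxel_indices(full_mask(g))
  a <- mask_of_indices(idx[1:2, ], g)
  b <- mask_of_indices(idx[2:3, ], g)
  expect_equal(dice(a, b), 0.5)                   # |a|=2, |b|=2, overlap 1
  expect_equal(dice(a, b), dice(b, a))
  expect_equal(dice(a, a), 1)
  disj <- mask_of_indices(idx[5:6, ], g)
  expect_equal(dice(a, disj), 0)
  empty <- binary_mask(array(0, dim = g$shape), g, strict = FALSE)
  expect_error(dice(a, empty), "empty")
})

test_that("Wilcoxon signed-rank matches an exhaustive enumeration oracle", {
  # oracle: enumerate all 2^n sign assignments of the observed ranks
  oracle_p <- function(d) {
    r <- rank(abs(d))
    w_obs <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), length(d))))
    w_all <- signs %*% r
    2 * min(mean(w_all >= w_obs), mean(w_all <= w_obs))
  }
  # hand case: x = (1,2,3), y = 0 -> W+ = 6, two-sided p = 2/8
  res <- wilcoxon_signed_rank(c(1, 2, 3), c(0, 0, 0))
  expect_equal(res$statistic, 6)
  expect_equal(res$p_value, 0.25)

  set.seed(80)
  for (n in 4:8) {
    for (rep in 1:6) {
      d <- sample(-9:9, n, replace = TRUE)
      d <- d[d != 0]
      if (length(d) < 3) next
      res <- wilcoxon_signed_rank(d, rep(0, length(d)))
      expect_equal(res$p_value, min(1, oracle_p(d)), tolerance = 1e-12)
    }
  }

  # tie-free data agree with the reference implementation's exact branch
  set.seed(81)
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(wilcoxon_signed_rank(x, y)$p_value,
               wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value,
               tolerance = 1e-12)

  expect_error(wilcoxon_signed_rank(1:4, 1:4), "zero")
})

test_that("large-sample Wilcoxon is calibrated under the null", {
  set.seed(82)
  ps <- replicate(200, {
    x <- rnorm(25); y <- x + rnorm(25)            # paired, null shift
    wilcoxon_signed_rank(y, x)$p_value
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("paired Cohen's d uses the sample sd of differences", {
  expect_equal(cohens_d_paired(c(0, 2), c(0, 0)), 1 / sqrt(2),
               tolerance = 1e-12)
  expect_error(cohens_d_paired(c(1, 2, 3, 4), c(0, 1, 2, 3)), "zero variance")
  set.seed(83)
  y <- rnorm(30)
  expect_gt(abs(cohens_d_paired(y + 5 + rnorm(30, sd = 1e-3), y)), 100)
})

test_that("Friedman statistic matches the rank-sum formula", {
  # ranks always (1,2,3) over 3 subjects x 3 conditions: chi^2 = 6
  m <- rbind(c(1, 2, 3), c(10, 20, 30), c(0.1, 0.2, 0.3))
  res <- friedman_test(m)
  expect_equal(res$statistic, 6)
  expect_equal(res$df, 2L)
  expect_equal(res$p_value, pchisq(6, 2, lower.tail = FALSE))

  # all-tied rows give statistic 0
  expect_equal(friedman_test(matrix(1, 4, 3))$statistic, 0)

  # tie-free data agree with the reference implementation
  set.seed(84)
  mm <- matrix(rnorm(24), 6, 4)
  expect_equal(friedman_test(mm)$statistic,
               unname(friedman.test(mm)$statistic), tolerance = 1e-10)
})

test_that("paired voxelwise test finds planted offsets and is antisymmetric", {
  g <- template_grid(c(6, 6, 6))
  bm <- full_mask(g)
  roi <- array(0, dim = g$shape); roi[2:3, 2:3, 2:3] <- 1
  set.seed(90)
  mk_pair <- function() {
    base <- array(rnorm(216, sd = 0.3), dim = g$shape)
    jitter <- array(rnorm(216, sd = 0.2), dim = g$shape)
    a <- network_map(base + jitter + roi * 1.5, g, "rmap", brain_mask = bm)
    b <- network_map(base, g, "rmap", brain_mask = bm)
    list(a = a, b = b)
  }
  prs <- lapply(1:10, function(i) mk_pair())
  as_ <- lapply(prs, `[[`, "a"); bs <- lapply(prs, `[[`, "b")
  res <- paired_voxelwise_test(as_, bs, n_perm = 200, rng_seed = 3)
  sig <- mask_voxel_indices(res$significant_pos)
  expect_gt(nrow(sig), 0)
  expect_equal(mask_fraction_in(res$significant_pos, binary_mask(roi, g)), 1)

  swapped <- paired_voxelwise_test(bs, as_, n_perm = 200, rng_seed = 3)
  expect_equal(swapped$stat_map$values, -res$stat_map$values,
               tolerance = 1e-10)
  expect_identical(swapped$significant_neg$values, res$significant_pos$values)

  same <- paired_voxelwise_test(as_, as_, n_perm = 100, rng_seed = 1)
  expect_equal(mask_count(same$significant), 0L)
})

test_that("two-sample voxelwise test detects group differences, not nulls", {
  g <- template_grid(c(6, 6, 6))
  bm <- full_mask(g)
  roi <- array(0, dim = g$shape); roi[4:5, 4:5, 4:5] <- 1
  set.seed(91)
  ga <- lapply(1:8, function(i)
    network_map(array(rnorm(216, sd = 0.4), dim = g$shape) + roi * 1.5,
                g, "rmap", brain_mask = bm))
  gb <- lapply(1:8, function(i)
    network_map(array(rnorm(216, sd = 0.4), dim = g$shape), g, "rmap",
                brain_mask = bm))
  res <- two_sample_voxelwise_test(ga, gb, n_perm = 200, rng_seed = 5)
  expect_gt(mask_count(res$significant), 0)
  expect_equal(mask_fraction_in(res$significant, binary_mask(roi, g)), 1)

  # identical lists: t identically zero
  res0 <- two_sample_voxelwise_test(ga, ga, n_perm = 50, rng_seed = 5)
  expect_equal(max(abs(res0$stat_map$values)), 0)

  # null false-positive rate within the binomial envelope
  fp <- sum(replicate(30, {
    m <- lapply(1:8, function(i)
      network_map(array(rnorm(64), dim = c(4, 4, 4)), tiny_grid(), "rmap",
                  brain_mask = full_mask(tiny_grid())))
    r <- two_sample_voxelwise_test(m[1:4], m[5:8], n_perm = 100,
                                   rng_seed = i <- sample.int(1e6, 1))
    mask_count(r$significant) > 0
  }))
  expect_lte(fp, qbinom(0.975, 30, 0.05))
})

test_that("behaviour correlation regressor honours nuisance and invariance", {
  g <- template_grid(c(5, 5, 5))
  bm <- full_mask(g)
  n <- 12
  set.seed(92)
  target <- c(3, 3, 3)
  maps <- vector("list", n)
  scores <- rnorm(n)
  sizes <- runif(n, 20, 40)
  for (i in 1:n) {
    arr <- array(rnorm(125, sd = 0.2), dim = g$shape)
    # near-noise-free predictor (tiny jitter keeps the residual well-posed)
    arr[target[1], target[2], target[3]] <- scores[i] + rnorm(1, sd = 0.05)
    maps[[i]] <- network_map(arr, g, "rmap", brain_mask = bm)
  }
  res <- voxelwise_behaviour_correlation(maps, scores, sizes, n_perm = 100,
                                         rng_seed = 7)
  peak <- which(abs(res$stat_map$values) == max(abs(res$stat_map$values)),
                arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), target)

  shifted <- voxelwise_behaviour_correlation(maps, scores + 100, sizes,
                                             n_perm = 100, rng_seed = 7)
  expect_equal(shifted$stat_map$values, res$stat_map$values, tolerance = 1e-8)

  expect_error(voxelwise_behaviour_correlation(maps, rep(1, n), sizes, 10, 1),
               "constant")
})
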