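test_that("lesion time-series extraction drops out-of-brain and flat voxels", {
  set.seed(10)
  fx <- run_from_matrix(matrix(rnorm(4 * 20), 4, 20))
  g <- fx$run$grid
  les <- mask_of_indices(fx$idx[1:3, ], g)
  ts <- extract_lesion_timeseries(fx$run, les)
  expect_equal(dim(ts$series), c(3L, 20L))

  # lesion entirely outside the brain mask (grid has 27 voxels, brain the first 4)
  outside <- mask_of_indices(mask_voxel_indices(full_mask(g))[20:22, ], g)
  expect_error(extract_lesion_timeseries(fx$run, outside), "brain mask")

  # one of four voxels constant: 3 x T plus a report of the dropped voxel
  mat <- matrix(rnorm(4 * 20), 4, 20); mat[2, ] <- 5
  fx2 <- run_from_matrix(mat)
  les4 <- mask_of_indices(fx2$idx, fx2$run$grid)
  ts2 <- extract_lesion_timeseries(fx2$run, les4)
  expect_equal(dim(ts2$series), c(3L, 20L))
  expect_equal(unname(ts2$dropped_constant), unname(fx2$idx[2, , drop = FALSE]))
})

test_that("within-lesion strength averages Fisher-z excluding the diagonal", {
  # two orthogonal-in-sample voxels: r = 0, strength (0, 0)
  x <- c(1, -1, 1, -1); y <- c(1, 1, -1, -1)
  expect_equal(within_lesion_strength(rbind(x, y)), c(0, 0), tolerance = 1e-12)

  # three voxels with all pairwise r = 0.5: each entry atanh(0.5)
  S <- matrix(c(1, .5, .5, .5, 1, .5, .5, .5, 1), 3)
  L <- chol(S)
  set.seed(4)
  M <- t(t(L) %*% matrix(rnorm(3 * 2000), 3))
  M <- t(M)
  emp <- within_lesion_strength(M)
  C <- cor(t(M))
  expected <- sapply(1:3, function(i) mean(atanh(C[i, -i])))
  expect_equal(emp, expected, tolerance = 1e-10)

  # duplicate series: clipped with a warning, stays finite
  dup <- rbind(rnorm(30), 0)
  dup[2, ] <- dup[1, ]
  expect_warning(s <- within_lesion_strength(dup), "clipped")
  expect_true(all(is.finite(s)))
  expect_equal(s, rep(atanh(1 - 1e-7), 2))

  expect_error(within_lesion_strength(matrix(rnorm(10), 1)), "at least 2")
})

test_that("strength matrix harmonizes voxels by intersection across subjects", {
  set.seed(20)
  mats <- lapply(1:5, function(i) matrix(rnorm(10 * 30), 10, 30))
  fx <- lapply(mats, run_from_matrix)
  g <- fx[[1]]$run$grid
  les <- mask_of_indices(fx[[1]]$idx, g)
  runs <- lapply(fx, `[[`, "run")
  sm <- build_strength_matrix(runs, les)
  expect_equal(dim(sm$values), c(10L, 5L))

  # flatten one voxel for one subject only: dropped for all
  mats2 <- mats
  mats2[[3]][7, ] <- 1
  runs2 <- lapply(mats2, function(m) run_from_matrix(m)$run)
  sm2 <- build_strength_matrix(runs2, les)
  expect_equal(dim(sm2$values), c(9L, 5L))
  expect_equal(unname(sm2$dropped), unname(fx[[1]]$idx[7, , drop = FALSE]))

  # identical runs for all subjects: identical columns
  runs3 <- lapply(1:4, function(i) run_from_matrix(mats[[1]])$run)
  sm3 <- build_strength_matrix(runs3, les)
  expect_true(all(abs(sm3$values - sm3$values[, 1]) < 1e-12))
})

test_that("outlier-subject exclusion applies the 3-SD rule on |strength|", {
  set.seed(30)
  fake_sm <- function(vals) {
    structure(list(values = vals,
                   voxel_order = cbind(i = seq_len(nrow(vals)), j = 1, k = 1),
                   subjects = sprintf("s%02d", seq_len(ncol(vals))),
                   dropped = matrix(integer(), 0, 3),
                   grid = tiny_grid(), lesion = NULL),
              class = "strength_matrix")
  }
  # identical columns: sd 0 handled as "no exclusion"
  sm_id <- fake_sm(matrix(rep(rnorm(6), 5), 6, 5))
  expect_equal(ncol(exclude_outlier_subjects(sm_id)$values), 5L)

  # 10 ordinary subjects + 1 with huge values: exactly that one excluded
  ordinary <- matrix(rnorm(8 * 10, sd = 0.1) + 0.5, 8, 10)
  out <- exclude_outlier_subjects(fake_sm(cbind(ordinary, rep(50, 8))))
  expect_equal(out$excluded_subjects, "s11")
  expect_equal(ncol(out$values), 10L)
  # rule arithmetic, independently: |column mean| vs mean +- 3 sd
  gbar <- colMeans(abs(cbind(ordinary, rep(50, 8))))
  expect_true(abs(gbar[11] - mean(gbar)) > 3 * sd(gbar))
  expect_true(all(abs(gbar[1:10] - mean(gbar)) <= 3 * sd(gbar)))

  # k_sd = Inf returns the input unchanged
  sm_r <- fake_sm(matrix(rnorm(40), 8, 5))
  expect_equal(exclude_outlier_subjects(sm_r, k_sd = Inf)$values, sm_r$values)
})

test_that("PC1 coefficients match hand-computed eigenstructure", {
  fake_sm <- function(vals) {
    structure(list(values = vals,
                   voxel_order = cbind(i = seq_len(nrow(vals)), j = 1, k = 1),
                   subjects = sprintf("s%02d", seq_len(ncol(vals))),
                   dropped = matrix(integer(), 0, 3),
                   grid = tiny_grid(), lesion = NULL),
              class = "strength_matrix")
  }
  # rank-1: columns are multiples of one pattern
  pattern <- c(1, 2, 3, 4)
  sm1 <- fake_sm(outer(pattern, c(1, 2, 3, 5)))
  p1 <- pc1_coefficients(sm1)
  expect_equal(p1$explained_variance_ratio[1], 1, tolerance = 1e-12)
  expect_equal(abs(p1$coefficients / p1$coefficients[1]), pattern,
               tolerance = 1e-10)

  # 2 voxels x 3 subjects [[1,2,3],[2,4,6]]: loadings proportional to (1,2)/sqrt(5)
  sm2 <- fake_sm(rbind(c(1, 2, 3), c(2, 4, 6)))
  p2 <- pc1_coefficients(sm2)
  expect_equal(abs(p2$coefficients), c(1, 2) / sqrt(5), tolerance = 1e-10)
  # sign convention: non-negative correlation with the mean strength vector
  expect_gte(cor(p2$coefficients, rowMeans(sm2$values)), 0)

  # explained-variance ratios are a proper descending simplex
  set.seed(40)
  smr <- fake_sm(matrix(rnorm(60), 10, 6))
  pr <- pc1_coefficients(smr)
  expect_equal(sum(pr$explained_variance_ratio), 1, tolerance = 1e-9)
  expect_true(all(diff(pr$explained_variance_ratio) <= 1e-12))

  # rank-0 matrix errors
  expect_error(pc1_coefficients(fake_sm(matrix(1, 4, 4))), "rank 0")
})

test_that("subject order does not affect the PC1 coefficients", {
  set.seed(41)
  co <- demo_cohort(n_subjects = 6, n_timepoints = 60, rng_seed = 42)
  g <- co$runs[[1]]$grid
  les <- make_lesion(g, co$tissue, co$atlas[[1]], 6, 6, rng_seed = 1)
  p_fwd <- pc1_coefficients(build_strength_matrix(co$runs, les))
  p_rev <- pc1_coefficients(build_strength_matrix(rev(co$runs), les))
  expect_equal(p_fwd$coefficients, p_rev$coefficients, tolerance = 1e-10)
})

test_that("seed thresholding keeps strictly supra-percentile coefficients", {
  g <- tiny_grid()
  fake_pc1 <- function(coefs) {
    idx <- mask_voxel_indices(full_mask(g))[seq_along(coefs), , drop = FALSE]
    structure(list(coefficients = coefs,
                   explained_variance_ratio = 1,
                   excluded_subjects = character(),
                   voxel_order = idx, grid = g,
                   lesion = mask_of_indices(idx, g), component = 1L),
              class = "pc1_result")
  }
  # percentile 0 cutoff is the minimum; strict inequality drops the minimum
  s0 <- threshold_seed(fake_pc1(c(0.1, 0.2, 0.3)), percentile = 0)
  expect_equal(mask_count(s0$mask), 2L)

  # linear interpolation: P20 of (0.05,0.1,0.2,0.5,0.9) = 0.09, keeps 4
  s20 <- threshold_seed(fake_pc1(c(0.05, 0.1, 0.2, 0.5, 0.9)), percentile = 20)
  expect_equal(mask_count(s20$mask), 4L)
  expect_equal(s20$percentile_used, 20)

  # all-tied coefficients: nothing strictly exceeds the cutoff
  expect_error(threshold_seed(fake_pc1(rep(0.3, 5))), "empty seed")

  # nesting: every refined seed is a subset of its lesion, at every sweep value
  set.seed(50)
  pc <- fake_pc1(runif(20))
  for (p in c(5, 10, 20, 50, 80)) {
    s <- threshold_seed(pc, percentile = p)
    expect_equal(mask_fraction_in(s$mask, pc$lesion), 1)
    expect_lte(mask_count(s$mask), mask_count(pc$lesion))
  }
})

test_that("the FDC baseline seed is the whole lesion with provenance", {
  g <- tiny_grid()
  les <- mask_of_indices(mask_voxel_indices(full_mask(g))[1:10, ], g)
  s <- fdc_seed(les)
  expect_equal(mask_count(s$mask), 10L)
  expect_identical(s$mask$values, les$values)
  expect_identical(s$parent_lesion$values, les$values)
  expect_true(is.na(s$percentile_used))
  empty <- binary_mask(array(0, dim = g$shape), g, strict = FALSE)
  expect_error(fdc_seed(empty), "empty")
})
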