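#' PCA feature reduction of r-maps
#'
#' Observations are subjects, variables are brain voxels (centred across
#' subjects, no scaling). The smallest leading set of components whose
#' cumulative explained variance reaches `variance_threshold` is retained;
#' loadings are kept so reliable weights can be back-projected to the brain.
#'
#' @param maps list of >= 3 `network_map`s on one grid.
#' @param variance_threshold cumulative explained-variance target in (0, 1].
#' @param domain_mask optional [binary_mask()]; defaults to the maps' brain
#'   mask.
#' @return object of class `feature_matrix`: list with `scores` (subjects x
#'   components), `loadings` (voxels x components), `sdev`,
#'   `explained_variance_ratio`, `variance_retained`, `centre`, `voxel_lin`,
#'   `grid`, `subjects`.
#' @export
pca_reduce_maps <- function(maps, variance_threshold = 0.95,
                            domain_mask = NULL) {
  if (length(maps) < 3L) stop("need at least 3 maps")
  g <- maps[[1L]]$grid
  for (m in maps) stop_if_grid_mismatch(g, m$grid, "maps")
  dm <- resolve_domain(maps, domain_mask)
  M <- t(map_matrix(maps, dm))                    # subjects x voxels
  ctr <- colMeans(M)
  Mc <- sweep(M, 2L, ctr)
  sv <- svd(Mc)
  ev <- sv$d^2
  nd <- sum(ev > max(ev) * 1e-12)
  if (nd < 2L) stop("fewer than 2 non-degenerate components")
  evr <- ev[seq_len(nd)] / sum(ev[seq_len(nd)])
  k <- which(cumsum(evr) >= variance_threshold - 1e-12)[1L]
  if (is.na(k)) k <- nd
  keep <- seq_len(k)
  structure(list(scores = sv$u[, keep, drop = FALSE] %*%
                   diag(sv$d[keep], nrow = k),
                 loadings = sv$v[, keep, drop = FALSE],
                 sdev = sv$d[seq_len(nd)] / sqrt(max(1, nrow(M) - 1)),
                 explained_variance_ratio = evr,
                 variance_retained = sum(evr[keep]),
                 centre = ctr,
                 voxel_lin = voxel_linear_index(mask_voxel_indices(dm),
                                                g$shape),
                 grid = g,
                 subjects = sprintf("sub%03d", seq_along(maps))),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$scores), " subjects x ", ncol(x$scores),
      " components (", signif(100 * x$variance_retained, 4),
      "% variance)\n", sep = "")
  invisible(x)
}

#' Global z-normalization of a feature matrix
#'
#' Subtracts the single global mean and divides by the single global
#' (population) standard deviation of the whole score matrix — one scalar
#' pair for the matrix, not per column — so the relative scale of the
#' components is preserved.
#'
#' @param fm a `feature_matrix` or plain numeric matrix.
#' @return the same type of object with normalized scores.
#' @export
znormalize_features <- function(fm) {
  X <- if (inherits(fm, "feature_matrix")) fm$scores else as.matrix(fm)
  mu <- mean(X)
  sdg <- sqrt(mean((X - mu)^2))                   # population sd
  if (!is.finite(sdg) || sdg == 0) stop("zero global variance")
  Xn <- (X - mu) / sdg
  if (inherits(fm, "feature_matrix")) { fm$scores <- Xn; fm } else Xn
}

#' Closed-form ridge regression weights
#'
#' \eqn{W = (X^T X + \lambda I)^{-1} X^T Y}, with no intercept (features and
#' outcome are expected to be centred by their z-normalization).
#'
#' @param X feature matrix (n x p).
#' @param Y outcome vector (length n).
#' @param lambda non-negative regularization strength.
#' @return weight vector of length p.
#' @export
ridge_weights <- function(X, Y, lambda) {
  if (lambda < 0) stop("`lambda` must be >= 0")
  X <- as.matrix(X)
  p <- ncol(X)
  drop(solve(crossprod(X) + diag(lambda, p), crossprod(X, Y)))
}

#' Default regularization grid
#'
#' `n` logarithmically spaced values between `lo` and `hi` (defaults: 100
#' values in `[1e-5, 1e5]`).
#' @param n grid size.
#' @param lo,hi grid bounds.
#' @return increasing numeric vector.
#' @export
lambda_grid <- function(n = 100, lo = 1e-5, hi = 1e5) {
  10^seq(log10(lo), log10(hi), length.out = n)
}

# per-training-set spectral cache: X = U diag(d) V'
ridge_svd <- function(X) {
  sv <- svd(as.matrix(X))
  list(U = sv$u, d = sv$d, V = sv$v)
}

# leave-one-out squared prediction errors within a training set, for every
# lambda at once; exact for ridge via the hat-matrix identity
# e_i = (y_i - yhat_i) / (1 - h_ii)
loo_press <- function(cache, y, grid = NULL) {
  uy <- drop(crossprod(cache$U, y))               # r
  if (is.null(cache$F)) {
    F <- outer(cache$d^2, grid, function(d2, l) d2 / (d2 + l))  # r x L
    H <- (cache$U^2) %*% F                        # n x L diag of hat matrix
  } else { F <- cache$F; H <- cache$H }
  Yhat <- cache$U %*% (F * uy)                    # n x L
  denom <- 1 - H
  E <- (y - Yhat) / denom
  press <- colSums(E^2)
  press[cache$bad_lambda %||% apply(denom, 2L, function(cc) any(cc < 1e-12))] <- Inf
  press
}

ridge_fit_from_svd <- function(cache, y, lambda) {
  uy <- drop(crossprod(cache$U, y))
  drop(cache$V %*% (cache$d / (cache$d^2 + lambda) * uy))
}

#' Tune ridge lambda by leave-one-out error
#'
#' Evaluates the exact leave-one-out squared prediction error of ridge
#' regression on the training set for every grid value and returns the
#' minimizer (ties broken towards the smallest lambda).
#'
#' @param X_train,Y_train training data (>= 3 subjects).
#' @param grid candidate lambdas (see [lambda_grid()]).
#' @return list with `lambda` (the selected value) and `press` (the LOO
#'   error per grid value).
#' @export
tune_lambda <- function(X_train, Y_train, grid = lambda_grid()) {
  if (length(grid) < 1L) stop("empty lambda grid")
  if (NROW(X_train) < 3L) stop("need at least 3 training subjects")
  grid <- sort(grid)
  press <- loo_press(ridge_svd(X_train), Y_train, grid)
  list(lambda = grid[which.min(press)], press = press)
}

# fold caches shared across permutations: X never changes, only Y, so the
# per-lambda shrink factors F and hat diagonals H are precomputed per fold
loocv_cache <- function(X, grid) {
  X <- as.matrix(X)
  n <- nrow(X)
  lapply(seq_len(n), function(i) {
    cc <- c(ridge_svd(X[-i, , drop = FALSE]), list(x_test = X[i, ], holdout = i))
    cc$F <- outer(cc$d^2, grid, function(d2, l) d2 / (d2 + l))
    cc$H <- (cc$U^2) %*% cc$F
    cc$bad_lambda <- apply(1 - cc$H, 2L, function(x) any(x < 1e-12))
    cc
  })
}

loocv_run <- function(caches, Y, grid) {
  n <- length(caches)
  p <- length(caches[[1L]]$x_test)
  pred <- numeric(n); lam <- numeric(n)
  W <- matrix(0, n, p)
  for (i in seq_len(n)) {
    cc <- caches[[i]]
    y_tr <- Y[-i]
    press <- loo_press(cc, y_tr, grid)
    lam[i] <- grid[which.min(press)]
    W[i, ] <- ridge_fit_from_svd(cc, y_tr, lam[i])
    pred[i] <- sum(cc$x_test * W[i, ])
  }
  list(predictions = pred, per_fold_lambda = lam, per_fold_weights = W)
}

#' Coefficient of determination, prediction-mean convention
#'
#' Implements \eqn{R^2 = 1 - \sum (Y - Y')^2 / \sum (Y - \bar{Y'})^2} where
#' `Y'` are the predictions and \eqn{\bar{Y'}} is the *mean of the
#' predictions* — the convention used by the original prediction framework,
#' kept literally here. It can be negative, and differs from the textbook
#' definition whose denominator centres on the mean of the observations;
#' that variant is available with `conventional = TRUE`.
#'
#' @param Y observed outcomes.
#' @param Y_pred predicted outcomes.
#' @param conventional use the observed-mean denominator instead?
#' @return R-squared value.
#' @export
r_squared <- function(Y, Y_pred, conventional = FALSE) {
  if (length(Y) != length(Y_pred)) stop("length mismatch")
  if (length(Y) < 2L) stop("need at least 2 values")
  centre <- if (conventional) mean(Y) else mean(Y_pred)
  den <- sum((Y - centre)^2)
  if (den == 0) stop("zero denominator in R^2")
  1 - sum((Y - Y_pred)^2) / den
}

#' Nested leave-one-out ridge prediction
#'
#' For each subject i, the ridge lambda is tuned by an inner leave-one-out
#' loop over the remaining n-1 subjects ([tune_lambda()]), the model is fit
#' on those n-1, and subject i's outcome is predicted — so every prediction
#' is strictly out of sample.
#'
#' @param X feature matrix (n x p), typically globally z-normalized scores.
#' @param Y outcome vector (z-normalized by convention).
#' @param grid candidate lambdas.
#' @return object of class `ridge_prediction`: list with `predictions`,
#'   `per_fold_lambda`, `per_fold_weights` (n x p), `r2` (prediction-mean
#'   convention), `r2_conventional`, `Y`, `grid`.
#' @export
loocv_predict <- function(X, Y, grid = lambda_grid()) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 5L) stop("need at least 5 subjects, got ", n)
  if (length(Y) != n) stop("X and Y disagree on the number of subjects")
  if (stats::var(Y) <= 0) stop("outcome is constant")
  grid <- sort(grid)
  run <- loocv_run(loocv_cache(X, grid), Y, grid)
  structure(c(run, list(r2 = r_squared(Y, run$predictions),
                        r2_conventional = r_squared(Y, run$predictions,
                                                    conventional = TRUE),
                        Y = Y, grid = grid)),
            class = "ridge_prediction")
}

#' @export
print.ridge_prediction <- function(x, ...) {
  cat("<ridge_prediction> n = ", length(x$Y), ", R^2 = ", signif(x$r2, 4),
      if (!is.null(x$perm_p)) paste0(", permutation p = ", signif(x$perm_p, 4)),
      "\n", sep = "")
  invisible(x)
}

#' Permutation significance of the ridge prediction
#'
#' Permutes the outcome across subjects `n_perm` times, reruns the entire
#' nested LOOCV pipeline (including lambda tuning) for each permutation, and
#' reports `p = #(null R^2 > observed R^2) / n_perm` — the plain counting
#' rule, which can return 0; `add_one = TRUE` applies the small-sample
#' correction `(b + 1) / (n_perm + 1)`. Per-fold weights of the null models
#' are harvested for [reliable_weight_map()].
#'
#' @param X,Y,grid as in [loocv_predict()].
#' @param n_perm number of outcome permutations.
#' @param rng_seed integer seed; bit-reproducible.
#' @param add_one small-sample-corrected counting rule?
#' @param collect_null_weights keep the null per-fold weight matrices?
#' @return a `ridge_prediction` (the observed fit) with extra fields
#'   `perm_p`, `null_r2` (length `n_perm`) and, if requested,
#'   `null_weights` (`n_perm * n` x p matrix of pooled null fold weights).
#' @export
permutation_significance <- function(X, Y, grid = lambda_grid(),
                                     n_perm = 10000, rng_seed = 1,
                                     add_one = FALSE,
                                     collect_null_weights = FALSE) {
  if (n_perm < 1L) stop("`n_perm` must be >= 1")
  X <- as.matrix(X)
  grid <- sort(grid)
  caches <- loocv_cache(X, grid)
  run <- loocv_run(caches, Y, grid)
  obs <- structure(c(run, list(r2 = r_squared(Y, run$predictions),
                               r2_conventional = r_squared(Y, run$predictions,
                                                           conventional = TRUE),
                               Y = Y, grid = grid)),
                   class = "ridge_prediction")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(rng_seed))
  null_r2 <- numeric(n_perm)
  nw <- if (collect_null_weights)
    matrix(0, n_perm * nrow(X), ncol(X)) else NULL
  for (b in seq_len(n_perm)) {
    Yb <- Y[sample.int(length(Y))]
    rb <- loocv_run(caches, Yb, grid)
    null_r2[b] <- r_squared(Yb, rb$predictions)
    if (collect_null_weights)
      nw[(b - 1L) * nrow(X) + seq_len(nrow(X)), ] <- rb$per_fold_weights
  }
  hits <- sum(null_r2 > obs$r2)
  obs$perm_p <- if (add_one) (hits + 1) / (n_perm + 1) else hits / n_perm
  obs$null_r2 <- null_r2
  obs$null_weights <- nw
  obs
}

#' Reliable-weight brain map
#'
#' Averages the per-fold ridge weights across the LOOCV loops, tests each
#' component's fold-weight distribution against the pooled null fold-weight
#' distribution (two-sample t-test), controls the false discovery rate
#' across components with Benjamini-Hochberg, zeroes non-surviving
#' components, and back-projects the surviving averaged weights to voxel
#' space through the transposed PCA loadings.
#'
#' @param fit a `ridge_prediction` from [permutation_significance()] run
#'   with `collect_null_weights = TRUE` (or a plain n x p fold-weight
#'   matrix).
#' @param fm the `feature_matrix` whose loadings map components to voxels.
#' @param null_weights pooled null fold weights (rows x p); taken from
#'   `fit$null_weights` when omitted.
#' @param fdr_q FDR level across components.
#' @return a [volume3d()] brain map of reliable predictive weights;
#'   attributes `component_p`, `component_q`, `kept` expose the per-component
#'   test.
#' @export
reliable_weight_map <- function(fit, fm, null_weights = NULL, fdr_q = 0.05) {
  W <- if (inherits(fit, "ridge_prediction")) fit$per_fold_weights else
    as.matrix(fit)
  null_weights <- null_weights %||%
    (if (inherits(fit, "ridge_prediction")) fit$null_weights else NULL)
  if (is.null(null_weights))
    stop("null weight distributions missing; rerun permutation_significance",
         " with collect_null_weights = TRUE")
  stopifnot(inherits(fm, "feature_matrix"), ncol(W) == ncol(fm$loadings))
  p <- ncol(W)
  pvals <- vapply(seq_len(p), function(j) {
    o <- W[, j]; nl <- null_weights[, j]
    if (stats::sd(o) == 0 && stats::sd(nl) == 0) return(1)
    stats::t.test(o, nl)$p.value
  }, numeric(1))
  q <- stats::p.adjust(pvals, method = "BH")
  keep <- q <= fdr_q
  wbar <- colMeans(W)
  wbar[!keep] <- 0
  vox <- drop(fm$loadings %*% wbar)
  arr <- array(0, dim = fm$grid$shape)
  arr[fm$voxel_lin] <- vox
  out <- volume3d(arr, fm$grid)
  attr(out, "component_p") <- pvals
  attr(out, "component_q") <- q
  attr(out, "kept") <- keep
  out
}

#' End-to-end behaviour prediction from r-maps
#'
#' The full prediction workflow: PCA reduction of the subject r-maps at the
#' given variance threshold, global z-normalization of the component scores,
#' z-normalization of the outcome, nested LOOCV ridge prediction,
#' permutation significance, and (optionally) the FDR-reliable weight map.
#'
#' @param maps list of subject `network_map`s.
#' @param scores outcome vector (one per subject).
#' @param variance_threshold PCA variance retained.
#' @param grid lambda grid.
#' @param n_perm outcome permutations.
#' @param rng_seed integer seed.
#' @param weight_map also compute the reliable-weight brain map?
#' @param fdr_q FDR level for reliable weights.
#' @return a `ridge_prediction` with extra fields `features` (the
#'   `feature_matrix`) and, if requested, `reliable_map`.
#' @export
predict_behaviour <- function(maps, scores, variance_threshold = 0.95,
                              grid = lambda_grid(), n_perm = 1000,
                              rng_seed = 1, weight_map = FALSE,
                              fdr_q = 0.05) {
  fm <- znormalize_features(pca_reduce_maps(maps, variance_threshold))
  y <- drop(scale(scores))
  fit <- permutation_significance(fm$scores, y, grid = grid, n_perm = n_perm,
                                  rng_seed = rng_seed,
                                  collect_null_weights = weight_map)
  fit$features <- fm
  if (weight_map) fit$reliable_map <- reliable_weight_map(fit, fm, fdr_q = fdr_q)
  fit
}
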