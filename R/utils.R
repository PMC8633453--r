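#' Fisher z transform with clipping
#'
#' `atanh(r)` after clipping `|r|` to `1 - clip_eps`. Perfect correlations
#' (duplicate series) would otherwise map to infinity and poison every row
#' average downstream; clipping keeps them large but finite. A warning is
#' emitted whenever clipping fires.
#'
#' @param r numeric vector/matrix of correlations.
#' @param clip_eps clip margin; `|r|` is capped at `1 - clip_eps`.
#' @param warn emit a warning when clipping occurs?
#' @return transformed values, same shape as `r`.
#' @export
fisher_z <- function(r, clip_eps = 1e-7, warn = TRUE) {
  cap <- 1 - clip_eps
  hit <- is.finite(r) & abs(r) > cap
  if (any(hit)) {
    if (warn) warning(sum(hit), " correlation(s) with |r| > ", format(cap),
                      " clipped before Fisher z")
    r[hit] <- sign(r[hit]) * cap
  }
  atanh(r)
}

# percentile with the linear-interpolation convention (quantile type 7),
# shared by seed thresholding and CDF cut-offs
pctl <- function(x, p) stats::quantile(x, p / 100, type = 7, names = FALSE)

# fast row-wise Pearson r between each row of M (n x T) and vector s (T);
# rows with zero variance yield NA
row_cor <- function(M, s) {
  Tn <- length(s)
  s_c <- s - mean(s)
  M_c <- M - rowMeans(M)
  num <- as.vector(M_c %*% s_c)
  den <- sqrt(rowSums(M_c^2) * sum(s_c^2))
  ifelse(den > 0, num / den, NA_real_)
}
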