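#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a ridge prediction
#'
#' One row per subject: observed outcome, out-of-sample prediction and the
#' lambda selected in that subject's fold.
#'
#' @param x a `ridge_prediction`.
#' @param ... unused.
#' @return a [tibble::tibble()] with columns `subject`, `observed`,
#'   `predicted`, `lambda`.
#' @method tidy ridge_prediction
#' @export
tidy.ridge_prediction <- function(x, ...) {
  tibble::tibble(subject = seq_along(x$Y), observed = x$Y,
                 predicted = x$predictions, lambda = x$per_fold_lambda)
}

#' One-row summary of a ridge prediction
#'
#' @param x a `ridge_prediction`.
#' @param ... unused.
#' @return a [tibble::tibble()] with `n`, `n_components`, `r2`,
#'   `r2_conventional`, `perm_p`, `median_lambda`.
#' @export
glance.ridge_prediction <- function(x, ...) {
  tibble::tibble(n = length(x$Y),
                 n_components = ncol(x$per_fold_weights),
                 r2 = x$r2, r2_conventional = x$r2_conventional,
                 perm_p = x$perm_p %||% NA_real_,
                 median_lambda = stats::median(x$per_fold_lambda))
}

#' Tidy an NCI result
#'
#' One row per scored template with its spatial correlation, winner flag and
#' the confidence index.
#'
#' @param x an `nci_result`.
#' @param ... unused.
#' @return a [tibble::tibble()] with columns `network`, `spatial_correlation`,
#'   `winner`, `nci`.
#' @method tidy nci_result
#' @export
tidy.nci_result <- function(x, ...) {
  tibble::tibble(network = c(x$winner, names(x$losing_scs)),
                 spatial_correlation = c(x$winner_sc, unname(x$losing_scs)),
                 winner = c(TRUE, rep(FALSE, length(x$losing_scs))),
                 nci = x$nci)
}

#' Plot observed versus predicted outcomes
#'
#' @param object a `ridge_prediction`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot ridge_prediction
#' @export
autoplot.ridge_prediction <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "observed score", y = "LOOCV prediction",
                  subtitle = sprintf("R² = %.3f%s", object$r2,
                                     if (!is.null(object$perm_p))
                                       sprintf(", permutation p = %.3g",
                                               object$perm_p) else "")) +
    ggplot2::theme_minimal()
}

#' Plot an axial mosaic of a volume or network map
#'
#' Simple slice montage of the map values; mainly a quick-look aid for
#' synthetic grids.
#'
#' @param object a `network_map`, [volume3d()] or [binary_mask()].
#' @param slices axial (k) slice indices; defaults to four evenly spaced.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot volume3d
#' @export
autoplot.volume3d <- function(object, slices = NULL, ...) {
  sh <- object$grid$shape
  if (is.null(slices))
    slices <- unique(round(seq(1, sh[3L], length.out = 4)))
  df <- do.call(rbind, lapply(slices, function(k) {
    data.frame(i = rep(seq_len(sh[1L]), sh[2L]),
               j = rep(seq_len(sh[2L]), each = sh[1L]),
               k = k, value = as.vector(object$values[, , k]))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~k, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick") +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' @method autoplot binary_mask
#' @export
autoplot.binary_mask <- autoplot.volume3d

#' @method autoplot network_map
#' @export
autoplot.network_map <- autoplot.volume3d

#' @importFrom ggplot2 .data
NULL
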