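#' Principal component analysis for wide feature matrices
#'
#' Fits PCA on a training feature matrix with many more features than
#' subjects (`D >> N`), via the eigendecomposition of the `N x N` Gram matrix
#' of the (optionally standardized) centered data — algebraically identical
#' to the SVD route but much cheaper at this shape. Components with
#' eigenvalue below `tol` times the largest are treated as zero and dropped,
#' so at most `N - 1` components survive (the rank bound of centered data).
#'
#' @param x Numeric `N x D` training matrix, `N >= 3`.
#' @param standardize Scale each feature by its training standard deviation
#'   before PCA (default `TRUE`; constant features are left unscaled).
#' @param tol Relative zero-eigenvalue cutoff (default `1e-10`).
#' @return Object of class `hyfc_pca`: `center`, `scale`, `rotation`
#'   (`D x m` orthonormal loadings), `sdev` (singular values / sqrt(N - 1)),
#'   `scores` (`N x m` training projections).
#' @export
fit_pca <- function(x, standardize = TRUE, tol = 1e-10) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3L) {
    stop_hyfc("PCA needs at least 3 training subjects.", class = "insufficient_data")
  }
  center <- colMeans(x)
  scale <- rep(1, ncol(x))
  if (standardize) {
    # vectorized column sd; numerically safe at these magnitudes
    scale <- sqrt(pmax(colSums(x^2) - n * center^2, 0) / (n - 1))
    scale[!is.finite(scale) | scale < 1e-12] <- 1
  }
  xc <- sweep(sweep(x, 2L, center, "-"), 2L, scale, "/")
  eg <- eigen(tcrossprod(xc), symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  keep <- which(ev > tol * max(ev, 1e-300))
  keep <- keep[keep <= n - 1L]
  d <- sqrt(ev[keep])
  u <- eg$vectors[, keep, drop = FALSE]
  rotation <- crossprod(xc, u) / rep(d, each = ncol(x))
  structure(
    list(center = center, scale = scale, rotation = rotation,
         sdev = d / sqrt(n - 1), scores = u * rep(d, each = n)),
    class = "hyfc_pca"
  )
}

#' Project new subjects onto fitted principal components
#'
#' Uses the stored training center/scale and loadings; never refits.
#'
#' @param pca A `hyfc_pca` from [fit_pca()].
#' @param x `M x D` matrix with the training column count.
#' @return `M x m` score matrix.
#' @export
project_pca <- function(pca, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(pca$center)) {
    stop_hyfc(sprintf("feature count mismatch: model has %d columns, data has %d.",
                      length(pca$center), ncol(x)), class = "shape_error")
  }
  sweep(sweep(x, 2L, pca$center, "-"), 2L, pca$scale, "/") %*% pca$rotation
}

# Lambda grid and LASSO path on PCA scores. The classical gaussian LASSO on
# +/-1 labels: glmnet's default path starts at the smallest lambda with an
# all-zero solution and descends log-linearly to lambda_min_ratio of it.
lasso_path <- function(scores, y, lambda = NULL, n_lambda = 20,
                       lambda_min_ratio = 1e-3) {
  scores <- as.matrix(scores)
  # glmnet requires >= 2 columns; pad a single score with an all-zero
  # column, which can never enter the active set
  if (ncol(scores) == 1L) scores <- cbind(scores, 0)
  glmnet::glmnet(scores, y, family = "gaussian", alpha = 1,
                 lambda = lambda, nlambda = n_lambda,
                 lambda.min.ratio = lambda_min_ratio,
                 standardize = FALSE, intercept = TRUE, thresh = 1e-7)
}

#' LASSO feature selection on principal-component scores
#'
#' L1-penalized least-squares regression of the class labels (coded -1/+1)
#' on the component scores; components with nonzero coefficients at `lambda`
#' are selected. A sufficiently large penalty honestly selects nothing —
#' the zero-selection fallback lives in [fit_selection()].
#'
#' @param scores `N x m` component-score matrix.
#' @param labels Binary labels (any coding accepted by the package).
#' @param lambda Penalty; if `NULL`, the full default path is fitted and the
#'   smallest path value is used.
#' @return List with `lambda`, `coef` (length-m vector), `selected` (integer
#'   indices of nonzero components; empty when the penalty shrinks
#'   everything away) and the fitted path (`path_lambda`, `path_df`).
#' @export
fit_lasso <- function(scores, labels, lambda = NULL) {
  y <- as_binary_labels(labels) * 2 - 1
  if (length(unique(y)) < 2L) {
    stop_hyfc("both classes must be present to fit the LASSO.",
              class = "degenerate_labels")
  }
  fit <- lasso_path(scores, y)
  if (is.null(lambda)) lambda <- min(fit$lambda)
  if (!any(abs(fit$lambda - lambda) < 1e-12)) {
    # refit on a path that contains the requested lambda so the coefficients
    # come from the coordinate-descent solution, not path interpolation
    grid <- sort(unique(c(fit$lambda, lambda)), decreasing = TRUE)
    fit <- lasso_path(scores, y, lambda = grid)
  }
  beta <- as.numeric(glmnet::coef.glmnet(fit, s = lambda, exact = FALSE))[-1L]
  beta <- beta[seq_len(ncol(as.matrix(scores)))] # drop any padding column
  selected <- which(beta != 0)
  list(lambda = lambda, coef = beta, selected = selected,
       path_lambda = fit$lambda, path_df = fit$df)
}

#' Fit the full feature-selection model (standardize + PCA + LASSO)
#'
#' Everything is estimated from the training rows only; applying the model
#' to new subjects uses the stored statistics, so nested cross-validation
#' stays leakage-free.
#'
#' @inheritParams fit_pca
#' @param labels Binary training labels.
#' @param lambda LASSO penalty (see [fit_lasso()]).
#' @return Object of class `hyfc_selector` bundling the PCA and the LASSO
#'   selection.
#' @export
fit_selection <- function(x, labels, lambda = NULL, standardize = TRUE) {
  pca <- fit_pca(x, standardize = standardize)
  las <- fit_lasso(pca$scores, labels, lambda = lambda)
  if (length(las$selected) == 0L && any(las$path_df > 0)) {
    # fall back to the smallest path lambda that selects anything
    lam_fb <- min(las$path_lambda[las$path_df > 0])
    las <- fit_lasso(pca$scores, labels, lambda = lam_fb)
    message(sprintf(
      "lasso selected no components at the requested lambda; falling back to lambda = %.4g (%d components).",
      lam_fb, length(las$selected)))
  }
  if (length(las$selected) == 0L) {
    # pathological: no component ever enters the path; keep the score most
    # correlated with the labels so downstream kernels are never empty
    y <- as_binary_labels(labels) * 2 - 1
    las$selected <- which.max(abs(as.numeric(stats::cor(pca$scores, y))))
    warning("lasso path empty; retaining the single most label-correlated component.")
  }
  structure(list(pca = pca, lambda = las$lambda, coef = las$coef,
                 selected = las$selected),
            class = "hyfc_selector")
}

#' Apply a fitted selection model to subjects
#'
#' @param model A `hyfc_selector` from [fit_selection()].
#' @param x `M x D` raw feature matrix (training column count).
#' @return `M x k` matrix of the selected component scores.
#' @export
apply_selection <- function(model, x) {
  stopifnot(inherits(model, "hyfc_selector"))
  project_pca(model$pca, x)[, model$selected, drop = FALSE]
}

#' @export
print.hyfc_selector <- function(x, ...) {
  cat(sprintf("<feature selector: %d of %d components kept (lambda = %.4g)>\n",
              length(x$selected), ncol(x$pca$rotation), x$lambda))
  invisible(x)
}

#' @rdname tidiers
#' @method tidy hyfc_selector
#' @export
tidy.hyfc_selector <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$coef),
    coefficient = x$coef,
    selected = seq_along(x$coef) %in% x$selected
  )
}
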