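#' Scale each subject's feature vector to unit Euclidean norm
#'
#' The kernel-level normalization: it uses no training statistics, so it is
#' safe to apply before any train/test split. All-zero rows are returned
#' unchanged.
#'
#' @param x `N x D` feature matrix.
#' @return Matrix of the same shape with unit-norm rows.
#' @export
unit_normalize <- function(x) {
  x <- as.matrix(x)
  nrm <- sqrt(rowSums(x^2))
  nrm[nrm == 0] <- 1
  x / nrm
}

#' Linear Gram matrix across subjects
#'
#' `Gram[a, b] = <f_a, f_b>` after optional per-subject unit normalization;
#' symmetric and positive semidefinite by construction.
#'
#' @param x `N x D` feature matrix with at least one feature.
#' @param normalize Unit-normalize rows first (default `TRUE`).
#' @return `N x N` Gram matrix.
#' @export
linear_gram <- function(x, normalize = TRUE) {
  x <- as.matrix(x)
  if (ncol(x) == 0L) {
    stop_hyfc("cannot build a kernel from zero-length feature vectors.",
              class = "empty_features")
  }
  if (normalize) x <- unit_normalize(x)
  tcrossprod(x)
}

#' Simplex grid of kernel weights
#'
#' All triples `(tau1, tau2, tau3)` with `tau1, tau2` on the grid
#' `{0, step, 2 step, ..., 1}`, `tau1 + tau2 <= 1` and
#' `tau3 = 1 - tau1 - tau2`. With `step = 0.1` this is the 66-point grid the
#' weight search runs on; `step = 1` gives just the three vertices.
#'
#' @param step Grid resolution in (0, 1].
#' @return Tibble with columns `tau1`, `tau2`, `tau3`.
#' @export
weight_grid <- function(step = 0.1) {
  if (!is_scalar_number(step) || step <= 0 || step > 1) {
    stop_hyfc("`step` must lie in (0, 1].", class = "invalid_argument")
  }
  v <- unique(c(seq(0, 1, by = step), 1))
  g <- expand.grid(tau1 = v, tau2 = v)
  g <- g[g$tau1 + g$tau2 <= 1 + 1e-9, ]
  out <- tibble::tibble(tau1 = g$tau1, tau2 = g$tau2,
                        tau3 = pmax(1 - g$tau1 - g$tau2, 0))
  out <- dplyr::distinct(out)
  # deterministic order: tau1 descending, then tau2 descending, so ties in
  # downstream grid searches resolve toward the low-order kernel
  dplyr::arrange(out, dplyr::desc(.data$tau1), dplyr::desc(.data$tau2))
}

#' Composite multi-kernel
#'
#' Convex combination `tau1 K_L + tau2 K_H + tau3 K_A` of per-network-type
#' Gram matrices; positive semidefinite whenever the parts are.
#'
#' @param grams List of conformable `N x N` Gram matrices.
#' @param weights Numeric weights, one per Gram, nonnegative and summing to
#'   1 (within `1e-9`).
#' @return `N x N` composite kernel.
#' @export
composite_kernel <- function(grams, weights) {
  weights <- as.numeric(weights)
  if (length(weights) != length(grams) || any(weights < -1e-9) ||
      abs(sum(weights) - 1) > 1e-9) {
    stop_hyfc("kernel weights must be nonnegative and sum to 1.",
              class = "invalid_weights")
  }
  Reduce(`+`, Map(`*`, grams, weights))
}

# Linear SVM (libsvm via e1071) on explicit feature vectors, returning
# decision values oriented so that positive means class +1.
svm_linear_decision <- function(xtr, ytr, xte, cost = 1) {
  if (length(unique(ytr)) < 2L) {
    stop_hyfc("training fold contains a single class.", class = "degenerate_fold")
  }
  fac <- factor(ytr, levels = c(-1, 1))
  # fitted = FALSE skips an internal predict on the training data and
  # na.action = identity the NA scan; inputs here are always finite
  fit <- e1071::svm(x = xtr, y = fac, kernel = "linear", cost = cost,
                    scale = FALSE, tolerance = 1e-6, fitted = FALSE,
                    na.action = identity)
  # decision value computed directly from the dual solution
  # (w = t(SV) %*% coefs); positive means libsvm's first training class,
  # i.e. fit$levels[fit$labels[1]]
  d <- as.numeric(as.matrix(xte) %*% crossprod(fit$SV, fit$coefs) - fit$rho)
  if (fit$levels[fit$labels[1L]] == "-1") d <- -d
  list(decision = d, predicted = ifelse(d >= 0, 1L, -1L), model = fit)
}

# Exact factorization of a PSD Gram matrix: returns train "virtual features"
# and a projector for cross-kernel rows, reproducing the precomputed-kernel
# SVM through libsvm's linear kernel.
factor_gram <- function(gram, tol = 1e-9) {
  gram <- (gram + t(gram)) / 2
  eg <- eigen(gram, symmetric = TRUE)
  if (min(eg$values) < -tol * max(abs(eg$values), 1)) {
    stop_hyfc("Gram matrix is not positive semidefinite.", class = "invalid_kernel")
  }
  keep <- which(eg$values > tol * max(eg$values, 1e-300))
  d <- sqrt(eg$values[keep])
  u <- eg$vectors[, keep, drop = FALSE]
  list(xtr = u * rep(d, each = nrow(gram)),
       project = function(cross) cross %*% u / rep(d, each = nrow(cross)))
}

#' Soft-margin SVM with a precomputed kernel
#'
#' Trains a C-SVM (libsvm, `C = cost`) on a precomputed training Gram matrix
#' and scores test subjects from their cross-kernel rows. Internally the PSD
#' Gram is factorized exactly (eigendecomposition) into virtual feature
#' vectors whose linear kernel reproduces the input kernel, so the solution
#' is the standard precomputed-kernel dual.
#'
#' @param train_gram `N x N` PSD kernel between training subjects.
#' @param train_labels Binary labels for the training subjects.
#' @param cross_gram Optional `M x N` kernel between test and training
#'   subjects; defaults to scoring the training subjects themselves.
#' @param cost Soft-margin parameter `C` (default 1, the study setting).
#' @return List with `decision` (numeric scores, positive = class 1),
#'   `predicted` (0/1 labels).
#' @export
svm_fit_predict <- function(train_gram, train_labels, cross_gram = NULL, cost = 1) {
  y <- as_binary_labels(train_labels) * 2 - 1
  fac <- factor_gram(train_gram)
  if (is.null(cross_gram)) cross_gram <- train_gram
  res <- svm_linear_decision(fac$xtr, y, fac$project(as.matrix(cross_gram)), cost = cost)
  list(decision = res$decision, predicted = as.integer(res$predicted > 0))
}
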