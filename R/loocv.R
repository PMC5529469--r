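#' @importFrom rlang .data
NULL

# Weight grids for 1, 2 or 3 fused kernels, ordered so the first argmax in a
# grid search is the tie-break winner (largest weight on the first = low-order
# kernel, then on the second).
weight_grid_k <- function(k, step) {
  if (k == 1L) return(tibble::tibble(tau1 = 1))
  if (k == 2L) {
    v <- sort(unique(c(seq(0, 1, by = step), 1)), decreasing = TRUE)
    return(tibble::tibble(tau1 = v, tau2 = 1 - v))
  }
  weight_grid(step)
}

majority_of <- function(y) if (sum(y > 0) > sum(y < 0)) 1L else -1L

# Fit selector ingredients for one training subset of one network type:
# PCA scores, projected left-out rows, and the LASSO coefficient path on a
# fixed lambda grid.
fold_cache_entry <- function(x, train_rows, other_rows, y_train, lam_grid,
                             standardize) {
  pca <- fit_pca(x[train_rows, , drop = FALSE], standardize = standardize)
  b <- lasso_path(pca$scores, y_train, lambda = lam_grid)$beta
  list(scores = pca$scores,
       proj = project_pca(pca, x[other_rows, , drop = FALSE]),
       beta = as.matrix(b)[seq_len(ncol(pca$scores)), , drop = FALSE])
}

support_at <- function(beta, lam_grid, lambda) {
  col <- which.min(abs(lam_grid - lambda))
  s <- which(beta[, col] != 0)
  if (length(s) == 0L) {
    # fallback: densest end of the path that selects anything
    nz <- colSums(beta != 0)
    if (any(nz > 0)) s <- which(beta[, max(which(nz > 0))] != 0)
  }
  s
}

svm_correct <- function(xtr, ytr, xte, yte, cost) {
  if (ncol(xtr) == 0L) return(as.numeric(majority_of(ytr) == yte))
  d <- svm_linear_decision(xtr, ytr, xte, cost = cost)
  as.numeric(d$predicted == yte)
}

# One outer fold of the nested LOOCV: inner LOOCV on the training subjects
# picks a LASSO lambda per network type (each judged by its own single-type
# kernel), then the kernel weights on the simplex grid; the winning
# configuration is refitted on all training subjects to score the held-out
# subject. Depends only on rows != test_idx of `fm` and `y`.
fit_outer_fold <- function(fm, y, test_idx, cfg) {
  types <- names(fm)
  n <- length(y)
  train <- setdiff(seq_len(n), test_idx)
  y_tr <- y[train]
  if (length(unique(y_tr)) < 2L) {
    stop_hyfc("outer training fold contains a single class.", class = "degenerate_fold")
  }

  # common lambda grid per type, from the outer-training set only
  lam_grids <- lapply(types, function(tp) {
    pca <- fit_pca(fm[[tp]][train, , drop = FALSE], standardize = cfg$standardize)
    lasso_path(pca$scores, y_tr, n_lambda = cfg$n_lambda,
               lambda_min_ratio = cfg$lambda_min_ratio)$lambda
  })
  names(lam_grids) <- types

  n_in <- length(train)
  cache <- lapply(types, function(tp) {
    lapply(seq_len(n_in), function(i) {
      fold_cache_entry(fm[[tp]], train[-i], train[i], y_tr[-i],
                       lam_grids[[tp]], cfg$standardize)
    })
  })
  names(cache) <- types

  # stage 1: lambda per type by single-kernel inner LOOCV accuracy
  lambdas <- vapply(types, function(tp) {
    lam <- lam_grids[[tp]]
    correct <- matrix(0, n_in, length(lam))
    for (i in seq_len(n_in)) {
      ce <- cache[[tp]][[i]]
      supports <- lapply(seq_len(ncol(ce$beta)), function(cc) which(ce$beta[, cc] != 0))
      keys <- vapply(supports, paste, character(1), collapse = ",")
      for (key in unique(keys)) {
        s <- supports[[match(key, keys)]]
        ok <- if (length(s) == 0L) {
          as.numeric(majority_of(y_tr[-i]) == y_tr[i])
        } else {
          svm_correct(unit_normalize(ce$scores[, s, drop = FALSE]), y_tr[-i],
                      unit_normalize(ce$proj[, s, drop = FALSE]), y_tr[i],
                      cfg$cost)
        }
        correct[i, keys == key] <- ok
      }
    }
    acc <- colMeans(correct)
    best <- which(acc == max(acc))
    min(lam[best]) # tie-break: the smallest lambda among the best
  }, numeric(1))

  # stage 2: kernel weights by inner LOOCV accuracy at the chosen lambdas
  taus <- cfg$tau_grid %||% weight_grid_k(length(types), cfg$tau_step)
  tau_mat <- as.matrix(taus)
  correct <- matrix(0, n_in, nrow(tau_mat))
  for (i in seq_len(n_in)) {
    blocks_tr <- vector("list", length(types))
    blocks_te <- vector("list", length(types))
    for (ti in seq_along(types)) {
      ce <- cache[[types[ti]]][[i]]
      s <- support_at(ce$beta, lam_grids[[types[ti]]], lambdas[ti])
      blocks_tr[[ti]] <- unit_normalize(ce$scores[, s, drop = FALSE])
      blocks_te[[ti]] <- unit_normalize(ce$proj[, s, drop = FALSE])
    }
    for (w in seq_len(nrow(tau_mat))) {
      use <- which(tau_mat[w, ] > 0)
      xtr <- do.call(cbind, lapply(use, function(ti) {
        sqrt(tau_mat[w, ti]) * blocks_tr[[ti]]
      }))
      xte <- do.call(cbind, lapply(use, function(ti) {
        sqrt(tau_mat[w, ti]) * blocks_te[[ti]]
      }))
      correct[i, w] <- svm_correct(xtr, y_tr[-i], xte, y_tr[i], cfg$cost)
    }
  }
  tau_acc <- colMeans(correct)
  tau_best <- tau_mat[which.max(tau_acc), ] # grid order implements the tie-break

  # refit the winning configuration on all training subjects
  blocks_tr <- vector("list", length(types))
  blocks_te <- vector("list", length(types))
  sel_sizes <- integer(length(types))
  for (ti in seq_along(types)) {
    sel <- suppressMessages(fit_selection(
      fm[[types[ti]]][train, , drop = FALSE], y_tr,
      lambda = lambdas[ti], standardize = cfg$standardize))
    sel_sizes[ti] <- length(sel$selected)
    blocks_tr[[ti]] <- unit_normalize(
      sel$pca$scores[, sel$selected, drop = FALSE])
    blocks_te[[ti]] <- unit_normalize(apply_selection(
      sel, fm[[types[ti]]][test_idx, , drop = FALSE]))
  }
  use <- which(tau_best > 0)
  xtr <- do.call(cbind, lapply(use, function(ti) sqrt(tau_best[ti]) * blocks_tr[[ti]]))
  xte <- do.call(cbind, lapply(use, function(ti) sqrt(tau_best[ti]) * blocks_te[[ti]]))
  fit <- svm_linear_decision(xtr, y_tr, xte, cost = cfg$cost)

  list(test_idx = test_idx,
       lambda = stats::setNames(lambdas, types),
       tau = stats::setNames(as.numeric(tau_best), paste0("tau", seq_along(types))),
       n_selected = stats::setNames(sel_sizes, types),
       inner_acc = max(tau_acc),
       decision = fit$decision,
       predicted = as.integer(fit$predicted > 0),
       coefs = fit$model$coefs, rho = fit$model$rho)
}

#' Nested leave-one-out cross-validation of the multi-kernel classifier
#'
#' The full evaluation protocol: each subject is held out once; an inner
#' leave-one-out loop on the remaining `N - 1` subjects first picks the LASSO
#' penalty per network type (judged by that type's kernel alone), then the
#' kernel weights `(tau1, tau2, tau3)` on a simplex grid; the winner is
#' refitted on all `N - 1` subjects and scores the held-out subject with a
#' soft-margin linear SVM (`C = cost`). Feature selection is refitted inside
#' every fold, so no test information leaks into training. Ties in the inner
#' accuracy resolve deterministically (larger weight on the low-order kernel,
#' then smaller lambda).
#'
#' @param features A feature table from [hyfc_features()], or a named list of
#'   `N x D` matrices (one per network type, same subject order).
#' @param labels Binary labels; taken from the feature table when omitted.
#' @param tau_step Simplex grid resolution for the kernel weights
#'   (default 0.1, a 66-point grid for three types).
#' @param n_lambda,lambda_min_ratio LASSO path: number of penalties and ratio
#'   of the smallest to the largest (defaults 20 and 0.001).
#' @param cost SVM soft-margin parameter (default 1).
#' @param standardize Standardize features before PCA (default `TRUE`).
#' @param tau_grid Optional data frame of kernel-weight rows (one column per
#'   network type) replacing the [weight_grid()] search, e.g. a single
#'   simplex vertex to force one kernel.
#' @return Object of class `hyfc_cv`: per-subject predictions and decision
#'   values, per-fold hyperparameter choices, and aggregate metrics
#'   (see [tidy.hyfc_cv()], [glance.hyfc_cv()], [autoplot.hyfc_cv()]).
#' @examples
#' \donttest{
#' co <- simulate_cohort(n_per_group = 4, n_roi = 10, n_timepoints = 40,
#'                       preset = "strong", seed = 1)
#' ft <- hyfc_features(co, window_spec(20, 2))
#' cv <- nested_loocv(ft, tau_step = 0.5, n_lambda = 8)
#' glance(cv)
#' }
#' @export
nested_loocv <- function(features, labels = NULL, tau_step = 0.1,
                         n_lambda = 20, lambda_min_ratio = 1e-3,
                         cost = 1, standardize = TRUE, tau_grid = NULL) {
  if (is.data.frame(features)) {
    fl <- feature_matrices(features)
    fm <- fl$features
    labels <- labels %||% fl$labels
    ids <- fl$subject_id
  } else {
    stopifnot(is.list(features), !is.null(names(features)))
    fm <- lapply(features, as.matrix)
    if (is.null(labels)) {
      stop_hyfc("`labels` is required when `features` is a list of matrices.",
                class = "invalid_argument")
    }
    ids <- rownames(fm[[1L]]) %||% sprintf("sub%03d", seq_len(nrow(fm[[1L]])))
  }
  y01 <- as_binary_labels(labels)
  y <- y01 * 2L - 1L
  n <- length(y)
  if (n < 6L || sum(y01) < 3L || sum(1L - y01) < 3L) {
    stop_hyfc("nested LOOCV needs at least 6 subjects with 3 per class.",
              class = "insufficient_data")
  }
  cfg <- list(tau_step = tau_step, n_lambda = n_lambda,
              lambda_min_ratio = lambda_min_ratio, cost = cost,
              standardize = standardize, tau_grid = tau_grid)

  folds <- lapply(seq_len(n), function(i) fit_outer_fold(fm, y, i, cfg))

  predictions <- tibble::tibble(
    subject_id = ids,
    label = y01,
    predicted = vapply(folds, `[[`, integer(1), "predicted"),
    decision = vapply(folds, `[[`, numeric(1), "decision")
  )
  fold_info <- dplyr::bind_cols(
    tibble::tibble(subject_id = ids),
    dplyr::bind_rows(lapply(folds, function(f) {
      tibble::as_tibble(c(as.list(f$lambda), as.list(f$tau),
                          list(inner_acc = f$inner_acc)))
    }))
  )
  metrics <- classification_metrics(predictions$label, predictions$predicted,
                                    predictions$decision)
  structure(list(predictions = predictions, folds = fold_info,
                 metrics = metrics, config = cfg, types = names(fm)),
            class = "hyfc_cv")
}

#' @export
print.hyfc_cv <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<nested LOOCV: %d subjects, types %s>\n  ACC %.1f%%  AUC %.3f  SEN %.1f%%  SPE %.1f%%\n",
    nrow(x$predictions), paste(x$types, collapse = "+"),
    100 * m$acc, m$auc, 100 * m$sen, 100 * m$spe))
  invisible(x)
}

#' Tidiers and plots for nested-LOOCV results
#'
#' `tidy()` returns the per-subject predictions with the per-fold
#' hyperparameter choices; `glance()` a one-row tibble of the aggregate
#' metrics (ACC, AUC, SEN, SPE and the confusion counts); `autoplot()` draws
#' the ROC curve implied by the held-out decision values.
#'
#' @param x A `hyfc_cv` object from [nested_loocv()].
#' @param object A `hyfc_cv` object.
#' @param ... Unused.
#' @name tidiers
NULL

#' @rdname tidiers
#' @method tidy hyfc_cv
#' @export
tidy.hyfc_cv <- function(x, ...) {
  dplyr::left_join(x$predictions, x$folds, by = "subject_id")
}

#' @rdname tidiers
#' @method glance hyfc_cv
#' @export
glance.hyfc_cv <- function(x, ...) {
  x$metrics
}

#' @rdname tidiers
#' @method autoplot hyfc_cv
#' @export
autoplot.hyfc_cv <- function(object, ...) {
  p <- object$predictions
  ord <- order(p$decision, decreasing = TRUE)
  tpr <- c(0, cumsum(p$label[ord] == 1) / sum(p$label == 1))
  fpr <- c(0, cumsum(p$label[ord] == 0) / sum(p$label == 0))
  df <- tibble::tibble(fpr = fpr, tpr = tpr)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step(linewidth = 0.8, colour = "#2c7fb8") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = "Held-out ROC, nested LOOCV",
      subtitle = sprintf("ACC %.1f%%, AUC %.3f", 100 * object$metrics$acc,
                         object$metrics$auc)) +
    ggplot2::theme_minimal()
}
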