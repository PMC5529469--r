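test_that("linear Gram matrices are dot products of unit-normalized subjects", {
  x <- rbind(c(2, 0, 0), c(3, 0, 0), c(0, 5, 0))
  g <- linear_gram(x)
  expect_equal(g[1, 2], 1) # identical directions
  expect_equal(g[1, 3], 0) # orthogonal subjects
  withr::local_seed(51)
  x <- matrix(rnorm(15), 5, 3)
  g <- linear_gram(x, normalize = FALSE)
  for (a in 1:5) for (b in 1:5) expect_equal(g[a, b], sum(x[a, ] * x[b, ]))
  expect_gte(min(eigen(g, symmetric = TRUE, only.values = TRUE)$values), -1e-9)
  expect_error(linear_gram(matrix(numeric(0), 3, 0)), class = "hyfcnet_empty_features")
})

test_that("weight grids enumerate the simplex at the requested resolution", {
  expect_identical(nrow(weight_grid(0.5)), 6L)
  g1 <- weight_grid(1)
  expect_identical(nrow(g1), 3L)
  expect_setequal(do.call(paste, g1), c("1 0 0", "0 1 0", "0 0 1"))
  g <- weight_grid(0.1)
  expect_identical(nrow(g), 66L)
  expect_identical(nrow(dplyr::distinct(g)), 66L)
  expect_true(all(abs(rowSums(g) - 1) < 1e-9))
  expect_true(all(as.matrix(g) >= 0))
  expect_error(weight_grid(0), class = "hyfcnet_invalid_argument")
})

test_that("composite kernels are exact convex combinations and stay PSD", {
  withr::local_seed(52)
  grams <- lapply(1:3, function(i) tcrossprod(matrix(rnorm(40), 8, 5)))
  expect_equal(composite_kernel(grams, c(1, 0, 0)), grams[[1]])
  expect_equal(composite_kernel(rep(grams[1], 3), c(0.2, 0.5, 0.3)), grams[[1]],
               tolerance = 1e-12)
  k <- composite_kernel(grams, c(0.3, 0.5, 0.2))
  expect_equal(k, 0.3 * grams[[1]] + 0.5 * grams[[2]] + 0.2 * grams[[3]])
  expect_gte(min(eigen(k, symmetric = TRUE, only.values = TRUE)$values), -1e-9)
  expect_error(composite_kernel(grams, c(0.5, 0.5, 0.5)),
               class = "hyfcnet_invalid_weights")
})

test_that("precomputed-kernel SVM separates a separable toy and respects symmetry", {
  x <- matrix(c(-1, -1, 1, 1), 4, 1)
  y <- c(0, 0, 1, 1)
  g <- tcrossprod(x)
  fit <- svm_fit_predict(g, y)
  expect_equal(fit$predicted, y, ignore_attr = TRUE)
  expect_true(all(sign(fit$decision) == c(-1, -1, 1, 1)))
  # symmetric two-point problem: the midpoint scores exactly zero
  x2 <- matrix(c(-1, 1), 2, 1)
  mid <- svm_fit_predict(tcrossprod(x2), c(0, 1),
                         cross_gram = matrix(c(0, 0), 1, 2))
  expect_equal(mid$decision, 0, tolerance = 1e-9)
  expect_error(svm_fit_predict(g, c(1, 1, 1, 1)), class = "hyfcnet_degenerate_fold")
})

test_that("duplicating every training subject leaves the decision function unchanged", {
  withr::local_seed(53)
  x <- matrix(rnorm(12), 6, 2)
  x[, 1] <- x[, 1] + rep(c(-3, 3), each = 3) # comfortably separable
  y <- rep(c(0, 1), each = 3)
  xt <- matrix(rnorm(8), 4, 2)
  base <- hyfcnet:::svm_linear_decision(x, 2 * y - 1, xt, cost = 1)
  dup <- hyfcnet:::svm_linear_decision(rbind(x, x), rep(2 * y - 1, 2), xt, cost = 1)
  expect_equal(dup$decision, base$decision, tolerance = 1e-6)
})

test_that("the factorized-kernel SVM agrees with an independent precomputed-kernel solver", {
  skip_if_not_installed("kernlab")
  withr::local_seed(54)
  x <- matrix(rnorm(20 * 4), 20, 4)
  y <- as.integer(x[, 1] + 0.3 * rnorm(20) > 0)
  gram <- tcrossprod(x)
  mine <- svm_fit_predict(gram, y)
  km <- kernlab::ksvm(kernlab::as.kernelMatrix(gram), factor(y), type = "C-svc",
                      C = 1, scaled = FALSE)
  kd <- kernlab::predict(km, kernlab::as.kernelMatrix(
    gram[, kernlab::SVindex(km), drop = FALSE]), type = "decision")
  kd <- as.numeric(kd)
  # orient kernlab's decision values to positive = class 1
  if (stats::cor(kd, mine$decision) < 0) kd <- -kd
  expect_equal(ifelse(kd >= 0, 1L, 0L), mine$predicted)
  expect_equal(kd, mine$decision, tolerance = 1e-3)
})

test_that("nested LOOCV recovers an oracle feature at modest dimension", {
  withr::local_seed(55)
  n <- 12
  y <- rep(c(0, 1), each = 6)
  x <- matrix(rnorm(n * 8), n, 8)
  x[, 1] <- y
  cv <- light_cv(list(low = x), labels = y)
  expect_equal(cv$metrics$acc, 1)
  expect_equal(cv$metrics$auc, 1)
})

test_that("restricting the weight grid to a vertex reproduces the single-type pipeline", {
  co <- tiny_strong_cohort(seed = 6)
  ft <- hyfc_features(co, tiny_window())
  fm <- hyfcnet:::feature_matrices(ft)
  vertex <- nested_loocv(fm$features, labels = fm$labels, n_lambda = 8,
                         lambda_min_ratio = 0.01,
                         tau_grid = data.frame(tau1 = 1, tau2 = 0, tau3 = 0))
  single <- nested_loocv(fm$features["low"], labels = fm$labels, n_lambda = 8,
                         lambda_min_ratio = 0.01)
  expect_equal(vertex$predictions$decision, single$predictions$decision,
               tolerance = 1e-10)
  expect_identical(vertex$predictions$predicted, single$predictions$predicted)
})

test_that("nested LOOCV is deterministic and exposes tidy/glance/autoplot", {
  co <- tiny_strong_cohort(seed = 7)
  ft <- hyfc_features(co, tiny_window(), types = c("low", "high"))
  cv1 <- light_cv(ft)
  cv2 <- light_cv(ft)
  expect_identical(cv1$predictions, cv2$predictions)
  expect_identical(cv1$folds, cv2$folds)
  td <- tidy(cv1)
  expect_true(all(c("subject_id", "decision", "tau1", "inner_acc") %in% names(td)))
  expect_identical(nrow(td), nrow(co))
  gl <- glance(cv1)
  expect_identical(gl$tp + gl$fn + gl$tn + gl$fp, nrow(co))
  expect_s3_class(autoplot(cv1), "ggplot")
})

test_that("held-out predictions never depend on the held-out subject", {
  co <- tiny_strong_cohort(seed = 8)
  ft <- hyfc_features(co, tiny_window(), types = "low")
  fm <- hyfcnet:::feature_matrices(ft)
  y <- fm$labels * 2L - 1L
  cfg <- list(tau_step = 0.5, n_lambda = 8, lambda_min_ratio = 0.01,
              cost = 1, standardize = TRUE, tau_grid = NULL)
  f1 <- hyfcnet:::fit_outer_fold(fm$features, y, 3L, cfg)
  fm2 <- fm
  fm2$features$low[3, ] <- rev(fm2$features$low[3, ]) + 100
  y2 <- y
  y2[3] <- -y2[3]
  f2 <- hyfcnet:::fit_outer_fold(fm2$features, y2, 3L, cfg)
  expect_identical(f1$lambda, f2$lambda)
  expect_identical(f1$tau, f2$tau)
  expect_identical(f1$coefs, f2$coefs)
  expect_identical(f1$rho, f2$rho)
})
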