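test_that("PCA retains at most N - 1 components and reconstructs centered data", {
  withr::local_seed(41)
  x <- matrix(rnorm(10 * 50), 10, 50)
  p <- fit_pca(x)
  expect_lte(ncol(p$scores), 9)
  # orthonormal loadings
  expect_equal(crossprod(p$rotation), diag(ncol(p$rotation)), tolerance = 1e-8)
  # full reconstruction of the standardized, centered data
  xs <- scale(x)
  expect_equal(p$scores %*% t(p$rotation), xs[, ], tolerance = 1e-8,
               ignore_attr = TRUE)
  # rank-2 data keeps exactly 2 components
  b <- matrix(rnorm(20), 10, 2)
  x2 <- b %*% matrix(rnorm(2 * 30), 2, 30)
  expect_identical(ncol(fit_pca(x2, standardize = FALSE)$scores), 2L)
  expect_error(fit_pca(x[1:2, ]), class = "hyfcnet_insufficient_data")
})

test_that("PCA dimension bound holds over random shapes", {
  withr::local_seed(42)
  for (rep in 1:10) {
    n <- sample(3:12, 1)
    d <- sample(c(n - 1, n, 5 * n), 1)
    p <- fit_pca(matrix(rnorm(n * d), n, d))
    expect_lte(ncol(p$scores), n - 1)
  }
})

test_that("a huge penalty selects nothing; no penalty keeps essentially everything", {
  withr::local_seed(43)
  x <- matrix(rnorm(20 * 10), 20, 10)
  y <- rep(c(0, 1), 10)
  scores <- fit_pca(x)$scores
  expect_length(fit_lasso(scores, y, lambda = 1e6)$selected, 0)
  dense <- fit_lasso(scores, y, lambda = 1e-8)
  expect_gte(length(dense$selected), ncol(scores) - 1)
  expect_error(fit_lasso(scores, rep(1, 20)), class = "hyfcnet_degenerate_labels")
})

test_that("the 1-D LASSO coefficient equals the closed-form soft threshold", {
  withr::local_seed(44)
  x <- matrix(rnorm(40), 40, 1)
  x <- x - mean(x)
  y <- sign(x[, 1] + rnorm(40, sd = 0.5))
  n <- 40
  cxy <- sum(x[, 1] * (y - mean(y))) / n
  vx <- sum(x[, 1]^2) / n
  soft <- function(z, g) sign(z) * max(abs(z) - g, 0)
  for (lam in c(0.01, 0.1, 0.3)) {
    got <- fit_lasso(x, y, lambda = lam)$coef
    expect_equal(got, soft(cxy, lam) / vx, tolerance = 1e-6)
  }
})

test_that("the number of selected components is non-increasing in lambda", {
  withr::local_seed(45)
  x <- matrix(rnorm(25 * 40), 25, 40)
  y <- rep(c(-1, 1), length.out = 25)
  fit <- hyfcnet:::lasso_path(fit_pca(x)$scores, y)
  df <- fit$df # path is ordered from the largest lambda down
  expect_true(all(diff(df) >= 0))
})

test_that("selection models transform train and test consistently, without refitting", {
  withr::local_seed(46)
  x <- matrix(rnorm(12 * 30), 12, 30)
  y <- rep(c(0, 1), 6)
  sel <- fit_selection(x, y, lambda = 0.05)
  # applying to the training set reproduces the stored selected scores
  expect_equal(apply_selection(sel, x),
               sel$pca$scores[, sel$selected, drop = FALSE], tolerance = 1e-10)
  # a test subject identical to a training subject maps onto that row
  expect_equal(apply_selection(sel, x[4, , drop = FALSE])[1, ],
               apply_selection(sel, x)[4, ], tolerance = 1e-10)
  expect_error(apply_selection(sel, x[, 1:10]), class = "hyfcnet_shape_error")
  expect_s3_class(tidy(sel), "tbl_df")
  expect_identical(sum(tidy(sel)$selected), length(sel$selected))
})

test_that("a hand-computed 3-subject, 4-feature projection matches manual algebra", {
  x <- matrix(c(1, 2, 4,
                0, 1, 5,
                2, 2, 2,
                1, 0, 1), nrow = 3)
  p <- fit_pca(x, standardize = FALSE)
  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc)
  keep <- sv$d > 1e-10 * sv$d[1]
  manual_scores <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], sum(keep))
  # scores agree up to per-component sign
  for (j in seq_len(ncol(p$scores))) {
    expect_equal(abs(p$scores[, j]), abs(manual_scores[, j]), tolerance = 1e-10)
  }
  expect_equal(project_pca(p, x), p$scores, tolerance = 1e-10)
})

test_that("selection fitted on training rows is invariant to held-out data", {
  withr::local_seed(47)
  x <- matrix(rnorm(15 * 20), 15, 20)
  y <- rep(c(0, 1), length.out = 15)
  train <- 1:14
  sel1 <- fit_selection(x[train, ], y[train], lambda = 0.05)
  x2 <- x
  x2[15, ] <- 1e6 # mutate the held-out subject arbitrarily
  sel2 <- fit_selection(x2[train, ], y[train], lambda = 0.05)
  expect_identical(sel1$pca$center, sel2$pca$center)
  expect_identical(sel1$pca$rotation, sel2$pca$rotation)
  expect_identical(sel1$selected, sel2$selected)
  expect_identical(sel1$coef, sel2$coef)
})
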