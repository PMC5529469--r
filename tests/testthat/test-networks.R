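test_that("low-order network is the Pearson matrix: unit diagonal, symmetry, range", {
  withr::local_seed(11)
  x <- matrix(rnorm(180), 30, 6)
  c_mat <- fc_low(x)
  expect_true(isSymmetric(c_mat))
  expect_equal(diag(c_mat), rep(1, 6), ignore_attr = TRUE)
  expect_true(all(abs(c_mat) <= 1))
  expect_equal(c_mat[, ], pearson_matrix_loop(x), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("perfectly correlated and anticorrelated ROIs hit the +/-1 bounds", {
  withr::local_seed(12)
  base <- rnorm(25)
  x <- cbind(base, 2 * base + 3, -base, rnorm(25))
  c_mat <- fc_low(x)
  expect_equal(c_mat[1, 2], 1)
  expect_equal(c_mat[1, 3], -1)
})

test_that("high-order network correlates pairs of connectivity profiles", {
  withr::local_seed(13)
  x <- matrix(rnorm(30 * 8), 30, 8)
  c_mat <- fc_low(x)
  h_mat <- fc_high(c_mat)
  expect_true(isSymmetric(h_mat))
  expect_equal(diag(h_mat), rep(1, 8), ignore_attr = TRUE)
  expect_true(all(abs(h_mat) <= 1))
  expect_equal(h_mat[, ], pearson_matrix_loop(c_mat), tolerance = 1e-12,
               ignore_attr = TRUE)
  # ROIs with identical connectivity profiles have high-order FC of 1
  c_dup <- c_mat
  c_dup[, 2] <- c_dup[, 1]
  c_dup[2, ] <- c_dup[1, ]
  expect_equal(fc_high(c_dup)[1, 2], 1)
})

test_that("associated network correlates low-order with high-order profiles", {
  withr::local_seed(14)
  x <- matrix(rnorm(30 * 8), 30, 8)
  c_mat <- fc_low(x)
  h_mat <- fc_high(c_mat)
  a_raw <- fc_assoc(c_mat, h_mat, symmetrize = FALSE)
  expect_equal(a_raw[, ], pearson_cross_loop(c_mat, h_mat), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(abs(a_raw) <= 1))
  expect_gt(max(abs(a_raw - t(a_raw))), 1e-8) # raw product is genuinely asymmetric
  a_sym <- fc_assoc(c_mat, h_mat)
  expect_true(isSymmetric(a_sym))
  expect_equal(a_sym, (a_raw + t(a_raw)) / 2)
  expect_true(all(abs(a_sym) <= 1))
  # substituting H = C makes the raw product already symmetric
  a_self <- fc_assoc(c_mat, c_mat, symmetrize = FALSE)
  expect_equal(a_self, (a_self + t(a_self)) / 2, tolerance = 1e-12)
  expect_error(fc_assoc(c_mat, h_mat[1:4, 1:4]), class = "hyfcnet_shape_error")
})

test_that("build_networks composes low -> high -> associated per window", {
  withr::local_seed(15)
  x <- matrix(rnorm(40 * 7), 40, 7)
  spec <- window_spec(20, 5)
  nets <- build_networks(x, spec)
  k <- window_count(40, spec)
  expect_named(nets, c("low", "high", "associated"))
  for (tp in names(nets)) expect_length(nets[[tp]], k)
  wins <- sliding_windows(x, spec)
  for (kk in seq_len(k)) {
    c_mat <- fc_low(wins[[kk]])
    expect_equal(nets$low[[kk]], c_mat)
    expect_equal(nets$high[[kk]], fc_high(c_mat))
    expect_equal(nets$associated[[kk]], fc_assoc(c_mat, fc_high(c_mat)))
  }
})

test_that("dynamic networks with L = P equal the static construction bit for bit", {
  withr::local_seed(16)
  x <- matrix(rnorm(25 * 5), 25, 5)
  dyn <- build_networks(x, window_spec(25, 1))
  stat <- build_networks(x, spec = NULL)
  for (tp in names(dyn)) {
    expect_length(dyn[[tp]], 1)
    expect_identical(dyn[[tp]][[1]], stat[[tp]][[1]])
  }
})

test_that("permuting ROIs permutes all three network types consistently", {
  withr::local_seed(17)
  x <- matrix(rnorm(30 * 6), 30, 6)
  perm <- sample(6)
  nets <- build_networks(x, spec = NULL)
  nets_p <- build_networks(x[, perm], spec = NULL)
  for (tp in names(nets)) {
    expect_equal(nets_p[[tp]][[1]], nets[[tp]][[1]][perm, perm],
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("a degenerate window is reported with its window index", {
  x <- matrix(rnorm(60), 20, 3)
  x[11:20, 2] <- 5 # constant in the second window only
  err <- expect_error(build_networks(x, window_spec(10, 10), types = "low"),
                      class = "hyfcnet_window_error")
  expect_match(conditionMessage(err), "window 2")
})
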