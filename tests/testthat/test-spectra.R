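test_that("edge series is the per-window lookup of one matrix entry", {
  withr::local_seed(21)
  mats <- lapply(1:5, function(k) {
    m <- matrix(rnorm(16), 4, 4)
    (m + t(m)) / 2
  })
  g <- edge_series(mats, 2, 3)
  expect_equal(g, vapply(1:5, function(k) mats[[k]][2, 3], numeric(1)))
  # unit diagonal of low-order networks gives an all-ones series
  lows <- lapply(1:4, function(k) fc_low(matrix(rnorm(40), 10, 4)))
  expect_equal(edge_series(lows, 3, 3), rep(1, 4))
  # identical windows give a constant series
  const <- rep(mats[1], 5)
  expect_equal(edge_series(const, 1, 2), rep(mats[[1]][1, 2], 5))
  expect_error(edge_series(mats, 1, 9), class = "hyfcnet_bounds_error")
})

test_that("power spectrum matches a direct quadratic-time DFT and its closed forms", {
  # constant series: all power in the DC bin
  expect_equal(power_spectrum(rep(3, 8)), c((8 * 3)^2, rep(0, 4)),
               tolerance = 1e-9)
  # cosine at an exact bin frequency: power only in that bin
  k <- 16
  x <- cos(2 * pi * 3 * (0:(k - 1)) / k)
  p <- power_spectrum(x)
  expect_equal(p[4], (k / 2)^2, tolerance = 1e-8)
  expect_lt(max(p[-4]), 1e-16 * p[4])
  # random series against the naive DFT oracle
  withr::local_seed(22)
  for (rep in 1:10) {
    x <- rnorm(8)
    expect_equal(power_spectrum(x), dft_power_loop(x), tolerance = 1e-10)
  }
  expect_error(power_spectrum(1), class = "hyfcnet_too_short_series")
})

test_that("spectral stacks have floor(K/2)+1 symmetric nonnegative networks", {
  withr::local_seed(23)
  for (k in c(2, 5, 8, 61)) {
    mats <- lapply(seq_len(k), function(i) {
      m <- matrix(rnorm(25), 5, 5)
      (m + t(m)) / 2
    })
    st <- spectral_stack(mats, step_s = 1, tr_seconds = 3)
    expect_length(st$spectra, k %/% 2 + 1)
    for (z in st$spectra) {
      expect_true(isSymmetric(z))
      expect_true(all(z >= 0))
    }
    # frequency axis: bin q at (q-1)/(K S TR), capped by the sliding Nyquist
    expect_equal(st$frequencies_hz,
                 (seq_len(k %/% 2 + 1) - 1) / (k * 3))
    expect_lte(max(st$frequencies_hz), 1 / (2 * 3))
  }
})

test_that("spectral stack agrees edgewise with power_spectrum and satisfies Parseval", {
  withr::local_seed(24)
  k <- 9
  mats <- lapply(seq_len(k), function(i) {
    m <- matrix(rnorm(36), 6, 6)
    (m + t(m)) / 2
  })
  st <- spectral_stack(mats)
  for (i in 1:6) {
    for (j in i:6) {
      g <- edge_series(mats, i, j)
      ps <- power_spectrum(g)
      expect_equal(vapply(st$spectra, function(z) z[i, j], numeric(1)), ps,
                   tolerance = 1e-10)
      # Parseval: two-sided DFT power (reconstructed from the one-sided
      # stack; for odd K every nonzero bin appears twice) equals K sum g^2
      two_sided <- ps[1] + 2 * sum(ps[-1])
      expect_equal(two_sided, k * sum(g^2), tolerance = 1e-8 * k * sum(g^2))
    }
  }
})

test_that("identical windows put all off-diagonal power in the DC network", {
  m <- fc_low(matrix(rnorm(50), 10, 5))
  st <- spectral_stack(rep(list(m), 6))
  off <- upper.tri(m)
  expect_equal(st$spectra[[1]][off], (6 * m[off])^2, tolerance = 1e-9)
  for (q in 2:4) expect_lt(max(abs(st$spectra[[q]][off])), 1e-14 * 36)
})

test_that("static network sets are rejected by the spectral transform", {
  m <- fc_low(matrix(rnorm(50), 10, 5))
  expect_error(spectral_stack(list(m)), class = "hyfcnet_static_input")
})

test_that("demeaning moves the DC bin to zero and leaves other bins unchanged", {
  withr::local_seed(25)
  x <- rnorm(12)
  p_raw <- power_spectrum(x)
  p_dm <- power_spectrum(x, demean = TRUE)
  expect_equal(p_dm[1], 0, tolerance = 1e-12)
  expect_equal(p_dm[-1], p_raw[-1], tolerance = 1e-9)
})
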