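# Independent brute-force oracles used to pin down the matrix algebra.
# Deliberately written as explicit scalar loops, sharing no code with the
# package implementations they check.

# Pearson correlation of two vectors by the textbook deviation formula.
pearson_loop <- function(a, b) {
  n <- length(a)
  ma <- sum(a) / n
  mb <- sum(b) / n
  num <- 0
  da <- 0
  db <- 0
  for (t in seq_len(n)) {
    num <- num + (a[t] - ma) * (b[t] - mb)
    da <- da + (a[t] - ma)^2
    db <- db + (b[t] - mb)^2
  }
  num / sqrt(da * db)
}

# Pairwise Pearson matrix of the columns of x, entry by entry.
pearson_matrix_loop <- function(x) {
  r <- ncol(x)
  out <- matrix(NA_real_, r, r)
  for (i in seq_len(r)) {
    for (j in seq_len(r)) {
      out[i, j] <- pearson_loop(x[, i], x[, j])
    }
  }
  out
}

# Cross-correlation: entry (i, j) = Pearson of a[, i] with b[, j].
pearson_cross_loop <- function(a, b) {
  out <- matrix(NA_real_, ncol(a), ncol(b))
  for (i in seq_len(ncol(a))) {
    for (j in seq_len(ncol(b))) {
      out[i, j] <- pearson_loop(a[, i], b[, j])
    }
  }
  out
}

# Quadratic-time direct DFT; one-sided squared magnitudes.
dft_power_loop <- function(x) {
  k <- length(x)
  q <- k %/% 2 + 1
  out <- numeric(q)
  for (qq in seq_len(q)) {
    re <- 0
    im <- 0
    for (t in seq_len(k)) {
      ang <- -2 * pi * (qq - 1) * (t - 1) / k
      re <- re + x[t] * cos(ang)
      im <- im + x[t] * sin(ang)
    }
    out[qq] <- re^2 + im^2
  }
  out
}

# Weighted local clustering coefficient by explicit set construction.
wlcc_loop <- function(z, i) {
  omega <- integer(0)
  for (j in seq_len(nrow(z))) {
    if (j != i && z[i, j] > 0) omega <- c(omega, j)
  }
  v <- length(omega)
  if (v <= 1) return(0)
  s <- 0
  for (j in omega) s <- s + z[i, j]^(1 / 3)
  2 * s / (v * (v - 1))
}

# AUC by exhaustive positive/negative pair counting, ties counting 1/2.
auc_pairs_loop <- function(decision, labels) {
  pos <- decision[labels == 1]
  neg <- decision[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Squared Pearson correlation with 0/1 labels, by the deviation formula.
r2_labels_loop <- function(values, labels) {
  pearson_loop(values, as.numeric(labels))^2
}

# Random symmetric nonnegative weight matrix with zero diagonal.
random_weights <- function(r, density = 0.7) {
  z <- matrix(0, r, r)
  up <- which(upper.tri(z))
  w <- stats::runif(length(up))
  w[stats::runif(length(up)) > density] <- 0
  z[up] <- w
  z + t(z)
}

# Small strong-effect cohort + light CV settings for fast classifier tests.
tiny_strong_cohort <- function(seed = 1, n_per_group = 5) {
  simulate_cohort(n_per_group = n_per_group, n_roi = 12, n_timepoints = 60,
                  n_modules = 2, base_coupling = 0.3,
                  modulation_amplitude = c(0, 0.9),
                  modulation_frequency_hz = c(1 / 90, 1 / 90),
                  seed = seed)
}

tiny_window <- function() window_spec(30, 1)

light_cv <- function(features, ...) {
  nested_loocv(features, tau_step = 0.5, n_lambda = 8,
               lambda_min_ratio = 0.01, ...)
}
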