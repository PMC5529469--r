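#' Dynamic FC series of one edge
#'
#' Concatenates entry (i, j) across the `K` windowed connectivity matrices,
#' giving the length-`K` time series of one connection's strength ("how the
#' FC fluctuates along time"). Samples are spaced `S * TR` seconds apart.
#'
#' @param mats List of `K` `R x R` matrices (one network type, window order).
#' @param i,j ROI indices in `1..R`.
#' @return Numeric vector of length `K`.
#' @export
edge_series <- function(mats, i, j) {
  r <- nrow(mats[[1L]])
  i <- check_count(i, "i"); j <- check_count(j, "j")
  if (i > r || j > r) {
    stop_hyfc(sprintf("edge (%d, %d) out of range for R = %d ROIs.", i, j, r),
              class = "bounds_error")
  }
  vapply(mats, function(m) m[i, j], numeric(1))
}

#' One-sided power spectrum of a dynamic FC series
#'
#' Squared magnitude of the discrete Fourier transform, retained for the
#' one-sided bins `q = 0..floor(K/2)`, so the output has
#' `Q = floor(K/2) + 1` entries including the zero-frequency (DC) bin. No
#' taper and no normalization are applied; `demean = TRUE` removes the series
#' mean before the transform (moving the DC bin to 0).
#'
#' @param x Numeric vector of length `K >= 2`.
#' @param demean Subtract the mean before transforming (default `FALSE`).
#' @param magnitude Return `|DFT|` instead of `|DFT|^2` (default `FALSE`).
#' @return Nonnegative numeric vector of length `floor(K/2) + 1`.
#' @examples
#' power_spectrum(rep(2, 8)) # all power in the DC bin: (8 * 2)^2
#' @export
power_spectrum <- function(x, demean = FALSE, magnitude = FALSE) {
  k <- length(x)
  if (k < 2L) {
    stop_hyfc("a dynamic FC series needs at least 2 windows for a spectrum.",
              class = "too_short_series")
  }
  if (demean) x <- x - mean(x)
  p <- Mod(stats::fft(x))[seq_len(k %/% 2L + 1L)]
  if (magnitude) p else p^2
}

#' Frequency axis of the dynamic-FC spectrum
#'
#' Bin `q` (1-based) sits at `(q - 1) / (K * S * TR)` Hz; the highest
#' retained bin is at or below the Nyquist frequency `1 / (2 * S * TR)` of
#' the window-sliding process.
#'
#' @param n_windows Number of windows `K`.
#' @param step_s Window step `S` in volumes.
#' @param tr_seconds Repetition time in seconds.
#' @return Numeric vector of `floor(K/2) + 1` frequencies in Hz.
#' @export
spectral_frequencies <- function(n_windows, step_s = 1, tr_seconds = 3) {
  q <- n_windows %/% 2L + 1L
  (seq_len(q) - 1L) / (n_windows * step_s * tr_seconds)
}

#' Frequency-power spectral networks of a dynamic network set
#'
#' Applies [power_spectrum()] to every edge's dynamic series, yielding `Q`
#' time-invariant `R x R` networks `Z^1..Z^Q` (one per frequency bin). Only
#' upper-triangle edges are transformed; symmetry of the input matrices makes
#' every `Z^q` symmetric, and the result is filled in symmetrically. Static
#' input (a single window) carries no temporal fluctuation and is rejected.
#'
#' @param mats List of `K >= 2` symmetric `R x R` matrices in window order.
#' @param step_s,tr_seconds Sampling of the window sequence, for the
#'   frequency axis.
#' @inheritParams power_spectrum
#' @return Object of class `hyfc_spectra`: a list with `spectra` (list of `Q`
#'   nonnegative symmetric matrices), `frequencies_hz`, `n_windows`.
#' @export
spectral_stack <- function(mats, step_s = 1, tr_seconds = 3,
                           demean = FALSE, magnitude = FALSE) {
  k <- length(mats)
  if (k < 2L) {
    stop_hyfc("spectral networks are undefined for a static network (K = 1).",
              class = "static_input")
  }
  r <- nrow(mats[[1L]])
  ut <- which(upper.tri(diag(r), diag = TRUE))
  # K x E matrix of edge series, one column per upper-triangle edge
  g <- t(vapply(mats, function(m) m[ut], numeric(length(ut))))
  if (demean) g <- sweep(g, 2L, colMeans(g))
  ft <- Mod(stats::mvfft(g))
  q <- k %/% 2L + 1L
  ft <- ft[seq_len(q), , drop = FALSE]
  if (!magnitude) ft <- ft^2
  lower <- which(lower.tri(diag(r)))
  spectra <- lapply(seq_len(q), function(qi) {
    z <- matrix(0, r, r, dimnames = dimnames(mats[[1L]]))
    z[ut] <- ft[qi, ]
    tz <- t(z)
    z[lower] <- tz[lower]
    z
  })
  structure(
    list(spectra = spectra,
         frequencies_hz = spectral_frequencies(k, step_s, tr_seconds),
         n_windows = k),
    class = "hyfc_spectra"
  )
}

#' @export
print.hyfc_spectra <- function(x, ...) {
  cat(sprintf("<spectral networks: Q = %d bins, R = %d ROIs, K = %d windows, %.4g-%.4g Hz>\n",
              length(x$spectra), nrow(x$spectra[[1L]]), x$n_windows,
              min(x$frequencies_hz), max(x$frequencies_hz)))
  invisible(x)
}
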