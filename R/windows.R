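#' Sliding-window specification
#'
#' Describes how a length-`P` ROI time series is segmented into overlapping
#' sub-series: windows of `length` volumes advanced by `step` volumes, giving
#' `K = floor((P - length) / step) + 1` windows. The study default is
#' `window_spec(70, 1)`: 70 volumes (210 s at a 3-s repetition time) stepped
#' one volume at a time.
#'
#' @param length Window length `L` in volumes (integer, `>= 2`).
#' @param step Step size `S` in volumes (integer, `>= 1`).
#' @return An object of class `hyfc_window` with fields `length_l` and
#'   `step_s`.
#' @examples
#' window_spec(70, 1)
#' @export
window_spec <- function(length, step = 1) {
  length <- check_count(length, "length", min = 2L)
  step <- check_count(step, "step", min = 1L)
  structure(list(length_l = length, step_s = step), class = "hyfc_window")
}

#' @export
print.hyfc_window <- function(x, ...) {
  cat(sprintf("<sliding window: L = %d volumes, S = %d>\n", x$length_l, x$step_s))
  invisible(x)
}

#' Number of sliding windows
#'
#' `K = floor((P - L) / S) + 1` for a series of `n_timepoints` volumes.
#'
#' @param n_timepoints Number of time points `P` in the full series.
#' @param spec A [window_spec()].
#' @return Integer window count `K`.
#' @examples
#' window_count(130, window_spec(70, 1)) # 61
#' @export
window_count <- function(n_timepoints, spec) {
  n_timepoints <- check_count(n_timepoints, "n_timepoints", min = 2L)
  stopifnot(inherits(spec, "hyfc_window"))
  if (spec$length_l > n_timepoints) {
    stop_hyfc(
      sprintf("window length L = %d exceeds series length P = %d.",
              spec$length_l, n_timepoints),
      class = "invalid_window"
    )
  }
  as.integer((n_timepoints - spec$length_l) %/% spec$step_s + 1L)
}

#' Segment a time series into sliding windows
#'
#' Splits a `P x R` matrix (rows = time points, columns = ROIs) into the
#' `K` overlapping `L x R` sub-series implied by `spec`; window `k` covers
#' rows `(k - 1) * S + 1` to `(k - 1) * S + L`.
#'
#' @param x Numeric `P x R` matrix.
#' @param spec A [window_spec()].
#' @return A list of `K` matrices of dimension `L x R`, in temporal order.
#' @examples
#' x <- matrix(rnorm(20), 10, 2)
#' length(sliding_windows(x, window_spec(4, 3))) # 3 windows: rows 1-4, 4-7, 7-10
#' @export
sliding_windows <- function(x, spec) {
  x <- as.matrix(x)
  k <- window_count(nrow(x), spec)
  lapply(seq_len(k), function(i) {
    from <- (i - 1L) * spec$step_s + 1L
    x[from:(from + spec$length_l - 1L), , drop = FALSE]
  })
}

#' Duration of one window in seconds
#'
#' @param spec A [window_spec()].
#' @param tr_seconds Repetition time in seconds.
#' @return `L * TR` in seconds (e.g. 70 volumes at TR = 3 s is 210 s).
#' @export
window_duration_seconds <- function(spec, tr_seconds) {
  stopifnot(inherits(spec, "hyfc_window"), is_scalar_number(tr_seconds), tr_seconds > 0)
  spec$length_l * tr_seconds
}

#' Longest wavelength passed by a high-pass filter
#'
#' Guideline helper for choosing a sliding-window length: a window should
#' exceed the longest wavelength composing the band-passed BOLD signal,
#' i.e. `1 / highpass_hz` seconds (100 s for the common 0.01 Hz cutoff).
#'
#' @param highpass_hz High-pass cutoff frequency in Hz.
#' @return Wavelength in seconds.
#' @export
longest_wavelength_seconds <- function(highpass_hz) {
  stopifnot(is_scalar_number(highpass_hz), highpass_hz > 0)
  1 / highpass_hz
}

#' Standardize matrix columns to mean zero and unit Euclidean norm
#'
#' After standardization `crossprod(x)` is exactly the Pearson correlation
#' matrix of the input columns, which is how all three network types are
#' computed. A column that is constant over the window has no direction and
#' raises a degenerate-signal error naming the column.
#'
#' @param x Numeric matrix with at least 2 rows.
#' @return Matrix of the same dimension; each column has mean 0 and
#'   `sqrt(sum(col^2)) == 1`.
#' @export
standardize_columns <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) {
    stop_hyfc("at least 2 rows are required to standardize columns.",
              class = "invalid_argument")
  }
  xc <- sweep(x, 2L, colMeans(x), "-")
  nrm <- sqrt(colSums(xc^2))
  # relative tolerance: a column is degenerate when its centered norm is
  # negligible against its own magnitude
  tol <- 1e-12 * pmax(sqrt(colSums(x^2)), 1)
  bad <- which(nrm <= tol)
  if (length(bad) > 0L) {
    nm <- colnames(x)[bad[1L]] %||% as.character(bad[1L])
    stop_hyfc(
      sprintf("column %s is constant over the window (zero variance).", nm),
      class = "degenerate_signal", column = bad
    )
  }
  sweep(xc, 2L, nrm, "/")
}
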