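#' Low-order functional connectivity network
#'
#' The conventional FC network: the `R x R` Pearson correlation matrix of the
#' ROI time series over one window, computed as `t(X) %*% X` on
#' column-standardized `X` (mean 0, unit norm per column).
#'
#' @param x Numeric `L x R` time-series window (rows = time points).
#' @return Symmetric `R x R` correlation matrix with unit diagonal, entries
#'   in `[-1, 1]`. ROI names are carried over from `colnames(x)`.
#' @seealso [fc_high()], [fc_assoc()], [build_networks()]
#' @export
fc_low <- function(x) {
  xs <- standardize_columns(x)
  c_mat <- clamp_unit(crossprod(xs))
  diag(c_mat) <- 1
  c_mat
}

#' High-order functional connectivity network
#'
#' "Correlation's correlation": entry (i, j) is the Pearson correlation
#' between the i-th and j-th columns of the low-order network `C` — i.e.
#' between the two ROIs' whole-brain connectivity profiles (full columns,
#' including the unit self-connection). Computed as `t(Cs) %*% Cs` on the
#' column-standardized `C`.
#'
#' @param c_mat Low-order network from [fc_low()].
#' @return Symmetric `R x R` matrix, unit diagonal, entries in `[-1, 1]`.
#' @export
fc_high <- function(c_mat) {
  cs <- tryCatch(
    standardize_columns(c_mat),
    hyfcnet_degenerate_signal = function(e) {
      stop_hyfc(
        "a connectivity profile (column of C) is constant; its correlation with other profiles is undefined.",
        class = "degenerate_profile", parent = e
      )
    }
  )
  h_mat <- clamp_unit(crossprod(cs))
  diag(h_mat) <- 1
  h_mat
}

#' Associated high-order functional connectivity network
#'
#' The inter-level network: entry (i, j) is the Pearson correlation between
#' the i-th low-order connectivity profile (column of `C`) and the j-th
#' high-order profile (column of `H`), computed as `t(Cs) %*% Hs` with both
#' factors column-standardized. The raw product is generally asymmetric; by
#' default it is symmetrized as `(A + t(A)) / 2`, which keeps entries in
#' `[-1, 1]`.
#'
#' @param c_mat Low-order network from [fc_low()].
#' @param h_mat High-order network from [fc_high()].
#' @param symmetrize If `TRUE` (default) return `(A + t(A)) / 2`; set `FALSE`
#'   to inspect the raw asymmetric matrix.
#' @return `R x R` matrix with entries in `[-1, 1]`.
#' @export
fc_assoc <- function(c_mat, h_mat, symmetrize = TRUE) {
  if (!identical(dim(c_mat), dim(h_mat))) {
    stop_hyfc(
      sprintf("dimension mismatch: C is %dx%d, H is %dx%d.",
              nrow(c_mat), ncol(c_mat), nrow(h_mat), ncol(h_mat)),
      class = "shape_error"
    )
  }
  cs <- tryCatch(standardize_columns(c_mat),
    hyfcnet_degenerate_signal = function(e) {
      stop_hyfc("a low-order profile is constant.", class = "degenerate_profile", parent = e)
    })
  hs <- tryCatch(standardize_columns(h_mat),
    hyfcnet_degenerate_signal = function(e) {
      stop_hyfc("a high-order profile is constant.", class = "degenerate_profile", parent = e)
    })
  a_mat <- clamp_unit(crossprod(cs, hs))
  if (symmetrize) a_mat <- (a_mat + t(a_mat)) / 2
  a_mat
}

#' Network types recognised by the pipeline
#' @keywords internal
hyfc_types <- c("low", "high", "associated")

match_types <- function(types) {
  types <- match.arg(types, hyfc_types, several.ok = TRUE)
  unique(types)
}

#' Build dynamic (or static) FC networks for one subject
#'
#' Segments the series with `spec` and, per window, computes the requested
#' network types in dependency order (low, then high, then associated, each
#' from the same window). The static variant is the limiting case `L = P`,
#' obtained by passing `spec = NULL`.
#'
#' @param x Numeric `P x R` time-series matrix for one subject.
#' @param spec A [window_spec()], or `NULL` for the static (full-series)
#'   network.
#' @param types Character vector among `"low"`, `"high"`, `"associated"`.
#'   Requesting `"high"` or `"associated"` computes the prerequisites
#'   internally but returns only what was asked for.
#' @param symmetrize Symmetrize the associated network (default `TRUE`).
#' @return Named list (one element per requested type), each a list of `K`
#'   `R x R` matrices in window order (`K = 1` for static).
#' @examples
#' x <- matrix(rnorm(130 * 10), 130, 10)
#' nets <- build_networks(x, window_spec(70, 1), types = "low")
#' length(nets$low) # 61
#' @export
build_networks <- function(x, spec = window_spec(70, 1),
                           types = hyfc_types, symmetrize = TRUE) {
  x <- as.matrix(x)
  types <- match_types(types)
  if (is.null(spec)) spec <- window_spec(nrow(x), 1L)
  wins <- sliding_windows(x, spec)
  need_high <- any(types %in% c("high", "associated"))
  need_assoc <- "associated" %in% types
  out <- lapply(seq_along(wins), function(k) {
    withCallingHandlers(
      {
        c_mat <- fc_low(wins[[k]])
        h_mat <- if (need_high) fc_high(c_mat) else NULL
        a_mat <- if (need_assoc) fc_assoc(c_mat, h_mat, symmetrize = symmetrize) else NULL
        list(low = c_mat, high = h_mat, associated = a_mat)
      },
      hyfcnet_error = function(e) {
        stop_hyfc(sprintf("in window %d: %s", k, conditionMessage(e)),
                  class = "window_error", window = k, parent = e)
      }
    )
  })
  stats::setNames(lapply(types, function(tp) lapply(out, `[[`, tp)), types)
}
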