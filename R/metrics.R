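#' Rank-statistic AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic on the
#' decision values: the probability that a random positive scores above a
#' random negative, with score ties contributing 1/2 (midranks).
#'
#' @param decision Numeric scores, larger = more positive.
#' @param labels Binary labels.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(decision, labels) {
  y <- as_binary_labels(labels)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop_hyfc("AUC needs both classes present.", class = "degenerate_labels")
  }
  r <- rank(decision)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Binary classification metrics
#'
#' Confusion counts and the standard derived rates, with class 1 as the
#' positive class: sensitivity `TP / (TP + FN)`, specificity
#' `TN / (TN + FP)`, accuracy `(TP + TN) / N`, plus the rank-statistic AUC
#' when decision values are supplied.
#'
#' @param truth,predicted Binary label vectors of equal length.
#' @param decision Optional decision values for the AUC.
#' @return One-row tibble: `tp`, `fn`, `tn`, `fp`, `acc`, `sen`, `spe`,
#'   `auc` (`NA` without decision values).
#' @examples
#' classification_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0), c(2, -1, -2, -3))
#' @export
classification_metrics <- function(truth, predicted, decision = NULL) {
  truth <- as_binary_labels(truth)
  predicted <- as_binary_labels(predicted)
  if (length(truth) != length(predicted)) {
    stop_hyfc("`truth` and `predicted` must have equal length.", class = "shape_error")
  }
  tp <- sum(truth == 1L & predicted == 1L)
  fn <- sum(truth == 1L & predicted == 0L)
  tn <- sum(truth == 0L & predicted == 0L)
  fp <- sum(truth == 0L & predicted == 1L)
  auc <- if (is.null(decision)) NA_real_ else auc_rank(decision, truth)
  tibble::tibble(
    tp = tp, fn = fn, tn = tn, fp = fp,
    acc = (tp + tn) / length(truth),
    sen = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    spe = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    auc = auc
  )
}

#' Squared point-biserial correlation (group separability)
#'
#' `r = (mean_1 - mean_0) / sigma * sqrt(n1 n0 / n^2)` with `sigma` the
#' population (divide-by-n) standard deviation over all values, so that
#' `r^2` equals the squared Pearson correlation between the values and the
#' 0/1 labels exactly. Larger values mean the feature separates the groups
#' better.
#'
#' @param values Numeric vector, one value per subject.
#' @param labels Binary group labels.
#' @return `r^2` in `[0, 1]`.
#' @export
pointwise_r2 <- function(values, labels) {
  y <- as_binary_labels(labels)
  if (length(values) != length(y)) {
    stop_hyfc("`values` and `labels` must have equal length.", class = "shape_error")
  }
  n1 <- sum(y == 1L); n0 <- sum(y == 0L); n <- n1 + n0
  if (n1 == 0L || n0 == 0L) {
    stop_hyfc("both groups must be present.", class = "degenerate_labels")
  }
  sig <- sqrt(mean((values - mean(values))^2))
  if (sig == 0) {
    stop_hyfc("values have zero variance; separability is undefined.",
              class = "undefined_separability")
  }
  r <- (mean(values[y == 1L]) - mean(values[y == 0L])) / sig * sqrt(n1 * n0 / n^2)
  r^2
}

#' Edge-wise group-separability map
#'
#' Computes [pointwise_r2()] across subjects for every edge of a set of
#' same-type connectivity matrices (one per subject), e.g. the static
#' low/high/associated networks of a cohort. Edges with zero variance across
#' subjects (notably the unit diagonal of correlation networks) are reported
#' as `NA`, not zero.
#'
#' @param mats List of `N` conformable `R x R` matrices, one per subject.
#' @param labels Binary group labels, length `N`.
#' @return Object of class `hyfc_separability` wrapping the symmetric
#'   `R x R` matrix of `r^2` values.
#' @export
edge_separability <- function(mats, labels) {
  y <- as_binary_labels(labels)
  r <- nrow(mats[[1L]])
  ut <- which(upper.tri(diag(r), diag = TRUE))
  vals <- vapply(mats, function(m) m[ut], numeric(length(ut))) # E x N
  r2 <- apply(vals, 1L, function(v) {
    tryCatch(pointwise_r2(v, y),
             hyfcnet_undefined_separability = function(e) NA_real_)
  })
  out <- matrix(NA_real_, r, r, dimnames = dimnames(mats[[1L]]))
  out[ut] <- r2
  tout <- t(out)
  lower <- which(lower.tri(out))
  out[lower] <- tout[lower]
  structure(list(r2 = out), class = "hyfc_separability")
}

#' @export
print.hyfc_separability <- function(x, ...) {
  cat(sprintf("<edge separability map: %d ROIs, max r2 = %.3f>\n",
              nrow(x$r2), max(x$r2, na.rm = TRUE)))
  invisible(x)
}

#' @rdname tidiers
#' @method tidy hyfc_separability
#' @export
tidy.hyfc_separability <- function(x, ...) {
  r <- nrow(x$r2)
  rois <- rownames(x$r2) %||% sprintf("ROI%02d", seq_len(r))
  idx <- which(upper.tri(x$r2), arr.ind = TRUE)
  tibble::tibble(
    roi_i = rois[idx[, 1L]], roi_j = rois[idx[, 2L]],
    r2 = x$r2[upper.tri(x$r2)]
  )
}

#' @rdname tidiers
#' @method autoplot hyfc_separability
#' @export
autoplot.hyfc_separability <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$roi_j, y = .data$roi_i,
                                   fill = .data$r2)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "#fff5f0", high = "#99000d",
                                 na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = expression(r^2),
                  title = "Edge-wise group separability") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Per-frequency separability of one dynamic FC edge
#'
#' For each requested sliding-window length, builds the cohort's dynamic
#' networks of `type`, takes the chosen edge's power spectrum per subject,
#' and computes the per-frequency-bin group separability `r^2`. With a
#' planted group-specific coupling modulation the curve peaks at the bin
#' nearest the modulation frequency.
#'
#' @param cohort Cohort tibble.
#' @param edge Length-2 integer vector `(i, j)` of ROI indices.
#' @param window_lengths Integer vector of window lengths `L` to profile.
#' @param type Network type for the dynamic networks (default `"low"`).
#' @param step Window step `S` (default 1).
#' @param demean Passed to [power_spectrum()].
#' @return Tibble of class `hyfc_spectrum_separability` with columns
#'   `window_length`, `bin`, `frequency_hz`, `r2`.
#' @export
spectrum_separability <- function(cohort, edge, window_lengths,
                                  type = "low", step = 1, demean = FALSE) {
  check_cohort(cohort)
  type <- match.arg(type, hyfc_types)
  y <- as_binary_labels(cohort$label)
  out <- purrr::map(window_lengths, function(l) {
    spec <- window_spec(l, step)
    pw <- lapply(cohort$series, function(x) {
      nets <- build_networks(x, spec, types = type)
      power_spectrum(edge_series(nets[[type]], edge[1L], edge[2L]),
                     demean = demean)
    })
    pw <- do.call(rbind, pw) # N x Q
    k <- window_count(nrow(cohort$series[[1L]]), spec)
    freqs <- spectral_frequencies(k, step, cohort$tr_seconds[1L])
    r2 <- apply(pw, 2L, function(v) {
      tryCatch(pointwise_r2(v, y),
               hyfcnet_undefined_separability = function(e) NA_real_)
    })
    tibble::tibble(window_length = l, bin = seq_along(freqs),
                   frequency_hz = freqs, r2 = r2)
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("hyfc_spectrum_separability", class(out))
  out
}

#' @rdname tidiers
#' @method autoplot hyfc_spectrum_separability
#' @export
autoplot.hyfc_spectrum_separability <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$frequency_hz, y = .data$r2,
                                       colour = factor(.data$window_length))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Frequency (Hz)", y = expression(r^2),
                  colour = "Window L",
                  title = "Dynamic-FC spectrum separability") +
    ggplot2::theme_minimal()
}
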