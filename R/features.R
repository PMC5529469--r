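#' Weighted local clustering coefficient
#'
#' Nodal "cliqueness" of a weighted graph with nonnegative symmetric weights
#' `Z`: for node `i`, with neighborhood `Omega_i = { j != i : Z_ij > 0 }` of
#' size `v_i`,
#' \deqn{f_i = 2 \sum_{j \in \Omega_i} Z_{ij}^{1/3} / (v_i (v_i - 1)).}
#' Nodes with `v_i <= 1` have no cliqueness and score 0. No sparsification
#' threshold is applied: any strictly positive weight counts as an edge.
#'
#' @param z Nonnegative symmetric `R x R` weight matrix (`R >= 3`), e.g. one
#'   frequency network from [spectral_stack()].
#' @param nodes Optional node indices; default all nodes.
#' @return Numeric vector of WLCC values (named after rownames of `z`).
#' @examples
#' z <- matrix(0, 3, 3); z[1, 2] <- z[2, 1] <- 1; z[1, 3] <- z[3, 1] <- 1
#' wlcc(z)[1] # node 1: two unit-weight neighbors -> 2 * (1 + 1) / (2 * 1) = 2
#' @export
wlcc <- function(z, nodes = NULL) {
  z <- as.matrix(z)
  r <- nrow(z)
  if (r < 3L || ncol(z) != r) {
    stop_hyfc("`z` must be a square matrix with at least 3 nodes.",
              class = "invalid_argument")
  }
  if (any(z < 0)) {
    stop_hyfc("negative weights are not allowed in the clustering coefficient.",
              class = "invalid_weight")
  }
  scale <- max(abs(z), 1e-300)
  if (max(abs(z - t(z))) > 1e-8 * scale) {
    stop_hyfc("weight matrix is asymmetric beyond tolerance.", class = "asymmetry")
  }
  diag(z) <- 0
  v <- rowSums(z > 0)
  s <- rowSums(z^(1 / 3))
  f <- ifelse(v > 1, 2 * s / (v * (v - 1)), 0)
  names(f) <- rownames(z)
  if (is.null(nodes)) f else f[nodes]
}

#' WLCC feature vector of a spectral network stack
#'
#' Concatenates the per-node clustering coefficients of all `Q` frequency
#' networks, frequency-major: `(f^1_1..f^1_R, f^2_1..f^2_R, ...)`, giving a
#' length `Q * R` vector. Names encode the frequency bin and ROI.
#'
#' @param stack A `hyfc_spectra` object from [spectral_stack()].
#' @return Named numeric vector of length `Q * R`.
#' @export
wlcc_features <- function(stack) {
  stopifnot(inherits(stack, "hyfc_spectra"))
  r <- nrow(stack$spectra[[1L]])
  rois <- rownames(stack$spectra[[1L]]) %||% sprintf("ROI%02d", seq_len(r))
  out <- unlist(lapply(seq_along(stack$spectra), function(qi) {
    f <- withCallingHandlers(
      wlcc(stack$spectra[[qi]]),
      hyfcnet_error = function(e) {
        stop_hyfc(sprintf("in frequency bin %d: %s", qi, conditionMessage(e)),
                  class = "feature_error", parent = e)
      }
    )
    stats::setNames(f, sprintf("q%02d_%s", qi, rois))
  }), use.names = TRUE)
  out
}

#' Static-network WLCC features
#'
#' For the static pathway there is no spectrum; the clustering coefficient is
#' taken directly on the full-series connectivity matrix. Correlations can be
#' negative, so a nonnegative edge transform is applied first: `"abs"`
#' (default) uses the correlation magnitude, `"positive"` zeroes negative
#' edges.
#'
#' @param mat Static `R x R` connectivity matrix.
#' @param edge_transform `"abs"` or `"positive"`.
#' @return Named numeric vector of length `R`.
#' @export
static_features <- function(mat, edge_transform = c("abs", "positive")) {
  edge_transform <- match.arg(edge_transform)
  w <- if (edge_transform == "abs") abs(mat) else pmax(mat, 0)
  w <- (w + t(w)) / 2 # guard rounding asymmetry from abs of a symmetrized matrix
  f <- wlcc(w)
  rois <- rownames(mat) %||% sprintf("ROI%02d", seq_len(nrow(mat)))
  stats::setNames(f, sprintf("static_%s", rois))
}

#' Cohort feature table
#'
#' Runs the full feature-extraction pathway for every subject of a cohort:
#' sliding-window networks of the requested types, per-edge power spectra,
#' and WLCC feature vectors per frequency network. Returns a tidy tibble with
#' one row per subject x network type and the feature vector in a list
#' column, ready for [nested_loocv()].
#'
#' @param cohort Cohort tibble from [simulate_cohort()] or [read_cohort()]
#'   (columns `subject_id`, `label`, `series`, `tr_seconds`).
#' @param window A [window_spec()]; ignored when `static = TRUE`.
#' @param types Network types to extract.
#' @param static If `TRUE`, use full-series static networks and
#'   [static_features()] instead of the spectral pathway.
#' @param demean Passed to [spectral_stack()].
#' @param edge_transform Passed to [static_features()] when `static = TRUE`.
#' @return Tibble with columns `subject_id`, `label`, `network_type`,
#'   `features` (list of named numeric vectors).
#' @examples
#' \donttest{
#' co <- simulate_cohort(n_per_group = 3, n_roi = 8, n_timepoints = 40, seed = 1)
#' ft <- hyfc_features(co, window_spec(20, 2), types = "low")
#' }
#' @export
hyfc_features <- function(cohort, window = window_spec(70, 1),
                          types = hyfc_types, static = FALSE,
                          demean = FALSE, edge_transform = "abs") {
  types <- match_types(types)
  check_cohort(cohort)
  rows <- purrr::map(seq_len(nrow(cohort)), function(si) {
    x <- cohort$series[[si]]
    tr <- cohort$tr_seconds[si]
    nets <- build_networks(x, spec = if (static) NULL else window, types = types)
    feats <- purrr::map(types, function(tp) {
      if (static) {
        static_features(nets[[tp]][[1L]], edge_transform = edge_transform)
      } else {
        wlcc_features(spectral_stack(nets[[tp]], step_s = window$step_s,
                                     tr_seconds = tr, demean = demean))
      }
    })
    tibble::tibble(
      subject_id = cohort$subject_id[si],
      label = cohort$label[si],
      network_type = types,
      features = feats
    )
  })
  dplyr::bind_rows(rows)
}

#' Feature matrix of one network type
#'
#' @param features_tbl Output of [hyfc_features()].
#' @param type One of the network types present in the table.
#' @return `N x D` numeric matrix (rows named by subject).
#' @export
feature_matrix <- function(features_tbl, type) {
  sub <- dplyr::filter(features_tbl, .data$network_type == type)
  if (nrow(sub) == 0L) {
    stop_hyfc(sprintf("no rows of network type '%s' in the feature table.", type),
              class = "invalid_argument")
  }
  m <- do.call(rbind, sub$features)
  rownames(m) <- sub$subject_id
  m
}

#' @importFrom rlang .data
#' @keywords internal
feature_matrices <- function(features_tbl) {
  types <- unique(features_tbl$network_type)
  labs <- dplyr::distinct(features_tbl, .data$subject_id, .data$label)
  x <- stats::setNames(lapply(types, feature_matrix, features_tbl = features_tbl), types)
  for (m in x) {
    if (!identical(rownames(m), labs$subject_id)) {
      stop_hyfc("subject order differs across network types.", class = "invalid_argument")
    }
  }
  list(features = x, labels = as_binary_labels(labs$label),
       subject_id = labs$subject_id)
}
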