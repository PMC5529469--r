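#' Simulate a two-group ROI time-series cohort
#'
#' Generates per-subject `P x R` ROI time series from a latent-factor model
#' with time-varying within-module coupling, emulating the kind of dynamic-FC
#' group differences the sliding-window pipeline is designed to detect. ROIs
#' are partitioned into `n_modules` modules; at scan time `t` every ROI in
#' module `m` follows
#' \deqn{x_i(t) = \sqrt{\rho(t)}\, u_m(t) + \sqrt{1 - \rho(t)}\, e_i(t) + \sigma\, \eta_i(t)}
#' with independent standard-normal factors `u_m`, `e_i` and observation
#' noise `eta_i`, so that within-module signal coupling equals
#' `rho(t) = base_coupling + a sin(2 pi f t + phi)` (clipped to `[0, 0.95]`),
#' with group-specific modulation amplitude `a` and frequency `f` and a
#' uniform random phase `phi` per subject. Controls are labelled 0, cases 1.
#'
#' Presets bundle the study conditions: `"null"` plants no group difference
#' (both amplitudes 0); `"strong"` gives cases a deep coupling modulation
#' (amplitude 0.9, so within-module connectivity cycles between collapse and
#' saturation) and controls none — an idealized, clearly detectable
#' dynamic-connectivity effect at desk scale.
#'
#' @param n_per_group Subjects per group (default 15).
#' @param n_roi Number of ROIs `R` (default 30).
#' @param n_timepoints Volumes `P` per subject (default 130, the usable scan
#'   length after equilibration dropout at TR = 3 s).
#' @param tr_seconds Repetition time (default 3).
#' @param n_modules Functional modules (default 2: at a coarse 30-ROI
#'   parcellation, two large intrinsic systems).
#' @param base_coupling Baseline within-module coupling in (0, 1)
#'   (default 0.3).
#' @param modulation_amplitude Length-2 vector `(control, case)` of coupling
#'   modulation amplitudes, `>= 0`.
#' @param modulation_frequency_hz Length-2 vector `(control, case)` of
#'   modulation frequencies in Hz; must lie below the dynamic-FC Nyquist
#'   `1 / (2 * TR)`. Default `1/183` Hz, the fundamental of the default
#'   61-window edge-series spectrum.
#' @param noise_sd Observation noise standard deviation, `> 0` (default 0.3).
#' @param seed Integer seed; the cohort is a deterministic function of the
#'   arguments and the seed.
#' @param preset `NULL`, `"null"` or `"strong"`; a preset overrides
#'   `modulation_amplitude`.
#' @return Tibble with one row per subject: `subject_id`, `group`
#'   (`control`/`case`), `label` (0/1), `tr_seconds`, `module` (list of the
#'   ROI-to-module assignment) and `series` (list of `P x R` matrices with
#'   ROI column names).
#' @examples
#' co <- simulate_cohort(n_per_group = 2, n_roi = 10, n_timepoints = 40, seed = 7)
#' dim(co$series[[1]])
#' @export
simulate_cohort <- function(n_per_group = 15, n_roi = 30, n_timepoints = 130,
                            tr_seconds = 3, n_modules = 2,
                            base_coupling = 0.3,
                            modulation_amplitude = c(0, 0),
                            modulation_frequency_hz = c(1 / 183, 1 / 183),
                            noise_sd = 0.3, seed,
                            preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("null", "strong"))
    modulation_amplitude <- switch(preset, null = c(0, 0), strong = c(0, 0.9))
  }
  n_per_group <- check_count(n_per_group, "n_per_group")
  n_roi <- check_count(n_roi, "n_roi", min = 2L)
  n_timepoints <- check_count(n_timepoints, "n_timepoints", min = 2L)
  n_modules <- check_count(n_modules, "n_modules")
  if (n_modules > n_roi) {
    stop_hyfc("`n_modules` cannot exceed `n_roi`.", class = "invalid_spec")
  }
  if (!is_scalar_number(tr_seconds) || tr_seconds <= 0) {
    stop_hyfc("`tr_seconds` must be a positive number.", class = "invalid_spec")
  }
  if (!is_scalar_number(base_coupling) || base_coupling <= 0 || base_coupling >= 1) {
    stop_hyfc("`base_coupling` must lie strictly inside (0, 1).", class = "invalid_spec")
  }
  if (length(modulation_amplitude) != 2L || any(modulation_amplitude < 0)) {
    stop_hyfc("`modulation_amplitude` must be two nonnegative numbers (control, case).",
              class = "invalid_spec")
  }
  nyquist <- 1 / (2 * tr_seconds)
  if (length(modulation_frequency_hz) != 2L ||
      any(modulation_frequency_hz < 0) || any(modulation_frequency_hz >= nyquist)) {
    stop_hyfc(sprintf(
      "`modulation_frequency_hz` must be two frequencies in [0, %.4g) Hz (dynamic-FC Nyquist at TR = %g s).",
      nyquist, tr_seconds), class = "invalid_spec")
  }
  if (!is_scalar_number(noise_sd) || noise_sd <= 0) {
    stop_hyfc("`noise_sd` must be > 0.", class = "invalid_spec")
  }
  if (missing(seed)) {
    stop_hyfc("`seed` is required: cohorts are reproducible by construction.",
              class = "invalid_spec")
  }
  seed <- check_count(seed, "seed", min = 0L)

  module <- sort(rep_len(seq_len(n_modules), n_roi))
  rois <- sprintf("ROI%02d", seq_len(n_roi))
  t_sec <- (seq_len(n_timepoints) - 1L) * tr_seconds
  n <- 2L * n_per_group
  group_of <- rep(c(0L, 1L), each = n_per_group)

  series <- withr::with_seed(seed, {
    lapply(seq_len(n), function(s) {
      g <- group_of[s] + 1L
      phi <- stats::runif(1, 0, 2 * pi)
      rho <- base_coupling + modulation_amplitude[g] *
        sin(2 * pi * modulation_frequency_hz[g] * t_sec + phi)
      rho <- pmin(pmax(rho, 0), 0.95)
      u <- matrix(stats::rnorm(n_timepoints * n_modules), n_timepoints, n_modules)
      e <- matrix(stats::rnorm(n_timepoints * n_roi), n_timepoints, n_roi)
      eta <- matrix(stats::rnorm(n_timepoints * n_roi), n_timepoints, n_roi)
      x <- sqrt(rho) * u[, module, drop = FALSE] + sqrt(1 - rho) * e +
        noise_sd * eta
      colnames(x) <- rois
      if (any(apply(x, 2L, stats::sd) == 0)) {
        stop_hyfc("generated a constant ROI series; increase `noise_sd`.",
                  class = "degenerate_signal")
      }
      x
    })
  })

  tibble::tibble(
    subject_id = sprintf("sub%03d", seq_len(n)),
    group = factor(ifelse(group_of == 1L, "case", "control"),
                   levels = c("control", "case")),
    label = group_of,
    tr_seconds = tr_seconds,
    module = list(stats::setNames(module, rois)),
    series = series
  )
}

check_cohort <- function(cohort) {
  need <- c("subject_id", "label", "tr_seconds", "series")
  if (!is.data.frame(cohort) || !all(need %in% names(cohort))) {
    stop_hyfc(sprintf("a cohort needs columns %s.", paste(need, collapse = ", ")),
              class = "invalid_cohort")
  }
  dims <- vapply(cohort$series, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])[1L]
    stop_hyfc(sprintf("subject %s has series dimensions %dx%d, expected %dx%d.",
                      cohort$subject_id[bad], dims[1, bad], dims[2, bad],
                      dims[1, 1], dims[2, 1]),
              class = "dimension_mismatch")
  }
  invisible(cohort)
}

#' Write a cohort to per-subject CSV files plus a manifest
#'
#' Each subject's series is written as a CSV (first row = ROI labels, rows =
#' time points) and a `manifest.csv` with columns `subject_id`, `path`,
#' `label`, `tr_seconds` indexes them.
#'
#' @param cohort Cohort tibble (see [simulate_cohort()]).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  check_cohort(cohort)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(cohort$subject_id, ".csv"))
  for (i in seq_len(nrow(cohort))) {
    # 17 significant digits guarantee an exact double round trip
    m <- cohort$series[[i]]
    ch <- matrix(sprintf("%.17g", m), nrow(m), ncol(m),
                 dimnames = dimnames(m))
    readr::write_csv(as.data.frame(ch), paths[i])
  }
  manifest <- tibble::tibble(
    subject_id = cohort$subject_id,
    path = basename(paths),
    label = cohort$label,
    tr_seconds = cohort$tr_seconds
  )
  mpath <- file.path(dir, "manifest.csv")
  readr::write_csv(manifest, mpath)
  invisible(mpath)
}

#' Read a cohort from a subject manifest
#'
#' Expects the layout written by [write_cohort()]: a manifest CSV with
#' columns `subject_id`, `path` (relative to the manifest), `label` (binary)
#' and optionally `tr_seconds`, pointing at per-subject time-series CSVs
#' (first row = ROI labels). All subjects must share the same ROI set and
#' order.
#'
#' @param manifest_path Path to the manifest CSV.
#' @param tr_seconds Fallback repetition time when the manifest has no
#'   `tr_seconds` column.
#' @return Cohort tibble in manifest order.
#' @export
read_cohort <- function(manifest_path, tr_seconds = 3) {
  if (!file.exists(manifest_path)) {
    stop_hyfc(sprintf("manifest not found: %s", manifest_path), class = "missing_file")
  }
  manifest <- readr::read_csv(manifest_path, show_col_types = FALSE)
  need <- c("subject_id", "path", "label")
  if (!all(need %in% names(manifest))) {
    stop_hyfc(sprintf("manifest must have columns %s.", paste(need, collapse = ", ")),
              class = "invalid_manifest")
  }
  labels <- as_binary_labels(manifest$label)
  base <- dirname(manifest_path)
  series <- lapply(seq_len(nrow(manifest)), function(i) {
    p <- manifest$path[i]
    if (!file.exists(p)) p <- file.path(base, manifest$path[i])
    if (!file.exists(p)) {
      stop_hyfc(sprintf("time-series file not found for subject %s: %s",
                        manifest$subject_id[i], manifest$path[i]),
                class = "missing_file")
    }
    # base strtod parsing is correctly rounded, giving exact round trips
    m <- as.matrix(utils::read.csv(p, check.names = FALSE))
    storage.mode(m) <- "double"
    m
  })
  rois <- colnames(series[[1L]])
  for (i in seq_along(series)) {
    if (!identical(colnames(series[[i]]), rois)) {
      stop_hyfc(sprintf("subject %s has different ROI labels/order.",
                        manifest$subject_id[i]), class = "dimension_mismatch")
    }
  }
  cohort <- tibble::tibble(
    subject_id = manifest$subject_id,
    group = factor(ifelse(labels == 1L, "case", "control"),
                   levels = c("control", "case")),
    label = labels,
    tr_seconds = if ("tr_seconds" %in% names(manifest)) manifest$tr_seconds else tr_seconds,
    series = series
  )
  check_cohort(cohort)
}

#' Tiny hand-checkable fixture inputs
#'
#' Deterministic miniature matrices used throughout the unit tests: a
#' `10 x 3` integer time series (whose 3 windows under `L = 4, S = 3` start
#' at rows 1, 4, 7) and an `R = 3, Q = 2` spectral stack exercising the
#' frequency-major feature ordering. Byte-stable across calls.
#'
#' @param seed Seed for the randomized fixture entries (default 1).
#' @return Named list with elements `windowing` (matrix) and `stack`
#'   (`hyfc_spectra`).
#' @export
fixture_matrices <- function(seed = 1) {
  windowing <- matrix(as.numeric(1:30), nrow = 10, ncol = 3,
                      dimnames = list(NULL, c("ROI01", "ROI02", "ROI03")))
  windowing[, 2] <- rev(windowing[, 2])
  windowing[, 3] <- (windowing[, 3] * 7) %% 11
  z1 <- matrix(c(0, 2, 1,
                 2, 0, 0.5,
                 1, 0.5, 0), 3, 3)
  z2 <- withr::with_seed(seed, {
    m <- matrix(stats::runif(9), 3, 3)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    m
  })
  stack <- structure(
    list(spectra = list(z1, z2),
         frequencies_hz = c(0, 1 / 9),
         n_windows = 3L),
    class = "hyfc_spectra"
  )
  list(windowing = windowing, stack = stack)
}
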