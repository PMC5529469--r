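#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom generics tidy glance
NULL

# Classed abort so callers/tests can match on condition class rather than text.
stop_hyfc <- function(msg, class, ...) {
  rlang::abort(msg, class = c(paste0("hyfcnet_", class), "hyfcnet_error"), ...)
}

# Clamp correlation-valued matrices into [-1, 1]; entries only ever exceed the
# range by floating-point rounding of unit-vector inner products.
clamp_unit <- function(m) {
  m[m > 1] <- 1
  m[m < -1] <- -1
  m
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_count <- function(x, name, min = 1L) {
  if (!is_scalar_number(x) || x != as.integer(x) || x < min) {
    stop_hyfc(
      sprintf("`%s` must be a single integer >= %d (got %s).", name, min,
              paste(format(x), collapse = ", ")),
      class = "invalid_argument"
    )
  }
  as.integer(x)
}

# Coerce labels to the internal 0/1 integer coding; accepts 0/1, -1/+1,
# logicals or a two-level factor.
as_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  if (is.logical(labels)) labels <- as.integer(labels)
  u <- sort(unique(labels))
  if (identical(u, c(-1, 1)) || identical(u, c(-1L, 1L))) {
    labels <- as.integer(labels > 0)
  }
  if (!all(labels %in% c(0, 1))) {
    stop_hyfc("labels must be binary (0/1, -1/+1, logical or two-level factor).",
              class = "invalid_labels")
  }
  as.integer(labels)
}
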