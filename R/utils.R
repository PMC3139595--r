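# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Strict upper triangle values of a square matrix, row-major over (i < j).
#' @keywords internal
upper_tri_values <- function(m) {
  m[upper.tri(m)]
}

# Indices (i, j) of the strict upper triangle in the same order as
# upper_tri_values (column-major, i < j).
#' @keywords internal
upper_tri_index <- function(n) {
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  idx[order(idx[, 2L], idx[, 1L]), , drop = FALSE]
}

# Rebuild a symmetric matrix (unit diagonal by default) from its strict
# upper-triangle vector.
#' @keywords internal
sym_from_upper <- function(values, n, diag_value = 1) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- values
  m <- m + t(m)
  diag(m) <- diag_value
  m
}

# Deterministic per-unit seed derived from a master seed and a small set of
# counters; keeps every stochastic unit reproducible independently of loop
# order. Result stays inside 32-bit integer range.
#' @keywords internal
derive_seed <- function(seed, ...) {
  counters <- c(...)
  x <- as.double(seed)
  for (k in counters) {
    x <- (x * 69069 + as.double(k) * 12345 + 1) %% 2147483647
  }
  as.integer(x)
}

#' @keywords internal
is_square_numeric <- function(m) {
  is.matrix(m) && is.numeric(m) && nrow(m) == ncol(m)
}

# Validate a correlation matrix: symmetric, unit diagonal, entries in [-1, 1].
#' @keywords internal
check_corr_matrix <- function(m, tol = 1e-8) {
  stopifnot(is_square_numeric(m))
  if (max(abs(m - t(m))) > tol) {
    stop("correlation matrix is not symmetric", call. = FALSE)
  }
  if (max(abs(diag(m) - 1)) > tol) {
    stop("correlation matrix diagonal is not 1", call. = FALSE)
  }
  if (max(abs(m)) > 1 + tol) {
    stop("correlation entries outside [-1, 1]", call. = FALSE)
  }
  invisible(m)
}

#' @keywords internal
roi_labels_of <- function(m) {
  rownames(m) %||% paste0("roi", seq_len(nrow(m)))
}
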