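# From ROI time series to per-subject-scan Pearson connectivity matrices:
# nuisance regression, temporal filtering, Fisher-z utilities, scan averaging,
# and matrix similarity.

#' Construct a ROI time-series matrix
#'
#' Container for one subject-scan's ROI time courses: `T` timepoints by `N`
#' regions of interest. Columns are ROI mean time series; the sampling
#' interval is the repetition time in seconds (e.g. 2.0 for TR = 2000 ms).
#'
#' @param values numeric matrix, timepoints x ROIs.
#' @param roi_labels character vector of ROI names; defaults to colnames or
#'   `roi1..roiN`.
#' @param subject_id,scan_id identifier strings.
#' @param sampling_interval sampling interval in seconds.
#' @return An object of class `time_series_matrix`.
#' @examples
#' ts <- time_series_matrix(matrix(rnorm(400), 100, 4), sampling_interval = 2)
#' dim(ts$values)
#' @export
time_series_matrix <- function(values, roi_labels = NULL,
                               subject_id = "sub-01", scan_id = "scan-1",
                               sampling_interval = 2.0) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 4) stop("need at least 4 timepoints")
  if (anyNA(values)) stop("time series contains missing values")
  if (is.null(roi_labels)) {
    roi_labels <- colnames(values) %||% paste0("roi", seq_len(ncol(values)))
  }
  stopifnot(length(roi_labels) == ncol(values))
  colnames(values) <- roi_labels
  structure(
    list(values = values, roi_labels = roi_labels,
         subject_id = subject_id, scan_id = scan_id,
         sampling_interval = sampling_interval),
    class = "time_series_matrix"
  )
}

#' @export
print.time_series_matrix <- function(x, ...) {
  cat(sprintf("<time_series_matrix> %s/%s: %d timepoints x %d ROIs, TR = %gs\n",
              x$subject_id, x$scan_id, nrow(x$values), ncol(x$values),
              x$sampling_interval))
  invisible(x)
}

#' Zero-phase band-pass filter of ROI time series
#'
#' Applies a forward-backward (zero-phase) 2nd-order Butterworth band-pass to
#' every ROI column and removes the column mean. The standard resting-state
#' band is 0.01-0.1 Hz.
#'
#' @param ts a [time_series_matrix()].
#' @param low_hz,high_hz band edges in Hz; `high_hz` must be below the
#'   Nyquist frequency `1 / (2 * sampling_interval)`.
#' @param order Butterworth order of the one-pass design (effective order is
#'   doubled by the forward-backward application).
#' @return A filtered `time_series_matrix` of the same shape.
#' @export
bandpass_filter <- function(ts, low_hz = 0.01, high_hz = 0.1, order = 2) {
  stopifnot(inherits(ts, "time_series_matrix"))
  nyquist <- 1 / (2 * ts$sampling_interval)
  if (!(low_hz >= 0 && low_hz < high_hz)) stop("need 0 <= low_hz < high_hz")
  if (high_hz >= nyquist) {
    stop(sprintf("high_hz (%g) must be below Nyquist (%g Hz)", high_hz, nyquist))
  }
  x <- ts$values
  # filtfilt needs some padding room; 3x the filter length is a safe floor
  if (nrow(x) < 3 * (2 * order + 1)) {
    stop("time series too short for the requested filter order")
  }
  x <- sweep(x, 2, colMeans(x))
  bf <- signal::butter(order, c(low_hz, high_hz) / nyquist, type = "pass")
  out <- apply(x, 2, function(col) signal::filtfilt(bf, col))
  out <- sweep(out, 2, colMeans(out))
  ts$values <- out
  colnames(ts$values) <- ts$roi_labels
  ts
}

#' Regress nuisance signals out of ROI time series
#'
#' Least-squares regression of each ROI column on an intercept plus the
#' supplied nuisance regressors (e.g. head-motion profiles, global signal);
#' the residuals replace the series. With no regressors this demeans each
#' column.
#'
#' @param ts a [time_series_matrix()].
#' @param nuisance numeric matrix (timepoints x regressors) or `NULL` for
#'   intercept-only.
#' @return A `time_series_matrix` of residuals, orthogonal to every
#'   regressor column.
#' @export
regress_nuisance <- function(ts, nuisance = NULL) {
  stopifnot(inherits(ts, "time_series_matrix"))
  n <- nrow(ts$values)
  if (is.null(nuisance)) {
    design <- matrix(1, n, 1)
    colnames(design) <- "intercept"
  } else {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != n) stop("nuisance rows must match timepoints")
    design <- cbind(intercept = 1, nuisance)
  }
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    bad <- colnames(design)[setdiff(seq_len(ncol(design)), qrd$pivot[seq_len(qrd$rank)])]
    stop("rank-deficient nuisance design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  ts$values <- qr.resid(qrd, ts$values)
  colnames(ts$values) <- ts$roi_labels
  ts
}

#' Pearson connectivity matrix of a time-series matrix
#'
#' Interregional functional connectivity: the Pearson correlation between
#' every pair of ROI time courses, with the diagonal fixed at 1.
#'
#' @param ts a [time_series_matrix()].
#' @return A symmetric N x N correlation matrix with ROI labels as dimnames
#'   and attributes `subject_id` / `scan_id`.
#' @export
correlation_matrix <- function(ts) {
  stopifnot(inherits(ts, "time_series_matrix"))
  sds <- apply(ts$values, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant ROI time series: ",
         paste(ts$roi_labels[sds == 0], collapse = ", "))
  }
  r <- stats::cor(ts$values)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  dimnames(r) <- list(ts$roi_labels, ts$roi_labels)
  attr(r, "subject_id") <- ts$subject_id
  attr(r, "scan_id") <- ts$scan_id
  r
}

#' Fisher r-to-z transform and its inverse
#'
#' `fisher_z` maps a correlation to `atanh(r)`; `fisher_z_inv` maps back with
#' `tanh`. Used for variance-stabilized averaging of connectivity matrices.
#'
#' @param r correlation values, `|r| < 1`.
#' @param z Fisher-z values.
#' @return Transformed numeric vector/matrix of the same shape.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE)) stop("fisher_z requires |r| < 1")
  atanh(r)
}

#' @rdname fisher_z
#' @export
fisher_z_inv <- function(z) tanh(z)

#' Average connectivity matrices across scans
#'
#' Off-diagonal entries are averaged in Fisher-z space and transformed back
#' (the field-standard variance-stabilized average), or directly in r-space
#' if requested. Used to pool scans 2 and 3 into the long-term condition.
#'
#' @param ms list of correlation matrices with identical shape and labels.
#' @param space `"z"` (default) or `"r"`.
#' @return A correlation matrix.
#' @export
average_matrices <- function(ms, space = c("z", "r")) {
  space <- match.arg(space)
  stopifnot(is.list(ms), length(ms) >= 2)
  n <- nrow(ms[[1]])
  labs <- roi_labels_of(ms[[1]])
  for (m in ms) {
    check_corr_matrix(m)
    if (nrow(m) != n || !identical(roi_labels_of(m), labs)) {
      stop("matrices must share shape and ROI labels")
    }
  }
  uppers <- vapply(ms, upper_tri_values, numeric(n * (n - 1) / 2))
  avg <- if (space == "z") {
    fisher_z_inv(rowMeans(fisher_z(uppers)))
  } else {
    rowMeans(uppers)
  }
  out <- sym_from_upper(avg, n)
  dimnames(out) <- list(labs, labs)
  out
}

#' Spatial similarity of two connectivity matrices
#'
#' Pearson correlation over the strict upper triangles (diagonal excluded)
#' of two matrices, quantifying how similar the connectivity patterns are.
#'
#' @param a,b correlation matrices of identical shape/labels.
#' @return list with `r`, `p` (two-sided), and `n_edges`.
#' @export
matrix_similarity <- function(a, b) {
  stopifnot(is_square_numeric(a), is_square_numeric(b))
  if (nrow(a) < 3) stop("need at least 3 ROIs")
  if (nrow(a) != nrow(b) || !identical(roi_labels_of(a), roi_labels_of(b))) {
    stop("matrices must share shape and ROI labels")
  }
  ua <- upper_tri_values(a)
  ub <- upper_tri_values(b)
  ct <- stats::cor.test(ua, ub)
  list(r = unname(ct$estimate), p = ct$p.value, n_edges = length(ua))
}
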