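# Plain-text interchange: square matrix TSVs, time-series TSVs, nuisance
# tables, edge lists, and metric tables.

#' Read / write a square labelled matrix as TSV
#'
#' The on-disk format is a square tab-separated table with a leading header
#' row and leading label column holding the ROI names.
#'
#' @param path file path.
#' @param m square numeric matrix with dimnames.
#' @return `read_matrix_tsv` returns the matrix; `write_matrix_tsv` returns
#'   the path invisibly.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (!identical(rownames(m), colnames(m))) {
    stop("matrix TSV row and column labels disagree: ", path)
  }
  m
}

#' @rdname read_matrix_tsv
#' @export
write_matrix_tsv <- function(m, path) {
  stopifnot(is_square_numeric(m))
  labs <- roi_labels_of(m)
  dimnames(m) <- list(labs, labs)
  df <- data.frame(roi = labs, m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write ROI time series as TSV
#'
#' Header row = ROI labels, one row per timepoint.
#'
#' @param path file path.
#' @param ts a [time_series_matrix()].
#' @param ... passed to [time_series_matrix()] (ids, sampling interval).
#' @export
read_timeseries_tsv <- function(path, ...) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  time_series_matrix(as.matrix(df), roi_labels = colnames(df), ...)
}

#' @rdname read_timeseries_tsv
#' @export
write_timeseries_tsv <- function(ts, path) {
  stopifnot(inherits(ts, "time_series_matrix"))
  utils::write.table(ts$values, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a thresholded network as an edge list with a JSON sidecar
#'
#' Edge list TSV columns: `i_label`, `j_label`, `weight`; the sidecar
#' records kind, membership, sparsity and the threshold used.
#'
#' @param net a `brain_network`.
#' @param path edge-list path; the sidecar is `<path>.json`.
#' @export
write_network_tsv <- function(net, path) {
  stopifnot(inherits(net, "brain_network"))
  adj <- net$adjacency
  idx <- which(upper.tri(adj) & adj != 0, arr.ind = TRUE)
  labs <- net$roi_labels
  df <- data.frame(i_label = labs[idx[, 1]], j_label = labs[idx[, 2]],
                   weight = adj[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(kind = net$kind, membership = net$membership,
         sparsity = net$sparsity, threshold_used = net$threshold_used),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a long-format metric table as TSV
#'
#' Columns: subject, scan, membership, kind, sparsity, metric, node (empty
#' for global metrics), value, flag.
#'
#' @param tab data frame as produced by [metrics_over_grid()].
#' @param path file path.
#' @export
write_metric_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
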