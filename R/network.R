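# Sparsity thresholding: converting correlation matrices into binarized or
# weighted undirected networks with an exact edge count at each sparsity
# level, under positive-only or absolute-value edge membership.

#' Sparsity grid
#'
#' Ordered sparsity levels in (0, 1). Sparsity S is the fraction of possible
#' edges retained: E / (N(N-1)/2). The default grid covers the full range in
#' steps of 0.01; callers truncate at the group-wise minimum attainable
#' sparsity when comparing scan conditions.
#'
#' @param from,to grid limits in (0, 1).
#' @param step grid spacing.
#' @return numeric vector of class `sparsity_grid`.
#' @export
sparsity_grid <- function(from = 0.01, to = 0.99, step = 0.01) {
  stopifnot(from > 0, to < 1, from <= to, step > 0)
  values <- seq(from, to, by = step)
  structure(values, step = step, class = c("sparsity_grid", "numeric"))
}

#' Maximum attainable sparsity of a correlation matrix
#'
#' Under absolute-value membership every connection is eligible, so the
#' maximum is 1. Under positive-only membership negative correlations are
#' zeroed, so the maximum is the fraction of strictly positive connections.
#'
#' @param m correlation matrix.
#' @param membership `"positive_only"` or `"absolute_both"`.
#' @return scalar in \[0, 1\].
#' @export
max_sparsity <- function(m, membership = c("positive_only", "absolute_both")) {
  membership <- match.arg(membership)
  stopifnot(is_square_numeric(m))
  if (membership == "absolute_both") return(1)
  u <- upper_tri_values(m)
  sum(u > 0) / length(u)
}

# Half-up rounding of the target edge count; deterministic and monotone in S.
#' @keywords internal
round_half_up <- function(x) floor(x + 0.5)

#' Threshold a correlation matrix at an exact sparsity level
#'
#' Connections are ranked by salience — `|r|` under absolute-value
#' membership, `r` after zeroing negatives under positive-only — and the top
#' `E = round_half_up(S * N(N-1)/2)` are kept, so every subject and scan ends
#' up with exactly the same number of edges. The implied subject-specific
#' correlation threshold `r0` (the smallest kept salience) is recorded.
#' Binarized networks carry 0/1 edges; weighted networks carry the salience
#' as weight (absolute value under absolute-value membership, the raw
#' positive correlation under positive-only). Ties at the cut are broken by
#' lexicographic (row, column) order, so edge sets are deterministic and
#' nested across sparsity levels.
#'
#' @param m correlation matrix.
#' @param s target sparsity in (0, max_sparsity\].
#' @param membership `"positive_only"` or `"absolute_both"`.
#' @param kind `"binarized"` or `"weighted"`.
#' @return A `brain_network`: list with `adjacency`, `kind`, `membership`,
#'   `sparsity`, `threshold_used`, `roi_labels`, `n_edges`.
#' @export
threshold_at_sparsity <- function(m, s,
                                  membership = c("positive_only", "absolute_both"),
                                  kind = c("binarized", "weighted")) {
  membership <- match.arg(membership)
  kind <- match.arg(kind)
  stopifnot(is_square_numeric(m))
  n <- nrow(m)
  e_max <- n * (n - 1) / 2
  s_max <- max_sparsity(m, membership)
  if (!(s > 0 && s <= s_max + 1e-12)) {
    stop(sprintf("sparsity %g outside (0, S_max = %g]", s, s_max))
  }
  e_target <- round_half_up(s * e_max)
  if (e_target == 0) stop("requested sparsity yields zero edges")

  idx <- upper_tri_index(n)
  r <- m[idx]
  salience <- if (membership == "absolute_both") abs(r) else pmax(r, 0)
  # order by decreasing salience, ties by (i, j) lexicographic
  ord <- order(-salience, idx[, 1L], idx[, 2L])
  keep <- ord[seq_len(e_target)]
  r0 <- min(salience[keep])

  adj <- matrix(0, n, n)
  ki <- idx[keep, , drop = FALSE]
  w <- if (kind == "binarized") 1 else salience[keep]
  adj[ki] <- w
  adj <- adj + t(adj)
  labs <- roi_labels_of(m)
  dimnames(adj) <- list(labs, labs)

  structure(
    list(adjacency = adj, kind = kind, membership = membership,
         sparsity = s, threshold_used = r0, roi_labels = labs,
         n_edges = e_target),
    class = "brain_network"
  )
}

#' @export
print.brain_network <- function(x, ...) {
  cat(sprintf("<brain_network> %d nodes, %d edges (S = %g), %s/%s, r0 = %.4g\n",
              length(x$roi_labels), x$n_edges, x$sparsity, x$kind,
              x$membership, x$threshold_used))
  invisible(x)
}

#' Build networks over a sparsity grid
#'
#' One network per grid value, with nested edge sets (the edge set at a
#' lower sparsity is a subset of the edge set at any higher sparsity).
#'
#' @param m correlation matrix.
#' @param grid a [sparsity_grid()] or numeric vector of sparsity levels.
#' @inheritParams threshold_at_sparsity
#' @return Named list of `brain_network`s (names = sparsity values).
#' @export
build_over_grid <- function(m, grid,
                            membership = c("positive_only", "absolute_both"),
                            kind = c("binarized", "weighted")) {
  membership <- match.arg(membership)
  kind <- match.arg(kind)
  stopifnot(all(diff(grid) > 0), all(grid > 0), all(grid < 1))
  nets <- lapply(grid, function(s)
    threshold_at_sparsity(m, s, membership, kind))
  names(nets) <- formatC(as.numeric(grid), format = "g")
  nets
}

#' Truncate a sparsity grid by the group-wise maximum attainable sparsity
#'
#' When comparing two scan conditions the grid must stay below the minimum
#' attainable sparsity over every subject and scan entering the comparison.
#'
#' @param grid numeric sparsity levels.
#' @param matrices list of correlation matrices (all subjects/scans in the
#'   comparison).
#' @param membership edge membership rule.
#' @return The truncated grid (possibly shorter), with attribute `s_max`.
#' @export
truncate_grid <- function(grid, matrices,
                          membership = c("positive_only", "absolute_both")) {
  membership <- match.arg(membership)
  s_max <- min(vapply(matrices, max_sparsity, numeric(1),
                      membership = membership))
  out <- as.numeric(grid)[as.numeric(grid) <= s_max + 1e-12]
  attr(out, "s_max") <- s_max
  out
}
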