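# Graph fixtures built in code: adjacency constructors, random connected
# graphs, and exhaustive enumeration of small labeled connected graphs.

# Wrap an adjacency matrix as a brain_network for metric tests.
make_net <- function(adj, kind = if (all(adj %in% c(0, 1))) "binarized" else "weighted") {
  adj <- as.matrix(adj)
  n <- nrow(adj)
  labs <- rownames(adj)
  if (is.null(labs)) labs <- paste0("n", seq_len(n))
  dimnames(adj) <- list(labs, labs)
  structure(
    list(adjacency = adj, kind = kind, membership = "absolute_both",
         sparsity = sum(adj[upper.tri(adj)] != 0) / (n * (n - 1) / 2),
         threshold_used = NA_real_, roi_labels = labs,
         n_edges = sum(adj[upper.tri(adj)] != 0)),
    class = "brain_network")
}

complete_adj <- function(n) {
  a <- matrix(1, n, n)
  diag(a) <- 0
  a
}

star_adj <- function(n) {
  a <- matrix(0, n, n)
  a[1, 2:n] <- a[2:n, 1] <- 1
  a
}

path_adj <- function(n) {
  a <- matrix(0, n, n)
  for (i in seq_len(n - 1)) a[i, i + 1] <- a[i + 1, i] <- 1
  a
}

# Ring lattice: each node connected to its k nearest neighbors (k even).
ring_lattice_adj <- function(n, k) {
  a <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (d in seq_len(k / 2)) {
      j <- ((i - 1 + d) %% n) + 1
      a[i, j] <- a[j, i] <- 1
    }
  }
  a
}

# Two disjoint complete cliques of size k each.
two_cliques_adj <- function(k) {
  a <- matrix(0, 2 * k, 2 * k)
  a[1:k, 1:k] <- 1
  a[(k + 1):(2 * k), (k + 1):(2 * k)] <- 1
  diag(a) <- 0
  a
}

is_connected_adj <- function(a) {
  n <- nrow(a)
  seen <- rep(FALSE, n)
  queue <- 1L
  seen[1] <- TRUE
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    nb <- which(a[v, ] != 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

# Random connected binarized graph (rejection sampling on G(n, p)).
random_connected_adj <- function(n, p = 0.4) {
  repeat {
    u <- stats::runif(n * (n - 1) / 2) < p
    a <- matrix(0, n, n)
    a[upper.tri(a)] <- as.numeric(u)
    a <- a + t(a)
    if (sum(u) >= 1 && is_connected_adj(a)) return(a)
  }
}

# Random connected weighted graph with weights in (0, 1].
random_weighted_adj <- function(n, p = 0.5) {
  a <- random_connected_adj(n, p)
  w <- stats::runif(sum(upper.tri(a) & a != 0), 0.05, 1)
  a[upper.tri(a) & a != 0] <- w
  a[lower.tri(a)] <- 0
  a + t(a)
}

# All labeled connected graphs on n nodes (n small), as adjacency matrices.
all_connected_graphs <- function(n) {
  n_edges <- n * (n - 1) / 2
  out <- list()
  for (mask in seq_len(2^n_edges) - 1L) {
    bits <- as.numeric(bitwAnd(bitwShiftR(mask, seq_len(n_edges) - 1L), 1L))
    if (sum(bits) == 0) next
    a <- matrix(0, n, n)
    a[upper.tri(a)] <- bits
    a <- a + t(a)
    if (is_connected_adj(a)) out[[length(out) + 1L]] <- a
  }
  out
}

# Random symmetric correlation-like matrix (entries in (-1, 1), unit diag).
random_corr_like <- function(n) {
  u <- stats::runif(n * (n - 1) / 2, -0.95, 0.95)
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- u
  m <- m + t(m)
  diag(m) <- 1
  dimnames(m) <- list(paste0("roi", 1:n), paste0("roi", 1:n))
  m
}
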