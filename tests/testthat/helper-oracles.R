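# Independent brute-force oracles for graph metrics and ICC. These are
# deliberately naive (Floyd-Warshall loops, explicit triangle enumeration,
# geodesic-count dynamic programming, hand-rolled ANOVA sums of squares)
# and never share code with the package implementation.

# All-pairs shortest paths by Floyd-Warshall; weighted edges have length
# 1/weight.
bf_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && adj[i, j] != 0) d[i, j] <- 1 / adj[i, j] * (adj[i, j] != 0)
  }
  d[adj != 0] <- 1 / adj[adj != 0]
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

bf_eglob <- function(adj) {
  d <- bf_distances(adj)
  n <- nrow(adj)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && is.finite(d[i, j])) tot <- tot + 1 / d[i, j]
  }
  tot / (n * (n - 1))
}

bf_lp <- function(adj) {
  d <- bf_distances(adj)
  n <- nrow(adj)
  off <- d[row(d) != col(d)]
  if (all(is.finite(off))) mean(off) else {
    length(off) / sum(ifelse(is.finite(off), 1 / off, 0))
  }
}

bf_nodal_eff <- function(adj) {
  d <- bf_distances(adj)
  n <- nrow(adj)
  sapply(seq_len(n), function(i) {
    vals <- d[i, -i]
    mean(ifelse(is.finite(vals) & vals > 0, 1 / vals, 0))
  })
}

# Binarized clustering by explicit triangle counting over neighbor pairs.
bf_clustering_bin <- function(adj) {
  n <- nrow(adj)
  sapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] != 0)
    k <- length(nb)
    if (k < 2) return(0)
    t <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      if (adj[nb[a], nb[b]] != 0) t <- t + 1
    }
    2 * t / (k * (k - 1))
  })
}

# Onnela weighted clustering: geometric mean of triangle intensities over
# max-normalized weights, explicit triple loop.
bf_clustering_onnela <- function(adj) {
  n <- nrow(adj)
  w <- adj / max(adj)
  sapply(seq_len(n), function(i) {
    k <- sum(adj[i, ] != 0)
    if (k < 2) return(0)
    tot <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j != i && h != i && j != h) {
        tot <- tot + (w[i, j] * w[i, h] * w[j, h])^(1 / 3)
      }
    }
    tot / (k * (k - 1))
  })
}

bf_eloc <- function(adj) {
  n <- nrow(adj)
  vals <- sapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] != 0)
    if (length(nb) < 2) return(0)
    bf_eglob(adj[nb, nb, drop = FALSE])
  })
  mean(vals)
}

# Geodesic counts by dynamic programming on a Floyd-Warshall distance
# matrix: sigma[s, t] = number of shortest s-t paths.
bf_geodesic_counts <- function(adj, d, tol = 1e-10) {
  n <- nrow(adj)
  len <- ifelse(adj != 0, 1 / adj, Inf)
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  # process targets in order of increasing distance from each source
  for (s in seq_len(n)) {
    ord <- order(d[s, ])
    for (t in ord) {
      if (t == s || !is.finite(d[s, t])) next
      tot <- 0
      for (u in seq_len(n)) {
        if (u != t && is.finite(len[u, t]) &&
            abs(d[s, u] + len[u, t] - d[s, t]) < tol) {
          tot <- tot + sigma[s, u]
        }
      }
      sigma[s, t] <- tot
    }
  }
  sigma
}

# Fractional betweenness, endpoints excluded, from geodesic counts.
bf_betweenness <- function(adj, tol = 1e-10) {
  n <- nrow(adj)
  d <- bf_distances(adj)
  sigma <- bf_geodesic_counts(adj, d, tol)
  b <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s < t && s != v && t != v && is.finite(d[s, t]) &&
          abs(d[s, v] + d[v, t] - d[s, t]) < tol && sigma[s, t] > 0) {
        b[v] <- b[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
  }
  b
}

# Degree-degree Pearson correlation over edges, both orientations.
bf_assortativity <- function(adj) {
  n <- nrow(adj)
  k <- rowSums(adj)
  x <- c()
  y <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (adj[i, j] != 0) {
      x <- c(x, k[i], k[j])
      y <- c(y, k[j], k[i])
    }
  }
  if (length(x) < 2 || stats::sd(x) == 0) return(NA_real_)
  stats::cor(x, y)
}

# Newman modularity Q of a given partition, direct formula.
bf_modularity_q <- function(adj, memb) {
  two_m <- sum(adj)
  k <- rowSums(adj)
  q <- 0
  n <- nrow(adj)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (memb[i] == memb[j]) {
      q <- q + adj[i, j] - k[i] * k[j] / two_m
    }
  }
  as.numeric(q / two_m)
}

# One-way random-effects ICC by explicit enumeration of squared deviations.
bf_icc <- function(values) {
  n <- nrow(values)
  k <- ncol(values)
  grand <- mean(values)
  ss_b <- 0
  ss_w <- 0
  for (i in seq_len(n)) {
    mi <- mean(values[i, ])
    ss_b <- ss_b + k * (mi - grand)^2
    for (j in seq_len(k)) ss_w <- ss_w + (values[i, j] - mi)^2
  }
  ms_b <- ss_b / (n - 1)
  ms_w <- ss_w / (n * (k - 1))
  (ms_b - ms_w) / (ms_b + (k - 1) * ms_w)
}

# Compare a package metric against its oracle on one adjacency matrix.
expect_metrics_match_oracles <- function(adj, tol = 1e-9) {
  net <- make_net(adj)
  expect_equal(unname(net_degree(net)), unname(rowSums(adj)), tolerance = tol)
  expect_equal(unname(shortest_path_lengths(net)), unname(bf_distances(adj)),
               tolerance = tol)
  expect_equal(characteristic_path_length(net), bf_lp(adj), tolerance = tol)
  expect_equal(global_efficiency(net), bf_eglob(adj), tolerance = tol)
  cl <- clustering_coef(net)
  oracle_cl <- if (net$kind == "binarized") bf_clustering_bin(adj) else
    bf_clustering_onnela(adj)
  expect_equal(unname(cl$nodal), oracle_cl, tolerance = tol)
  expect_equal(cl$global, mean(oracle_cl), tolerance = tol)
  expect_equal(local_efficiency(net), bf_eloc(adj), tolerance = tol)
  expect_equal(unname(betweenness_centrality(net)), bf_betweenness(adj),
               tolerance = 1e-7)
  expect_equal(unname(nodal_efficiency(net)), bf_nodal_eff(adj),
               tolerance = tol)
  expect_equal(assortativity_coef(net), bf_assortativity(adj),
               tolerance = tol)
  invisible(NULL)
}
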