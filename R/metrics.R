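# Graph metrics of thresholded brain networks: 12 global and 6 nodal
# measures for binarized and weighted undirected networks, with
# degree-preserving surrogate normalization and modularity-based
# participation. Standard graph primitives (shortest paths, betweenness,
# rewiring, greedy community agglomeration) are delegated to igraph; the
# remaining measures are computed directly on the adjacency matrix.
#
# Conventions: weighted "degree" is strength (sum of weights); weighted path
# length uses edge length = 1/weight; weighted clustering is the Onnela
# geometric-mean triangle intensity with weights normalized by the network
# maximum. Undefined values (assortativity of a regular graph, hierarchy
# with too few eligible nodes, normalized participation with one module)
# are returned as NA and excluded pairwise downstream, never silently
# zeroed.

#' @keywords internal
as_igraph <- function(net) {
  stopifnot(inherits(net, "brain_network"))
  igraph::graph_from_adjacency_matrix(
    net$adjacency, mode = "undirected",
    weighted = if (net$kind == "weighted") TRUE else NULL, diag = FALSE)
}

#' @keywords internal
edge_lengths <- function(g) {
  if ("weight" %in% igraph::edge_attr_names(g)) {
    1 / igraph::E(g)$weight
  } else {
    NULL
  }
}

#' @keywords internal
binary_adjacency <- function(net) {
  (net$adjacency != 0) * 1
}

#' Node degree (binarized) or strength (weighted)
#'
#' The number of connections linked directly to a node; for weighted
#' networks, the sum of connection weights.
#'
#' @param net a `brain_network`.
#' @return named numeric vector, one value per node.
#' @export
net_degree <- function(net) {
  stopifnot(inherits(net, "brain_network"))
  rowSums(net$adjacency)
}

#' All-pairs shortest path lengths
#'
#' Hop counts for binarized networks; for weighted networks the minimum sum
#' of edge lengths with length = 1/weight (stronger connections are
#' shorter). Unreachable pairs are `Inf`.
#'
#' @param net a `brain_network`.
#' @return N x N matrix of distances, zero diagonal.
#' @export
shortest_path_lengths <- function(net) {
  g <- as_igraph(net)
  d <- igraph::distances(g, weights = edge_lengths(g))
  dimnames(d) <- list(net$roi_labels, net$roi_labels)
  d
}

#' @keywords internal
lp_eglob_from_distances <- function(d) {
  n <- nrow(d)
  if (n < 2) stop("path-length metrics need at least 2 nodes")
  off <- d[row(d) != col(d)]
  inv <- 1 / off
  inv[!is.finite(inv)] <- 0
  eglob <- mean(inv)
  if (all(is.finite(off))) {
    lp <- mean(off)
  } else {
    # disconnected: harmonic-mean-based path length stays finite
    lp <- length(off) / sum(inv)
  }
  list(lp = lp, eglob = eglob)
}

#' Characteristic path length
#'
#' Mean shortest path length over all node pairs. For disconnected networks
#' (unavoidable at low sparsity) the harmonic-mean-based form
#' `N(N-1) / sum(1/d)` is reported so the value stays finite.
#'
#' @param net a `brain_network`.
#' @return scalar Lp.
#' @export
characteristic_path_length <- function(net) {
  lp_eglob_from_distances(shortest_path_lengths(net))$lp
}

#' Global efficiency
#'
#' Mean inverse shortest path length over all ordered node pairs;
#' unreachable pairs contribute 0, so the value is defined for any network
#' and lies in \[0, 1\].
#'
#' @param net a `brain_network`.
#' @return scalar Eglob.
#' @export
global_efficiency <- function(net) {
  lp_eglob_from_distances(shortest_path_lengths(net))$eglob
}

#' Clustering coefficient (nodal and global)
#'
#' Binarized: the fraction of a node's neighbor pairs that are themselves
#' connected, `2 t_i / (k_i (k_i - 1))`; nodes with fewer than two neighbors
#' get 0. Weighted: the Onnela geometric-mean triangle intensity with
#' weights normalized by the network maximum, which keeps values in
#' \[0, 1\]. The global coefficient Cp is the mean over all nodes.
#'
#' @param net a `brain_network`.
#' @return list with `nodal` (named vector c_i) and `global` (Cp).
#' @export
clustering_coef <- function(net) {
  stopifnot(inherits(net, "brain_network"))
  a <- binary_adjacency(net)
  k <- rowSums(a)
  denom <- k * (k - 1)
  if (net$kind == "binarized") {
    tri <- diag(a %*% a %*% a)
  } else {
    wmax <- max(net$adjacency)
    w3 <- (net$adjacency / wmax)^(1 / 3)
    tri <- diag(w3 %*% w3 %*% w3)
  }
  ci <- ifelse(denom > 0, tri / denom, 0)
  names(ci) <- net$roi_labels
  list(nodal = ci, global = mean(ci))
}

#' Local efficiency
#'
#' The mean over nodes of the global efficiency of each node's
#' neighbor-induced subgraph; nodes with fewer than two neighbors
#' contribute 0.
#'
#' @param net a `brain_network`.
#' @return scalar Eloc.
#' @export
local_efficiency <- function(net) {
  stopifnot(inherits(net, "brain_network"))
  a <- binary_adjacency(net)
  n <- nrow(a)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] != 0)
    if (length(nb) < 2) next
    sub <- net
    sub$adjacency <- net$adjacency[nb, nb, drop = FALSE]
    sub$roi_labels <- net$roi_labels[nb]
    vals[i] <- global_efficiency(sub)
  }
  mean(vals)
}

#' Betweenness centrality
#'
#' The standard fractional betweenness: the sum over source-target pairs of
#' the fraction of shortest paths passing through a node, endpoints
#' excluded. Weighted geodesics use edge length = 1/weight.
#'
#' @param net a `brain_network`.
#' @return named numeric vector b_i.
#' @export
betweenness_centrality <- function(net) {
  g <- as_igraph(net)
  b <- igraph::betweenness(g, weights = edge_lengths(g), directed = FALSE)
  names(b) <- net$roi_labels
  b
}

#' Nodal efficiency
#'
#' How efficiently a node communicates with the rest of the network: the
#' mean inverse shortest path length from the node to every other node
#' (unreachable nodes contribute 0).
#'
#' @param net a `brain_network`.
#' @return named numeric vector e_i.
#' @export
nodal_efficiency <- function(net) {
  d <- shortest_path_lengths(net)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  e <- rowSums(inv) / (nrow(d) - 1)
  names(e) <- net$roi_labels
  e
}

#' Assortativity coefficient
#'
#' The Pearson correlation of the degrees (weighted: strengths) at the two
#' ends of every edge, with both orientations counted. Undefined when the
#' endpoint degrees have zero variance (e.g. regular graphs); returned as
#' NA in that case.
#'
#' @param net a `brain_network`.
#' @return scalar, or NA when degenerate.
#' @export
assortativity_coef <- function(net) {
  stopifnot(inherits(net, "brain_network"))
  idx <- which(upper.tri(net$adjacency) & net$adjacency != 0, arr.ind = TRUE)
  if (nrow(idx) < 2) return(NA_real_)
  k <- net_degree(net)
  x <- c(k[idx[, 1]], k[idx[, 2]])
  y <- c(k[idx[, 2]], k[idx[, 1]])
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Hierarchy coefficient
#'
#' The exponent b of the power-law scaling of clustering with degree,
#' `c_i ~ k_i^(-b)`, estimated as minus the least-squares slope of
#' `log(c_i)` on `log(k_i)` over nodes with degree >= 2 and positive
#' clustering. NA when fewer than 3 nodes are eligible or log-degree has
#' zero variance.
#'
#' @param net a `brain_network`.
#' @return scalar b, or NA when degenerate.
#' @export
hierarchy_coef <- function(net) {
  k <- net_degree(net)
  ci <- clustering_coef(net)$nodal
  elig <- which(k >= 2 & ci > 0)
  if (length(elig) < 3) return(NA_real_)
  lk <- log(k[elig])
  lc <- log(ci[elig])
  if (stats::sd(lk) == 0) return(NA_real_)
  fit <- stats::lm.fit(cbind(1, lk), lc)
  -unname(fit$coefficients[2])
}

#' Synchronizability
#'
#' The ratio of the second-smallest to the largest eigenvalue of the
#' (weighted) graph Laplacian L = D - A; large values indicate a network
#' whose nodes can lock into a common dynamic pattern. Disconnected
#' networks have a zero second eigenvalue and return 0.
#'
#' @param net a `brain_network`.
#' @return scalar in \[0, 1\].
#' @export
synchronization_coef <- function(net) {
  a <- net$adjacency
  lap <- diag(rowSums(a)) - a
  ev <- sort(eigen(lap, symmetric = TRUE, only.values = TRUE)$values)
  lmax <- ev[length(ev)]
  if (lmax <= 1e-12) return(0)
  l2 <- ev[2]
  if (l2 < 1e-10) return(0)
  l2 / lmax
}

#' Modularity partition and Q
#'
#' Community structure by deterministic greedy modularity agglomeration
#' (fast-greedy), maximizing Newman's Q; the weighted generalization uses
#' connection strengths. No stochastic restarts, so repeated runs on the
#' same network give identical partitions — reliability comparisons must
#' not inject algorithmic randomness.
#'
#' @param net a `brain_network` with at least one edge.
#' @return list with `membership` (named module id per node), `n_modules`,
#'   and `Q`.
#' @export
modularity_partition <- function(net) {
  stopifnot(inherits(net, "brain_network"))
  if (net$n_edges < 1) stop("modularity is undefined for an edgeless network")
  g <- as_igraph(net)
  w <- if (net$kind == "weighted") igraph::E(g)$weight else NULL
  comm <- igraph::cluster_fast_greedy(g, weights = w)
  memb <- igraph::membership(comm)
  q <- igraph::modularity(g, memb, weights = w)
  # the greedy cut can miss the trivial one-community state, whose Q is 0
  # by definition; any partition with Q <= 0 is then dominated by it
  if (q <= 0) {
    memb <- rep(1L, igraph::vcount(g))
    q <- igraph::modularity(g, memb, weights = w)
  }
  memb <- as.integer(memb)
  names(memb) <- net$roi_labels
  list(membership = memb, n_modules = length(unique(memb)), Q = q)
}

#' Participation coefficient
#'
#' How evenly a node's connections are spread over the modules of a
#' partition: `PC_i = 1 - sum_m (k_im / k_i)^2` (weighted: strengths);
#' isolated nodes get 0. The normalized version divides by `1 - 1/M`
#' (M = number of modules), so a node spread perfectly evenly over all M
#' modules attains 1; with a single module it is undefined (NA).
#'
#' @param net a `brain_network`.
#' @param partition a partition as returned by [modularity_partition()], or
#'   a plain integer vector of module labels per node.
#' @return list with `pc` and `pc_norm`, named numeric vectors.
#' @export
participation_coef <- function(net, partition) {
  stopifnot(inherits(net, "brain_network"))
  memb <- if (is.list(partition)) partition$membership else partition
  if (length(memb) != length(net$roi_labels) || anyNA(memb)) {
    stop("partition must label every node")
  }
  mods <- sort(unique(memb))
  m <- length(mods)
  k <- net_degree(net)
  # k_im: strength of node i into module m
  kim <- vapply(mods, function(mm)
    rowSums(net$adjacency[, memb == mm, drop = FALSE]), numeric(nrow(net$adjacency)))
  frac2 <- (kim / ifelse(k > 0, k, 1))^2
  pc <- ifelse(k > 0, 1 - rowSums(frac2), 0)
  pc_norm <- if (m > 1) pc / (1 - 1 / m) else rep(NA_real_, length(pc))
  names(pc) <- names(pc_norm) <- net$roi_labels
  list(pc = pc, pc_norm = pc_norm)
}

#' Degree-preserving random surrogate of a network
#'
#' Rewires the topology by double-edge swaps, preserving every node's
#' binary degree exactly, with no self-loops or multi-edges; for weighted
#' networks the original weight multiset is reassigned to the rewired edges
#' by a random permutation. On networks with no feasible swap (e.g.
#' complete graphs) the input topology is returned unchanged. Deterministic
#' given `seed`.
#'
#' @param net a `brain_network` with >= 2 edges.
#' @param n_iterations number of attempted swaps; default 10x edge count.
#' @param seed integer seed.
#' @return a rewired `brain_network`.
#' @export
random_rewire <- function(net, n_iterations = NULL, seed = 1L) {
  stopifnot(inherits(net, "brain_network"))
  if (net$n_edges < 2) stop("rewiring needs at least 2 edges")
  n_iterations <- n_iterations %||% (10 * net$n_edges)
  set.seed(seed)
  a_bin <- binary_adjacency(net)
  g <- igraph::graph_from_adjacency_matrix(a_bin, mode = "undirected",
                                           diag = FALSE)
  g2 <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                 niter = n_iterations))
  adj <- as.matrix(igraph::as_adjacency_matrix(g2, sparse = FALSE))
  if (net$kind == "weighted") {
    idx <- which(upper.tri(adj) & adj != 0, arr.ind = TRUE)
    w_orig <- net$adjacency[which(upper.tri(net$adjacency) &
                                    net$adjacency != 0)]
    w_new <- sample(w_orig)
    adj[adj != 0] <- 0
    adj[idx] <- w_new
    adj <- adj + t(adj)
  }
  dimnames(adj) <- list(net$roi_labels, net$roi_labels)
  out <- net
  out$adjacency <- adj
  out
}

#' Small-world parameters
#'
#' Normalized clustering gamma = Cp / <Cp_rand>, normalized path length
#' lambda = Lp / <Lp_rand>, and small-worldness sigma = gamma / lambda,
#' where the surrogate ensemble consists of `n_random` degree-preserving
#' rewired networks. A small-world network has gamma >> 1 and lambda ~ 1.
#'
#' @param net a `brain_network`.
#' @param n_random surrogate ensemble size.
#' @param n_iterations swap attempts per surrogate (default 10x edges).
#' @param seed integer seed; surrogate i uses a seed derived from it.
#' @return list with `gamma`, `lambda`, `sigma`, `cp`, `lp`, and the
#'   surrogate means `cp_rand`, `lp_rand`.
#' @export
small_world <- function(net, n_random = 100, n_iterations = NULL, seed = 1L) {
  cp <- clustering_coef(net)$global
  lp <- characteristic_path_length(net)
  cps <- numeric(n_random)
  lps <- numeric(n_random)
  for (i in seq_len(n_random)) {
    surr <- random_rewire(net, n_iterations, seed = derive_seed(seed, 90L, i))
    cps[i] <- clustering_coef(surr)$global
    lps[i] <- characteristic_path_length(surr)
  }
  cp_rand <- mean(cps)
  lp_rand <- mean(lps)
  if (cp_rand == 0) stop("degenerate surrogate ensemble: mean clustering 0")
  gamma <- cp / cp_rand
  lambda <- lp / lp_rand
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda,
       cp = cp, lp = lp, cp_rand = cp_rand, lp_rand = lp_rand)
}

#' Metric name constants
#'
#' The 12 global and 6 nodal metric names understood by
#' [global_metrics()], [nodal_metrics()] and [metrics_over_grid()]; pass
#' subsets of these to restrict computation.
#'
#' @format Character vectors.
#' @export
GLOBAL_METRIC_NAMES <- c("Cp", "Lp", "gamma", "lambda", "sigma", "Eloc",
                         "Eglob", "assortativity", "hierarchy",
                         "synchronization", "modularity_Q", "n_modules")

#' @rdname GLOBAL_METRIC_NAMES
#' @export
NODAL_METRIC_NAMES <- c("degree", "efficiency", "betweenness", "clustering",
                        "participation", "participation_norm")

#' All 12 global metrics of a network
#'
#' Computes clustering Cp, characteristic path length Lp, normalized
#' gamma/lambda/sigma against degree-preserving surrogates, local and
#' global efficiency, assortativity, hierarchy, synchronizability,
#' modularity Q, and the number of modules.
#'
#' @param net a `brain_network`.
#' @param n_random surrogate ensemble size for gamma/lambda/sigma.
#' @param n_iterations swap attempts per surrogate.
#' @param seed integer seed for the surrogate ensemble.
#' @param metrics subset of metric names to compute (default all 12).
#' @return named numeric vector (NA for undefined values).
#' @export
global_metrics <- function(net, n_random = 100, n_iterations = NULL,
                           seed = 1L, metrics = GLOBAL_METRIC_NAMES) {
  metrics <- match.arg(metrics, GLOBAL_METRIC_NAMES, several.ok = TRUE)
  out <- stats::setNames(rep(NA_real_, length(metrics)), metrics)
  need <- function(x) any(x %in% metrics)

  if (need(c("Lp", "Eglob"))) {
    le <- lp_eglob_from_distances(shortest_path_lengths(net))
    if ("Lp" %in% metrics) out["Lp"] <- le$lp
    if ("Eglob" %in% metrics) out["Eglob"] <- le$eglob
  }
  if (need("Cp")) out["Cp"] <- clustering_coef(net)$global
  if (need("Eloc")) out["Eloc"] <- local_efficiency(net)
  if (need(c("gamma", "lambda", "sigma"))) {
    # a degenerate surrogate ensemble (all-zero clustering) flags the
    # normalized quantities rather than aborting the pipeline
    sw <- tryCatch(small_world(net, n_random, n_iterations, seed),
                   error = function(e) list(gamma = NA_real_,
                                            lambda = NA_real_,
                                            sigma = NA_real_))
    for (nm in c("gamma", "lambda", "sigma")) {
      if (nm %in% metrics) out[nm] <- sw[[nm]]
    }
  }
  if (need("assortativity")) out["assortativity"] <- assortativity_coef(net)
  if (need("hierarchy")) out["hierarchy"] <- hierarchy_coef(net)
  if (need("synchronization")) {
    out["synchronization"] <- synchronization_coef(net)
  }
  if (need(c("modularity_Q", "n_modules"))) {
    part <- modularity_partition(net)
    if ("modularity_Q" %in% metrics) out["modularity_Q"] <- part$Q
    if ("n_modules" %in% metrics) out["n_modules"] <- part$n_modules
  }
  out
}

#' All 6 nodal metrics of a network
#'
#' Degree (strength), nodal efficiency, betweenness, clustering,
#' participation, and normalized participation (the latter two require a
#' module partition; by default one is obtained from
#' [modularity_partition()]).
#'
#' @param net a `brain_network`.
#' @param partition optional precomputed partition.
#' @param metrics subset of nodal metric names (default all 6).
#' @return data frame with columns `node` and one column per metric.
#' @export
nodal_metrics <- function(net, partition = NULL,
                          metrics = NODAL_METRIC_NAMES) {
  metrics <- match.arg(metrics, NODAL_METRIC_NAMES, several.ok = TRUE)
  out <- data.frame(node = net$roi_labels, stringsAsFactors = FALSE)
  if ("degree" %in% metrics) out$degree <- unname(net_degree(net))
  if ("efficiency" %in% metrics) {
    out$efficiency <- unname(nodal_efficiency(net))
  }
  if ("betweenness" %in% metrics) {
    out$betweenness <- unname(betweenness_centrality(net))
  }
  if ("clustering" %in% metrics) {
    out$clustering <- unname(clustering_coef(net)$nodal)
  }
  if (any(c("participation", "participation_norm") %in% metrics)) {
    if (is.null(partition)) partition <- modularity_partition(net)
    pc <- participation_coef(net, partition)
    if ("participation" %in% metrics) out$participation <- unname(pc$pc)
    if ("participation_norm" %in% metrics) {
      out$participation_norm <- unname(pc$pc_norm)
    }
  }
  out
}

#' Metric curves over a sparsity grid for one subject-scan
#'
#' Thresholds a correlation matrix at every grid value and computes the
#' requested global and nodal metrics, returning a long-format table ready
#' for AUC summarization and reliability analysis.
#'
#' @param m correlation matrix.
#' @param grid sparsity levels.
#' @param membership,kind network construction factors.
#' @param global_names,nodal_names metric subsets (NULL = skip that family).
#' @param n_random,n_iterations,seed surrogate ensemble controls.
#' @param subject_id,scan_id identifiers copied into the table.
#' @return data frame: subject, scan, membership, kind, sparsity, metric,
#'   node (NA for global metrics), value.
#' @export
metrics_over_grid <- function(m, grid,
                              membership = c("positive_only", "absolute_both"),
                              kind = c("binarized", "weighted"),
                              global_names = GLOBAL_METRIC_NAMES,
                              nodal_names = NODAL_METRIC_NAMES,
                              n_random = 100, n_iterations = NULL, seed = 1L,
                              subject_id = attr(m, "subject_id") %||% "sub",
                              scan_id = attr(m, "scan_id") %||% "scan") {
  membership <- match.arg(membership)
  kind <- match.arg(kind)
  rows <- vector("list", length(grid))
  for (gi in seq_along(grid)) {
    s <- as.numeric(grid[gi])
    net <- threshold_at_sparsity(m, s, membership, kind)
    part <- NULL
    chunks <- list()
    if (!is.null(global_names) && length(global_names)) {
      gm <- global_metrics(net, n_random, n_iterations,
                           seed = derive_seed(seed, 7L, gi),
                           metrics = global_names)
      chunks$global <- data.frame(metric = names(gm), node = NA_character_,
                                  value = unname(gm),
                                  stringsAsFactors = FALSE)
    }
    if (!is.null(nodal_names) && length(nodal_names)) {
      nm <- nodal_metrics(net, partition = part, metrics = nodal_names)
      long <- do.call(rbind, lapply(setdiff(names(nm), "node"), function(col)
        data.frame(metric = col, node = nm$node, value = nm[[col]],
                   stringsAsFactors = FALSE)))
      chunks$nodal <- long
    }
    tab <- do.call(rbind, chunks)
    tab$sparsity <- s
    rows[[gi]] <- tab
  }
  out <- do.call(rbind, rows)
  out$subject <- subject_id
  out$scan <- scan_id
  out$membership <- membership
  out$kind <- kind
  rownames(out) <- NULL
  out[, c("subject", "scan", "membership", "kind", "sparsity", "metric",
          "node", "value")]
}
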