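# Graph metrics: analytic cases, brute-force oracle agreement, invariance
# properties, surrogate normalization, modularity and participation.

test_that("complete graphs attain the extreme values of every metric", {
  for (n in c(5, 8)) {
    net <- make_net(complete_adj(n))
    expect_equal(unname(net_degree(net)), rep(n - 1, n))
    expect_equal(clustering_coef(net)$global, 1)
    expect_equal(characteristic_path_length(net), 1)
    expect_equal(global_efficiency(net), 1)
    expect_equal(local_efficiency(net), 1)
    expect_equal(synchronization_coef(net), 1)  # eigenvalues {0, n, ..., n}
  }
})

test_that("star graphs: center betweenness, zero clustering, assortativity -1", {
  n <- 6
  net <- make_net(star_adj(n))
  k <- net_degree(net)
  expect_equal(unname(k), c(n - 1, rep(1, n - 1)))
  b <- betweenness_centrality(net)
  expect_equal(unname(b[1]), (n - 1) * (n - 2) / 2)
  expect_equal(unname(b[-1]), rep(0, n - 1))
  expect_equal(clustering_coef(net)$global, 0)
  expect_equal(local_efficiency(net), 0)
  expect_equal(assortativity_coef(net), -1)
  e <- nodal_efficiency(net)
  expect_equal(unname(e[1]), 1)
  expect_equal(unname(e[2]), (1 + (n - 2) / 2) / (n - 1))  # leaf: 0.6 at n=6
})

test_that("path graphs match pair-enumeration distances and P4 eigen oracle", {
  net <- make_net(path_adj(3))
  d <- shortest_path_lengths(net)
  expect_equal(d[1, 3], 2)
  expect_equal(unname(betweenness_centrality(net)), c(0, 1, 0))
  p4 <- make_net(path_adj(4))
  # Eglob by explicit pair sum: pairs at distance 1 (x3), 2 (x2), 3 (x1)
  expect_equal(global_efficiency(p4),
               (3 * 1 + 2 * (1 / 2) + 1 * (1 / 3)) * 2 / (4 * 3))
  # Laplacian eigenvalues of P4: 2 - 2*cos(k*pi/4)... use explicit eigen
  lap <- diag(c(1, 2, 2, 1)) - path_adj(4)
  ev <- sort(eigen(lap, symmetric = TRUE, only.values = TRUE)$values)
  expect_equal(synchronization_coef(p4), ev[2] / ev[4], tolerance = 1e-12)
})

test_that("weighted edges use reciprocal lengths and a pendant triangle clusters at 1/3", {
  a <- matrix(0, 2, 2)
  a[1, 2] <- a[2, 1] <- 0.5
  expect_equal(shortest_path_lengths(make_net(a))[1, 2], 2)
  # triangle plus one pendant attached to node 1
  adj <- matrix(0, 4, 4)
  adj[1, 2] <- adj[2, 1] <- 1
  adj[1, 3] <- adj[3, 1] <- 1
  adj[2, 3] <- adj[3, 2] <- 1
  adj[1, 4] <- adj[4, 1] <- 1
  ci <- clustering_coef(make_net(adj))$nodal
  expect_equal(unname(ci[1]), 2 * 1 / (3 * 2))
})

test_that("edgeless and disconnected degenerate cases are handled", {
  iso <- matrix(0, 4, 4)
  iso[1, 2] <- iso[2, 1] <- 1  # two isolated nodes remain
  net <- make_net(iso)
  expect_equal(synchronization_coef(net), 0)
  e <- nodal_efficiency(net)
  expect_equal(unname(e[3]), 0)
  expect_equal(global_efficiency(make_net(matrix(0, 3, 3))), 0)
  expect_error(modularity_partition(make_net(matrix(0, 3, 3))), "edgeless")
  # two disjoint edges: all endpoint degrees equal -> assortativity NA
  dis <- matrix(0, 4, 4)
  dis[1, 2] <- dis[2, 1] <- dis[3, 4] <- dis[4, 3] <- 1
  expect_true(is.na(assortativity_coef(make_net(dis))))
})

test_that("hierarchy recovers exact and noisy power-law exponents", {
  # construct a network-free check through the regression itself:
  # feed a crafted net whose clustering/degree follow c = k^(-2)
  # by monkey-level construction: use a known graph and verify against an
  # explicit least-squares fit instead.
  set.seed(20)
  adj <- random_connected_adj(12, 0.5)
  net <- make_net(adj)
  k <- net_degree(net)
  ci <- clustering_coef(net)$nodal
  elig <- k >= 2 & ci > 0
  fit <- stats::lm(log(ci[elig]) ~ log(k[elig]))
  expect_equal(hierarchy_coef(net), -unname(coef(fit)[2]), tolerance = 1e-10)
  # degenerate: star has no node with c_i > 0
  expect_true(is.na(hierarchy_coef(make_net(star_adj(6)))))
})

test_that("modularity finds planted structure deterministically", {
  net <- make_net(two_cliques_adj(5))
  part <- modularity_partition(net)
  expect_equal(part$n_modules, 2)
  expect_equal(part$Q, 0.5, tolerance = 1e-12)
  expect_equal(part$Q, bf_modularity_q(net$adjacency, part$membership),
               tolerance = 1e-12)
  # identical partition on repeated runs (no algorithmic randomness)
  expect_identical(part, modularity_partition(net))
  # complete graph: a single community
  expect_equal(modularity_partition(make_net(complete_adj(6)))$n_modules, 1)
  # planted 3-block graph
  set.seed(21)
  n_block <- 10
  adj <- matrix(0, 3 * n_block, 3 * n_block)
  for (i in 1:(3 * n_block - 1)) for (j in (i + 1):(3 * n_block)) {
    p <- if (((i - 1) %/% n_block) == ((j - 1) %/% n_block)) 0.9 else 0.05
    if (runif(1) < p) adj[i, j] <- adj[j, i] <- 1
  }
  part3 <- modularity_partition(make_net(adj))
  expect_equal(part3$n_modules, 3)
  planted <- rep(1:3, each = n_block)
  # label-agreement: every recovered module maps to one planted block
  tab <- table(part3$membership, planted)
  expect_true(all(apply(tab > 0, 1, sum) == 1))
})

test_that("participation follows the module-spread formula", {
  # two cliques joined by nothing: all edges within own module -> PC = 0
  net <- make_net(two_cliques_adj(4))
  part <- modularity_partition(net)
  pc <- participation_coef(net, part)
  expect_equal(unname(pc$pc), rep(0, 8))
  # node with edges split evenly across 2 modules: PC = 0.5, PCnorm = 1
  adj <- matrix(0, 5, 5)
  adj[1, 2] <- adj[2, 1] <- 1   # module 1
  adj[1, 3] <- adj[3, 1] <- 1   # module 2
  adj[2, 4] <- adj[4, 2] <- 1
  adj[3, 5] <- adj[5, 3] <- 1
  memb <- c(1, 1, 2, 1, 2)
  pc2 <- participation_coef(make_net(adj), memb)
  expect_equal(unname(pc2$pc[1]), 0.5)
  expect_equal(unname(pc2$pc_norm[1]), 1)
  # single module: PCnorm undefined
  pc3 <- participation_coef(net, rep(1L, 8))
  expect_true(all(is.na(pc3$pc_norm)))
  expect_error(participation_coef(net, c(1, 2)), "label every node")
})

test_that("rewiring preserves degrees, leaves K_n unchanged, keeps density", {
  kn <- make_net(complete_adj(6))
  expect_equal(random_rewire(kn, seed = 1)$adjacency, kn$adjacency)
  set.seed(22)
  adj <- random_connected_adj(12, 0.4)
  net <- make_net(adj)
  for (s in 1:5) {
    rw <- random_rewire(net, seed = s)
    expect_equal(unname(sort(rowSums(rw$adjacency))), sort(rowSums(adj)))
    expect_equal(diag(rw$adjacency), rep(0, 12), ignore_attr = TRUE)
  }
  # weighted: weight multiset preserved
  set.seed(23)
  wadj <- random_weighted_adj(10, 0.5)
  wnet <- make_net(wadj)
  rww <- random_rewire(wnet, seed = 7)
  expect_equal(sort(rww$adjacency[upper.tri(rww$adjacency) &
                                    rww$adjacency != 0]),
               sort(wadj[upper.tri(wadj) & wadj != 0]))
  expect_equal(unname(sort(rowSums(rww$adjacency != 0))),
               sort(rowSums(wadj != 0)))
  # deterministic given seed
  expect_equal(random_rewire(net, seed = 3)$adjacency,
               random_rewire(net, seed = 3)$adjacency)
})

test_that("surrogate ensemble clustering matches the density expectation", {
  # Erdos-Renyi graph: degree-preserving surrogates keep expected
  # clustering near edge density
  set.seed(24)
  adj <- random_connected_adj(20, 0.35)
  net <- make_net(adj)
  density <- net$n_edges / (20 * 19 / 2)
  cps <- vapply(1:100, function(i)
    clustering_coef(random_rewire(net, seed = i))$global, numeric(1))
  se <- stats::sd(cps) / sqrt(length(cps))
  expect_lt(abs(mean(cps) - density), max(4 * se, 0.04))
})

test_that("small-world normalization: ER near 1, ring lattice far above 1", {
  set.seed(25)
  adj <- random_connected_adj(24, 0.3)
  sw <- small_world(make_net(adj), n_random = 30, seed = 1)
  expect_equal(sw$sigma, sw$gamma / sw$lambda, tolerance = 1e-12)
  expect_lt(abs(sw$gamma - 1), 0.5)
  expect_lt(abs(sw$lambda - 1), 0.2)
  lattice <- make_net(ring_lattice_adj(100, 6))
  # lattice Cp = 0.6 vastly exceeds the surrogate mean
  expect_equal(clustering_coef(lattice)$global, 0.6, tolerance = 1e-12)
  swl <- small_world(lattice, n_random = 10, seed = 2)
  expect_gt(swl$gamma, 3)
})

test_that("metrics agree with brute-force oracles on random graphs", {
  set.seed(26)
  for (i in 1:10) {
    expect_metrics_match_oracles(random_connected_adj(8, 0.45))
    expect_metrics_match_oracles(random_weighted_adj(8, 0.5))
  }
})

test_that("metrics are invariant under node relabeling", {
  set.seed(27)
  adj <- random_weighted_adj(9, 0.5)
  net <- make_net(adj)
  perm <- sample(9)
  netp <- make_net(adj[perm, perm])
  expect_equal(unname(net_degree(netp)), unname(net_degree(net))[perm])
  expect_equal(unname(betweenness_centrality(netp)),
               unname(betweenness_centrality(net))[perm], tolerance = 1e-9)
  expect_equal(unname(nodal_efficiency(netp)),
               unname(nodal_efficiency(net))[perm], tolerance = 1e-12)
  expect_equal(clustering_coef(netp)$global, clustering_coef(net)$global,
               tolerance = 1e-12)
  expect_equal(characteristic_path_length(netp),
               characteristic_path_length(net), tolerance = 1e-12)
  expect_equal(assortativity_coef(netp), assortativity_coef(net),
               tolerance = 1e-12)
  expect_equal(synchronization_coef(netp), synchronization_coef(net),
               tolerance = 1e-9)
})

test_that("weight scaling behaves as documented per metric", {
  set.seed(28)
  adj <- random_weighted_adj(8, 0.6)
  net <- make_net(adj)
  net2 <- make_net(3 * adj)
  # efficiency-type metrics scale linearly with weights
  expect_equal(global_efficiency(net2), 3 * global_efficiency(net),
               tolerance = 1e-12)
  expect_equal(unname(nodal_efficiency(net2)),
               3 * unname(nodal_efficiency(net)), tolerance = 1e-12)
  # max-normalized Onnela clustering is scale-invariant
  expect_equal(clustering_coef(net2)$nodal, clustering_coef(net)$nodal,
               tolerance = 1e-12)
  # binarized metrics are unchanged by scaling before binarization
  bin <- make_net((adj != 0) * 1)
  bin2 <- make_net(((3 * adj) != 0) * 1)
  expect_equal(bin$adjacency, bin2$adjacency)
})

test_that("metric curves over a grid produce a complete long table", {
  set.seed(29)
  m <- random_corr_like(12)
  tab <- metrics_over_grid(m, c(0.2, 0.3, 0.4), "absolute_both", "binarized",
                           n_random = 5, subject_id = "s1", scan_id = "t1")
  expect_setequal(unique(tab$metric[is.na(tab$node)]),
                  c("Cp", "Lp", "gamma", "lambda", "sigma", "Eloc", "Eglob",
                    "assortativity", "hierarchy", "synchronization",
                    "modularity_Q", "n_modules"))
  expect_setequal(unique(tab$metric[!is.na(tab$node)]),
                  c("degree", "efficiency", "betweenness", "clustering",
                    "participation", "participation_norm"))
  # 12 global + 6 nodal x 12 nodes per grid point
  expect_equal(nrow(tab), 3 * (12 + 6 * 12))
  # sigma = gamma / lambda wherever both are defined
  for (s in c(0.2, 0.3, 0.4)) {
    g <- tab$value[tab$metric == "gamma" & tab$sparsity == s]
    l <- tab$value[tab$metric == "lambda" & tab$sparsity == s]
    sg <- tab$value[tab$metric == "sigma" & tab$sparsity == s]
    if (!is.na(g) && !is.na(l)) expect_equal(sg, g / l, tolerance = 1e-12)
  }
  # subsetting computes only what is asked
  tab2 <- metrics_over_grid(m, c(0.2, 0.3), "absolute_both", "binarized",
                            global_names = NULL, nodal_names = "degree")
  expect_setequal(unique(tab2$metric), "degree")
})
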