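test_that("degree counts supra-threshold edges", {
  # star K1,3
  w <- matrix(0, 4, 4)
  w[1, 2:4] <- w[2:4, 1] <- 0.5
  net <- weighted_network(w, modality = "DTI")
  expect_equal(node_degree(net)$values, c(3, 1, 1, 1))

  set.seed(5)
  dense <- random_network(7, lo = 0.1, hi = 0.9)
  expect_equal(node_degree(dense)$values, rep(6, 7))

  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.4; w[1, 3] <- w[3, 1] <- 0.6
  net <- weighted_network(w, modality = "DTI")
  expect_equal(node_degree(net, 0.5)$values[1], 1)
  expect_error(node_degree(net, 1), "edge_threshold")
})

test_that("strength is the row sum and equals degree on unit weights", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.2; w[1, 3] <- w[3, 1] <- 0.3
  net <- weighted_network(w, modality = "DTI")
  expect_equal(node_strength(net)$values, c(0.5, 0.2, 0.3))

  # uniform complete graph: (N-1) w each; isolated node scores 0
  u <- weighted_network(sym_mat(rep(0.4, 10), 5), modality = "GM")
  expect_equal(node_strength(u)$values, rep(4 * 0.4, 5))

  set.seed(19)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    mask <- runif(n * (n - 1) / 2) < 0.5
    net <- weighted_network(sym_mat(as.numeric(mask), n), modality = "DTI")
    expect_equal(node_strength(net)$values, node_degree(net)$values)
  }
})

test_that("local efficiency matches hand computations", {
  tri <- weighted_network(sym_mat(rep(1, 3), 3), modality = "DTI")
  expect_equal(local_efficiency(tri)$values, rep(1, 3))

  # path a-b-c: middle node's neighbors are unconnected inside Gamma(b)
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 1; w[2, 3] <- w[3, 2] <- 1
  path <- weighted_network(w, modality = "DTI")
  le <- local_efficiency(path)$values
  expect_equal(le[2], 0) # unreachable neighbor pair contributes 0
  expect_equal(le[1], 0) # single neighbor
  # isolated node
  iso <- weighted_network(matrix(0, 4, 4), modality = "DTI")
  expect_equal(local_efficiency(iso)$values, rep(0, 4))
})

test_that("betweenness and closeness match hand-worked path graphs", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 1; w[2, 3] <- w[3, 2] <- 1
  path <- weighted_network(w, modality = "DTI")
  expect_equal(betweenness_centrality(path)$values, c(0, 1, 0))
  expect_equal(closeness_centrality(path)$values[1], 2 / 3)

  # 4-cycle: the pair of opposite endpoints splits credit over two middles
  w <- matrix(0, 4, 4)
  for (e in list(c(1, 2), c(2, 3), c(3, 4), c(4, 1)))
    w[e[1], e[2]] <- w[e[2], e[1]] <- 1
  cyc <- weighted_network(w, modality = "DTI")
  expect_equal(betweenness_centrality(cyc)$values,
               rep(0.5 / 3, 4)) # 0.5 credit, normalized by (3)(2)/2

  comp <- weighted_network(sym_mat(rep(1, 10), 5), modality = "GM")
  expect_equal(betweenness_centrality(comp)$values, rep(0, 5))
  expect_equal(closeness_centrality(comp)$values, rep(1, 5))

  expect_equal(closeness_centrality(iso <- weighted_network(
    matrix(0, 3, 3), modality = "DTI"))$values, rep(0, 3))
})

test_that("betweenness and closeness agree with exhaustive enumeration", {
  set.seed(23)
  for (i in 1:12) {
    n <- sample(4:6, 1)
    ne <- n * (n - 1) / 2
    vals <- ifelse(runif(ne) < 0.7, runif(ne, 0.2, 1), 0)
    net <- weighted_network(sym_mat(vals, n), modality = "DTI")
    expect_equal(betweenness_centrality(net)$values,
                 oracle_betweenness(net$weights), tolerance = 1e-9)
    expect_equal(closeness_centrality(net)$values,
                 oracle_closeness(net$weights), tolerance = 1e-9)
  }
})

test_that("metrics are permutation-equivariant and edge-monotone", {
  set.seed(29)
  net <- random_network(7)
  perm <- sample(7)
  pnet <- weighted_network(net$weights[perm, perm], modality = "DTI")
  for (m in c("degree", "strength", "local_efficiency", "betweenness",
              "closeness")) {
    v <- node_metric(net, m)$values
    pv <- node_metric(pnet, m)$values
    expect_equal(pv, v[perm], tolerance = 1e-12, info = m)
    expect_true(all(is.finite(v) & v >= 0), info = m)
  }

  # adding an edge never decreases degree or strength
  w <- net$weights
  zero <- which(upper.tri(w) & w == 0, arr.ind = TRUE)
  w2 <- w; w2[2, 5] <- w2[5, 2] <- min(1, w2[2, 5] + 0.3)
  net2 <- weighted_network(pmin(w2, 1), modality = "DTI")
  expect_true(all(node_strength(net2)$values >= node_strength(net)$values))
  expect_true(all(node_degree(net2)$values >= node_degree(net)$values))
})

test_that("multilayer metrics follow the supra convention", {
  n <- 3
  # two identical layers, replica coupling 1: strength of each replica is
  # single-layer strength + coupling + DTI row sum
  layer <- sym_mat(c(0.2, 0.4, 0.6), n)
  dti_w <- sym_mat(rep(0.3, 3), n)
  s <- subject_record("s1", "HV", 40, "F", list(
    GM = weighted_network(layer, modality = "GM"),
    DTI = weighted_network(dti_w, modality = "DTI"),
    FMRI = weighted_network(layer, modality = "FMRI")))
  ml <- build_supra_adjacency(s, replica_coupling = 1)
  st <- multilayer_metric(ml, "strength", aggregate = "none")$values
  expect_equal(st[1:n], rowSums(layer) + 1 + rowSums(dti_w))
  expect_equal(st[(n + 1):(2 * n)], st[1:n])

  # DTI = 0, mean aggregation: average of the two layers' own metrics
  layer2 <- sym_mat(c(0.5, 0.1, 0.9), n)
  s2 <- subject_record("s2", "HV", 40, "F", list(
    GM = weighted_network(layer, modality = "GM"),
    DTI = weighted_network(matrix(0, n, n), modality = "DTI"),
    FMRI = weighted_network(layer2, modality = "FMRI")))
  ml2 <- build_supra_adjacency(s2)
  dg <- multilayer_metric(ml2, "degree", aggregate = "mean")$values
  g1 <- node_degree(s2$networks$GM)$values
  g2 <- node_degree(s2$networks$FMRI)$values
  expect_equal(dg, (g1 + g2) / 2)
  expect_equal(length(multilayer_metric(ml2, "closeness")$values), n)
  expect_error(multilayer_metric(ml2, "pagerank"), "unknown")
})
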