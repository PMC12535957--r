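# Shared fixtures, built in code.

# symmetric zero-diagonal matrix with given upper-triangle values
sym_mat <- function(vals, n) {
  w <- matrix(0, n, n)
  w[upper.tri(w)] <- vals
  w + t(w)
}

# random dense network with uniform weights
random_network <- function(n, modality = "DTI", space = "raw",
                           lo = 0.05, hi = 0.95) {
  ne <- n * (n - 1) / 2
  weighted_network(sym_mat(runif(ne, lo, hi), n), modality = modality,
                   space = space)
}

# small cohort for fast end-to-end tests
tiny_cohort <- function(n_hv = 6, n_pwms = 6, N = 10, seed = 7, delta = 0,
                        ...) {
  cfg <- synthetic_config(n_hv = n_hv, n_pwms = n_pwms,
                          parcellation_size = N, seed = seed,
                          group_effect = list(target_modality = "DTI",
                                              affected_edge_fraction = 0.3,
                                              delta = delta),
                          ...)
  generate_cohort(cfg)
}

# number of connected components of the graph with edges <= t
n_components_at <- function(net, t) {
  adj <- net$weights <= t
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::components(g)$no
}

expect_symmetric01 <- function(w) {
  expect_equal(w, t(w))
  expect_true(all(w >= 0 & w <= 1))
  expect_true(all(diag(w) == 0))
}
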