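test_that("flag filtration enumerates cliques with the max-edge rule", {
  w <- sym_mat(c(0.2, 0.3, 0.4), 3) # triangle
  net <- weighted_network(w, modality = "DTI", space = "inverted")
  f <- build_flag_filtration(net, max_hom_dim = 1)
  expect_equal(f$simplices[[1]]$values, rep(0, 3))
  expect_equal(sort(f$simplices[[2]]$values), c(0.2, 0.3, 0.4))
  expect_equal(f$simplices[[3]]$values, 0.4) # 2-simplex at max of its edges

  # complete graph N=5 up to dim 3: binomial simplex counts
  set.seed(2)
  k5 <- random_network(5, space = "inverted", lo = 0.1, hi = 0.9)
  f5 <- build_flag_filtration(k5, max_hom_dim = 2)
  expect_equal(vapply(f5$simplices, function(s) length(s$values), 0),
               c(5, 10, 10, 5))

  expect_error(build_flag_filtration(random_network(4)), "inverted")
  expect_error(build_flag_filtration(k5, max_hom_dim = 3), "0, 1 or 2")
})

test_that("persistence matches hand-worked elder-rule and cycle cases", {
  # single vertex
  one <- weighted_network(matrix(0, 1, 1), modality = "DTI",
                          space = "inverted")
  dg <- compute_persistence(one, 0)
  expect_equal(nrow(dg), 1)
  expect_equal(dg$death, Inf)

  # path on 3 vertices, edges 0.2 / 0.5 (absent edge at dissimilarity 1)
  w <- matrix(1, 3, 3); diag(w) <- 0
  w[1, 2] <- w[2, 1] <- 0.2; w[2, 3] <- w[3, 2] <- 0.5
  dg <- compute_persistence(
    weighted_network(w, modality = "DTI", space = "inverted"), 1)
  d0 <- dg[dg$dimension == 0, ]
  expect_equal(sort(d0$death), c(0.2, 0.5, Inf))
  expect_equal(d0$birth, rep(0, 3))

  # 4-cycle at 0.3 with chords at 0.9: one loop born 0.3, filled at 0.9
  w <- matrix(0.9, 4, 4); diag(w) <- 0
  for (e in list(c(1, 2), c(2, 3), c(3, 4), c(4, 1)))
    w[e[1], e[2]] <- w[e[2], e[1]] <- 0.3
  dg <- compute_persistence(
    weighted_network(w, modality = "DTI", space = "inverted"), 1)
  d1 <- dg[dg$dimension == 1, ]
  expect_equal(nrow(d1), 1)
  expect_equal(c(d1$birth, d1$death), c(0.3, 0.9))
})

test_that("filtration object route equals network route and flags corruption", {
  set.seed(13)
  net <- random_network(7, space = "inverted")
  f <- build_flag_filtration(net, max_hom_dim = 2)
  expect_equal(compute_persistence(f), compute_persistence(net, 2))

  broken <- f
  broken$simplices[[3]]$values[1] <- -0.5 # triangle before its edges
  expect_error(compute_persistence(broken), "monotone")
})

test_that("betti curves follow the half-open interval convention", {
  dg <- data.frame(dimension = 0L, birth = 0.25, death = 0.5)
  class(dg) <- c("persistence_diagram", "data.frame")
  attr(dg, "max_hom_dim") <- 0L
  bc <- betti_curve(dg, grid_size = 5) # grid 0, 0.25, 0.5, 0.75, 1 (exact)
  expect_equal(unname(bc["dim0", ]), c(0L, 1L, 0L, 0L, 0L))
  # alive at birth, dead exactly at death (half-open convention)

  empty <- dg[0, ]
  class(empty) <- c("persistence_diagram", "data.frame")
  attr(empty, "max_hom_dim") <- 2L
  expect_true(all(betti_curve(empty, grid_size = 10) == 0))
  expect_error(betti_curve(dg, grid_size = 1), "grid_size")
})

test_that("rank oracle reproduces textbook Betti numbers", {
  # two isolated vertices
  iso <- weighted_network(matrix(c(0, 1, 1, 0), 2), modality = "DTI",
                          space = "inverted")
  expect_equal(betti_bruteforce_oracle(iso, 0.5, 0), 2)

  # hollow octahedron: beta_2 = 1, no 4-cliques to fill it
  w <- matrix(0.5, 6, 6); diag(w) <- 0
  w[1, 2] <- w[2, 1] <- 1; w[3, 4] <- w[4, 3] <- 1; w[5, 6] <- w[6, 5] <- 1
  oct <- weighted_network(w, modality = "DTI", space = "inverted")
  expect_equal(betti_bruteforce_oracle(oct, 0.6, 2), 1)
  expect_equal(betti_bruteforce_oracle(oct, 0.6, 1), 0)

  # complete K4: triangles fill all cycles
  k4 <- weighted_network(sym_mat(rep(0.5, 6), 4), modality = "DTI",
                         space = "inverted")
  expect_equal(betti_bruteforce_oracle(k4, 0.6, 1), 0)

  expect_error(betti_bruteforce_oracle(random_network(15, space = "inverted"),
                                       0.5, 2), "size guard")
})

test_that("reduction equals the GF(2) rank oracle on random networks", {
  set.seed(101)
  for (i in 1:12) {
    n <- sample(5:10, 1)
    net <- random_network(n, space = "inverted", lo = 0, hi = 1)
    dg <- compute_persistence(net, 2)
    bc <- betti_curve(dg, grid_size = 100)
    grid <- attr(bc, "grid")
    # curves change only at edge values: check a thinned grid + breakpoints
    for (t_idx in seq(1, 100, by = 9)) {
      for (k in 0:2)
        expect_equal(unname(bc[paste0("dim", k), t_idx]),
                     betti_bruteforce_oracle(net, grid[t_idx], k),
                     info = sprintf("n=%d t=%.2f k=%d", n, grid[t_idx], k))
    }
  }
})

test_that("dim-0 Betti numbers equal graph component counts (igraph)", {
  set.seed(55)
  for (i in 1:10) {
    n <- sample(6:12, 1)
    # sparse-ish dissimilarities so components vary with threshold
    ne <- n * (n - 1) / 2
    vals <- ifelse(runif(ne) < 0.4, runif(ne, 0.1, 0.8), 1)
    net <- weighted_network(sym_mat(vals, n), modality = "DTI",
                            space = "inverted")
    dg <- compute_persistence(net, 0)
    bc <- betti_curve(dg, grid_size = 21)
    grid <- attr(bc, "grid")
    for (t_idx in seq_along(grid))
      expect_equal(unname(bc["dim0", t_idx]),
                   n_components_at(net, grid[t_idx]))
    # before the first edge: N components; at/after max edge: full graph
    expect_equal(unname(bc["dim0", 1]), n)
    expect_equal(unname(bc["dim0", 21]), n_components_at(net, 1))
  }
})

test_that("Euler identity holds at every threshold on random instances", {
  set.seed(77)
  for (i in 1:20) {
    n <- sample(5:9, 1)
    net <- random_network(n, space = "inverted", lo = 0, hi = 1)
    for (t in c(0.15, 0.45, 0.75, 1)) {
      eu <- euler_identity(net, t, max_dim = 3)
      expect_equal(eu$simplex_side, eu$betti_side)
    }
  }
})

test_that("diagrams are invariant under vertex relabeling", {
  set.seed(9)
  net <- random_network(8, space = "inverted")
  dg1 <- compute_persistence(net, 2)
  perm <- sample(8)
  net2 <- weighted_network(net$weights[perm, perm],
                           modality = "DTI", space = "inverted")
  dg2 <- compute_persistence(net2, 2)
  key <- function(d) d[order(d$dimension, d$birth, d$death), ]
  expect_equal(key(dg1)$birth, key(dg2)$birth)
  expect_equal(key(dg1)$death, key(dg2)$death)
  expect_equal(key(dg1)$dimension, key(dg2)$dimension)
})

test_that("a dense 76-region subject completes dims 0-2 within budget", {
  cfg <- synthetic_config(n_hv = 8, n_pwms = 0, parcellation_size = 76,
                          seed = 17)
  set.seed(17)
  net <- invert_weights(sample_base_network("DTI", cfg))
  elapsed <- system.time(dg <- compute_persistence(net, 2))[["elapsed"]]
  expect_lt(elapsed, 120)
  expect_true(all(dg$dimension %in% 0:2))
  expect_equal(sum(dg$dimension == 0 & is.infinite(dg$death)), 1)
  b0 <- betti_curve(dg, dims = 0)["dim0", ]
  expect_true(all(diff(b0) <= 0)) # components only ever merge
  expect_equal(unname(b0[1]), 76)
})

test_that("diagram CSV export writes inf deaths readably", {
  set.seed(3)
  dg <- compute_persistence(random_network(6, space = "inverted"), 1)
  p <- withr::local_tempfile(fileext = ".csv")
  write_diagram(dg, p)
  back <- read.csv(p)
  expect_equal(nrow(back), nrow(dg))
  expect_true(any(grepl("inf", readLines(p), fixed = TRUE)))

  bc <- betti_curve(dg, grid_size = 25)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_betti_curves(bc, p2)
  back2 <- read.csv(p2)
  expect_equal(dim(back2), c(2, 26)) # dim label + 25 grid columns
  expect_equal(unname(as.matrix(back2[, -1])), unname(bc),
               ignore_attr = TRUE)
})
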