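test_that("base networks match their target inverted-weight distributions", {
  cfg <- synthetic_config(parcellation_size = 142, seed = 3) # ~10k edges
  set.seed(3)
  dti <- sample_base_network("DTI", cfg)
  inv <- 1 - dti$weights[upper.tri(dti$weights)]
  expect_gt(mean(inv >= 0.4 & inv <= 0.8), 0.80)

  gm <- sample_base_network("GM", cfg)
  inv <- 1 - gm$weights[upper.tri(gm$weights)]
  expect_gt(mean(inv >= 0.3 & inv <= 0.5), 0.80)

  # fmri: raw magnitudes concentrated low, inverted |r| skewed high
  fmri <- sample_base_network("FMRI", cfg)
  vals <- fmri$weights[upper.tri(fmri$weights)]
  expect_true(any(vals < 0)) # signed correlations present
  inv <- 1 - abs(vals)
  expect_gt(mean(inv > 0.5), 0.6)

  expect_error(sample_base_network("PET", cfg), "modality")
})

test_that("inverted DTI weights match the configured truncated normal (KS)", {
  cfg <- synthetic_config(parcellation_size = 142, seed = 5)
  set.seed(5)
  dti <- sample_base_network("DTI", cfg)
  inv <- 1 - dti$weights[upper.tri(dti$weights)]
  # closed-form CDF of 1 - X, X ~ N(0.40, 0.10) truncated to [0, 1]
  pl <- pnorm(0, 0.40, 0.10); ph <- pnorm(1, 0.40, 0.10)
  cdf <- function(q) 1 - (pnorm(1 - q, 0.40, 0.10) - pl) / (ph - pl)
  ks <- suppressWarnings(ks.test(inv, cdf))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("degenerate sd collapses edges to the mean", {
  cfg <- synthetic_config(parcellation_size = 10,
                          modality_params = list(
                            DTI = list(mean = 0.4, sd = 0),
                            GM = list(mean = 0.6, sd = 0.05),
                            FMRI = list(shape1 = 1.2, shape2 = 4,
                                        signed_fraction = 0)))
  net <- sample_base_network("DTI", cfg)
  expect_equal(unique(net$weights[upper.tri(net$weights)]), 0.4)
})

test_that("covariate injection shifts edges linearly and clamps at bounds", {
  set.seed(1)
  net <- random_network(8, lo = 0.3, hi = 0.6)
  same <- inject_covariate_effects(net, 50, "F", list(age = 0, sex = 0))
  expect_identical(same$weights, net$weights)

  up <- inject_covariate_effects(net, 52.5, "M",
                                 list(age = 0.004, sex = 0.01))
  off <- upper.tri(net$weights)
  expect_equal(up$weights[off], net$weights[off] + 0.004 * 10 + 0.01)

  hot <- weighted_network(sym_mat(rep(0.95, 3), 3), modality = "DTI")
  expect_message(
    clamped <- inject_covariate_effects(hot, 62.5, "F",
                                        list(age = 0.02, sex = 0)),
    "clamped")
  expect_equal(max(clamped$weights), 1)
})

test_that("cohorts carry a positive age-weight correlation before residualization", {
  cfg <- synthetic_config(n_hv = 40, n_pwms = 0, parcellation_size = 8,
                          seed = 21,
                          covariate_slopes = list(
                            DTI = list(age = 0.004, sex = 0),
                            GM = list(age = 0, sex = 0),
                            FMRI = list(age = 0, sex = 0)),
                          group_effect = list(target_modality = "DTI",
                                              affected_edge_fraction = 0,
                                              delta = 0))
  ch <- generate_cohort(cfg)
  ages <- vapply(ch$subjects, function(s) s$age, 0)
  W <- sapply(ch$subjects, function(s) s$networks$DTI$weights[2, 5])
  expect_gt(cor(W, ages), 0)
})

test_that("group effect is monotone in delta and null at delta zero", {
  mean_gap <- function(delta, seed = 9) {
    cfg <- synthetic_config(n_hv = 100, n_pwms = 100, parcellation_size = 8,
                            seed = seed,
                            covariate_slopes = list(
                              DTI = list(age = 0, sex = 0),
                              GM = list(age = 0, sex = 0),
                              FMRI = list(age = 0, sex = 0)),
                            group_effect = list(target_modality = "DTI",
                                                affected_edge_fraction = 0.3,
                                                delta = delta))
    ch <- generate_cohort(cfg)
    grp <- cohort_groups(ch)
    up <- upper.tri(ch$subjects[[1]]$networks$DTI$weights)
    W <- t(sapply(ch$subjects, function(s) s$networks$DTI$weights[up]))
    mask <- topoconnectome:::affected_edge_mask(cfg)
    mean(W[grp == "HV", mask]) - mean(W[grp == "PwMS", mask])
  }
  g0 <- mean_gap(0); g05 <- mean_gap(0.05); g15 <- mean_gap(0.15)
  # delta = 0: difference within 2 standard errors of zero
  se <- 0.10 / sqrt(100 * round(0.3 * 28))
  expect_lt(abs(g0), 2 * se)
  expect_lt(g0, g05)
  expect_lt(g05, g15)
  expect_equal(g15, 0.15, tolerance = 0.02)

  # HV networks are untouched bit for bit
  cfg <- synthetic_config(parcellation_size = 8, seed = 2)
  set.seed(2)
  net <- sample_base_network("DTI", cfg)
  expect_identical(inject_group_effect(net, "HV", cfg)$weights, net$weights)
})

test_that("generation is deterministic and independent of subject order", {
  cfg <- synthetic_config(n_hv = 5, n_pwms = 5, parcellation_size = 10,
                          seed = 7)
  ch1 <- generate_cohort(cfg)
  ch2 <- generate_cohort(cfg)
  expect_identical(
    lapply(ch1$subjects, function(s) s$networks$DTI$weights),
    lapply(ch2$subjects, function(s) s$networks$DTI$weights))

  # enlarging the cohort leaves earlier subjects untouched
  cfg2 <- synthetic_config(n_hv = 8, n_pwms = 5, parcellation_size = 10,
                           seed = 7)
  ch3 <- generate_cohort(cfg2)
  expect_identical(ch1$subjects[[3]]$networks$GM$weights,
                   ch3$subjects[[3]]$networks$GM$weights)

  expect_error(generate_cohort(synthetic_config(3, 3, 10)), "at least 8")
})

test_that("generated cohorts satisfy all network invariants at small N", {
  ch <- tiny_cohort(4, 4, N = 10)
  expect_equal(length(ch$subjects), 8)
  for (s in ch$subjects) {
    for (m in c("GM", "DTI")) expect_symmetric01(s$networks[[m]]$weights)
    w <- s$networks$FMRI$weights
    expect_equal(w, t(w))
    expect_true(all(abs(w) <= 1) && all(diag(w) == 0))
  }
})

test_that("yaml config round-trips through the reader", {
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_hv: 5", "n_pwms: 6", "parcellation_size: 12", "seed: 99",
               "group_effect:", "  target_modality: DTI",
               "  affected_edge_fraction: 0.2", "  delta: 0.1"), p)
  cfg <- read_synthetic_config(p)
  expect_equal(cfg$n_hv, 5)
  expect_equal(cfg$parcellation_size, 12)
  expect_equal(cfg$group_effect$delta, 0.1)
  expect_equal(cfg$modality_params$DTI$mean, 0.40) # defaults preserved
})
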