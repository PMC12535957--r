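# Synthetic multimodal cohort generator.
#
# Base edge-weight distributions are chosen so that the *inverted* weights
# (1 - e) reproduce the qualitative histogram shapes of real multimodal
# connectomes: inverted structural (DTI/FA) mass concentrated in 0.4-0.8 and
# roughly normal, inverted gray-matter similarity narrower in 0.3-0.5, and
# inverted functional correlations spread over [0, 1] but skewed high (raw
# correlations concentrated near zero).

#' Configuration for the synthetic multimodal cohort generator
#'
#' @param n_hv,n_pwms Number of healthy volunteers / people with MS.
#' @param parcellation_size Number of regions N (default 76).
#' @param seed Master seed; the whole cohort is a deterministic function of it.
#' @param modality_params Named list per modality. `DTI` and `GM` take
#'   `mean`/`sd` of a `[0,1]`-truncated normal on raw weights; `FMRI` takes
#'   Beta `shape1`/`shape2` on correlation magnitude plus `signed_fraction`,
#'   the expected fraction of edges carrying a negative raw correlation.
#' @param covariate_slopes Named list per modality with `age` (per year,
#'   applied to centered age) and `sex` (additive shift for males).
#' @param group_effect List with `target_modality`, `affected_edge_fraction`
#'   and `delta`: the mean shift subtracted from a fixed, seed-determined
#'   subset of edges in PwMS subjects (a consistent disease-affected
#'   subnetwork).
#' @param community_structure Optional list with `n_blocks` and `boost`
#'   (within-community additive weight contrast), or `NULL`.
#' @param reference_age Age at which covariate effects vanish.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_hv = 30, n_pwms = 30, parcellation_size = 76,
                             seed = 1,
                             modality_params = list(
                               DTI = list(mean = 0.40, sd = 0.10),
                               GM = list(mean = 0.60, sd = 0.05),
                               FMRI = list(shape1 = 1.2, shape2 = 4.0,
                                           signed_fraction = 0.3)),
                             covariate_slopes = list(
                               DTI = list(age = -0.002, sex = 0.01),
                               GM = list(age = -0.002, sex = 0.01),
                               FMRI = list(age = -0.002, sex = 0.01)),
                             group_effect = list(target_modality = "DTI",
                                                 affected_edge_fraction = 0.3,
                                                 delta = 0.15),
                             community_structure = NULL,
                             reference_age = 42.5) {
  stopifnot(n_hv >= 0, n_pwms >= 0, parcellation_size >= 2)
  if (group_effect$affected_edge_fraction < 0 ||
      group_effect$affected_edge_fraction > 1)
    stop("affected_edge_fraction must lie in [0, 1]", call. = FALSE)
  structure(list(n_hv = n_hv, n_pwms = n_pwms,
                 parcellation_size = parcellation_size, seed = as.integer(seed),
                 modality_params = modality_params,
                 covariate_slopes = covariate_slopes,
                 group_effect = group_effect,
                 community_structure = community_structure,
                 reference_age = reference_age),
            class = "synthetic_config")
}

#' Read a generator configuration from YAML
#'
#' The YAML fields mirror the arguments of [synthetic_config()] exactly.
#'
#' @param path YAML file path.
#' @return A `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  y <- yaml::read_yaml(path)
  defaults <- formals(synthetic_config)
  args <- list()
  for (nm in names(defaults)) if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  do.call(synthetic_config, args)
}

# truncated normal on [0, 1] via inverse-CDF sampling
rtrunc01 <- function(n, mean, sd) {
  if (sd <= 0) return(rep(mean, n))
  lo <- stats::pnorm(0, mean, sd)
  hi <- stats::pnorm(1, mean, sd)
  stats::qnorm(lo + runif(n) * (hi - lo), mean, sd)
}

# fill a symmetric zero-diagonal matrix from a vector of upper-tri values
sym_from_upper <- function(vals, n) {
  w <- matrix(0, n, n)
  w[upper.tri(w)] <- vals
  w + t(w)
}

#' Draw one base network for a modality
#'
#' Raw DTI weights are truncated normal (default mean 0.40, sd 0.10) so that
#' inverted weights concentrate in 0.4-0.8; raw GM similarity is truncated
#' normal (mean 0.60, sd 0.05) so inverted mass falls in 0.3-0.5; raw FMRI
#' magnitudes are Beta(1.2, 4.0) (correlations mostly weak, inverted values
#' skewed high), with a configurable fraction of edges flipped negative.
#' Optional block community structure adds a within-community weight boost.
#'
#' @param modality `"GM"`, `"DTI"` or `"FMRI"`.
#' @param config A [synthetic_config()].
#' @return A [weighted_network()] in raw space.
#' @export
sample_base_network <- function(modality, config) {
  if (!modality %in% c("GM", "DTI", "FMRI"))
    stop("unknown modality: ", modality, call. = FALSE)
  n <- config$parcellation_size
  ne <- n * (n - 1L) / 2L
  p <- config$modality_params[[modality]]
  vals <- if (modality == "FMRI") {
    mag <- rbeta(ne, p$shape1, p$shape2)
    sf <- if (is.null(p$signed_fraction)) 0 else p$signed_fraction
    sign <- ifelse(runif(ne) < sf, -1, 1)
    mag * sign
  } else {
    rtrunc01(ne, p$mean, p$sd)
  }
  w <- sym_from_upper(vals, n)
  cs <- config$community_structure
  if (!is.null(cs)) {
    block <- rep_len(seq_len(cs$n_blocks), n)
    same <- outer(block, block, "==")
    diag(same) <- FALSE
    w[same] <- w[same] + cs$boost
    w <- if (modality == "FMRI") clamp_range(w, -1) else clamp01(w)
    diag(w) <- 0
  }
  weighted_network(w, modality = modality, space = "raw")
}

#' Add linear age and sex effects to a network's edges
#'
#' Shifts every edge by `slope_age * (age - reference_age) + slope_sex * I(male)`
#' and clamps back into the admissible range; the count of clamped entries is
#' reported via a message when nonzero.
#'
#' @param net A raw-space [weighted_network()].
#' @param age Age in years.
#' @param sex `"F"` or `"M"`.
#' @param slopes List with `age` and `sex` slopes.
#' @param reference_age Age at which the effect vanishes.
#' @return The shifted network.
#' @export
inject_covariate_effects <- function(net, age, sex, slopes,
                                     reference_age = 42.5) {
  stopifnot(is.finite(slopes$age), is.finite(slopes$sex))
  shift <- slopes$age * (age - reference_age) + slopes$sex * (sex == "M")
  w <- net$weights
  off <- row(w) != col(w)
  shifted <- w
  shifted[off] <- w[off] + shift
  lo <- if (net$modality == "FMRI" && net$space == "raw") -1 else 0
  clamped <- sum(shifted[off] < lo | shifted[off] > 1)
  if (clamped > 0)
    message(sprintf("inject_covariate_effects: clamped %d edges", clamped))
  shifted <- clamp_range(shifted, lo)
  weighted_network(shifted, net$region_labels, net$modality, net$space)
}

# the disease-affected edge subset: fixed per config seed, shared by subjects
affected_edge_mask <- function(config) {
  n <- config$parcellation_size
  ne <- n * (n - 1L) / 2L
  k <- round(config$group_effect$affected_edge_fraction * ne)
  old <- .Random.seed.save()
  set.seed((config$seed * 7919L + 13L) %% 2147483647L)
  idx <- sample.int(ne, k)
  .Random.seed.restore(old)
  mask <- logical(ne)
  mask[idx] <- TRUE
  mask
}

.Random.seed.save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed.restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Subtract the group effect from a PwMS subject's target-modality network
#'
#' For PwMS subjects, `delta` is subtracted from a fixed, seed-determined
#' subset of edges (the same subnetwork for every subject, so the group
#' signal is consistent and learnable). HV subjects and non-target
#' modalities pass through unchanged.
#'
#' @param net A [weighted_network()].
#' @param group `"HV"` or `"PwMS"`.
#' @param config A [synthetic_config()] (carries the effect spec and seed).
#' @return The (possibly shifted) network.
#' @export
inject_group_effect <- function(net, group, config) {
  eff <- config$group_effect
  if (group != "PwMS" || net$modality != eff$target_modality ||
      eff$delta == 0)
    return(net)
  mask <- affected_edge_mask(config)
  w <- net$weights
  up <- upper.tri(w)
  vals <- w[up]
  vals[mask] <- vals[mask] - eff$delta
  lo <- if (net$modality == "FMRI" && net$space == "raw") -1 else 0
  vals <- clamp_range(vals, lo)
  w2 <- sym_from_upper(vals, nrow(w))
  weighted_network(w2, net$region_labels, net$modality, net$space)
}

#' Generate a reproducible synthetic cohort
#'
#' Ages are uniform on 25-60 years, sex is Bernoulli (60% female). Each
#' subject receives three networks through the sample -> covariate-effect ->
#' group-effect chain. Each subject is generated from its own seed derived
#' from the master seed, so subject order and cohort size do not perturb
#' individual subjects.
#'
#' @param config A [synthetic_config()].
#' @return A [cohort()].
#' @export
generate_cohort <- function(config) {
  n_tot <- config$n_hv + config$n_pwms
  if (n_tot < 8)
    stop("need at least 8 subjects to support 4-fold cross-validation",
         call. = FALSE)
  groups <- c(rep("HV", config$n_hv), rep("PwMS", config$n_pwms))
  labs <- sprintf("r%03d", seq_len(config$parcellation_size))
  subjects <- lapply(seq_len(n_tot), function(i) {
    set.seed((config$seed * 104729L + i * 7L) %% 2147483647L)
    age <- runif(1, 25, 60)
    sex <- if (runif(1) < 0.6) "F" else "M"
    nets <- lapply(c("GM", "DTI", "FMRI"), function(m) {
      net <- sample_base_network(m, config)
      net$region_labels <- labs
      net <- inject_covariate_effects(net, age, sex,
                                      config$covariate_slopes[[m]],
                                      config$reference_age)
      inject_group_effect(net, groups[i], config)
    })
    names(nets) <- c("GM", "DTI", "FMRI")
    subject_record(sprintf("S%03d", i), groups[i], age, sex, nets)
  })
  cohort(subjects,
         provenance = sprintf("synthetic seed=%d n_hv=%d n_pwms=%d N=%d",
                              config$seed, config$n_hv, config$n_pwms,
                              config$parcellation_size))
}
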