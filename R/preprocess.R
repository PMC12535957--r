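# Network-level preprocessing: absolute value of functional correlations,
# edge-wise covariate residualization across subjects, weight inversion for
# persistent homology, and supra-adjacency multilayer assembly.

#' Absolute value of signed functional correlations
#'
#' @param net A raw-space FMRI [weighted_network()] with entries in `[-1, 1]`.
#' @return The network with elementwise absolute values.
#' @export
absolute_correlations <- function(net) {
  if (min(net$weights) < -1 || max(net$weights) > 1)
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  weighted_network(abs(net$weights), net$region_labels, net$modality,
                   net$space)
}

#' Edge-wise residualization of age and sex effects
#'
#' For each modality and each edge independently, ordinary least squares of
#' edge weight on (intercept, age, sex indicator) is fitted across subjects;
#' each value is replaced by its residual plus that edge's cross-subject
#' mean. Singular designs (e.g. constant covariates) are handled through the
#' pseudoinverse and degrade to mean-centering round-trips, never an error.
#' Residuals may leave `[0, 1]`; they are clamped, with the clamp count
#' reported via a message.
#'
#' @param ch A [cohort()] with at least 3 subjects. FMRI networks should be
#'   in absolute-value form first (see [preprocess_cohort()]).
#' @return The residualized cohort.
#' @export
residualize_edgewise <- function(ch) {
  n <- length(ch$subjects)
  if (n < 3) stop("residualization needs at least 3 subjects", call. = FALSE)
  age <- vapply(ch$subjects, function(s) s$age, 0)
  sex <- vapply(ch$subjects, function(s) as.numeric(s$sex == "M"), 0)
  X <- cbind(1, age, sex)
  # hat matrix through the pseudoinverse so rank-deficient designs are fine
  sv <- svd(X)
  pos <- sv$d > max(sv$d) * 1e-12
  Xp <- sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  np <- ch$parcellation_size
  up <- upper.tri(matrix(0, np, np))
  subjects <- ch$subjects
  total_clamped <- 0L
  for (m in c("GM", "DTI", "FMRI")) {
    W <- do.call(rbind, lapply(subjects, function(s) s$networks[[m]]$weights[up]))
    fitted <- X %*% (Xp %*% W)
    resid <- W - fitted
    out <- sweep(resid, 2, colMeans(W), "+")
    clamped <- sum(out < 0 | out > 1)
    total_clamped <- total_clamped + clamped
    out <- clamp01(out)
    for (i in seq_len(n)) {
      w <- sym_from_upper(out[i, ], np)
      net <- subjects[[i]]$networks[[m]]
      subjects[[i]]$networks[[m]] <-
        weighted_network(w, net$region_labels, net$modality, net$space)
    }
  }
  if (total_clamped > 0)
    message(sprintf("residualize_edgewise: clamped %d values to [0, 1]",
                    total_clamped))
  cohort(subjects, provenance = paste0(ch$provenance, " +residualized"))
}

#' Invert edge weights to dissimilarities
#'
#' Applies `1 - e` to every off-diagonal entry, turning connectivity scores
#' into dissimilarities for the flag filtration (absent connections, weight
#' 0, map to maximal dissimilarity 1). The diagonal stays 0 and is ignored
#' by the filtration. Double inversion is rejected through the `space` flag
#' unless `force = TRUE`.
#'
#' @param net A raw-space [weighted_network()] with nonnegative weights.
#' @param force Allow inverting an already-inverted network (the map is an
#'   involution; used in tests).
#' @return The network in inverted space.
#' @export
invert_weights <- function(net, force = FALSE) {
  if (net$space == "inverted" && !force)
    stop("network is already in inverted space", call. = FALSE)
  if (min(net$weights) < 0)
    stop("cannot invert signed weights; apply absolute_correlations() first",
         call. = FALSE)
  w <- 1 - net$weights
  diag(w) <- 0
  weighted_network(w, net$region_labels, net$modality,
                   space = if (net$space == "raw") "inverted" else "raw")
}

#' Assemble the supra-adjacency multilayer network of one subject
#'
#' Builds the 2N x 2N block matrix `[[GM, DTI], [t(DTI), FMRI]]`: the GM and
#' FMRI networks form the two intralayer blocks while the DTI structural
#' matrix provides the interlayer links. The coupling between region i's two
#' replicas is the DTI diagonal as stored (0) unless `replica_coupling`
#' overrides it with a constant in (0, 1].
#'
#' @param subject A [subject_record()] whose three networks share one space.
#' @param replica_coupling `NULL` (keep DTI diagonal, i.e. 0) or a constant
#'   in (0, 1].
#' @return An object of class `multilayer_network` holding the supra
#'   `weighted_network` (modality `"SUPRA"`) plus layer bookkeeping.
#' @export
build_supra_adjacency <- function(subject, replica_coupling = NULL) {
  nets <- subject$networks
  ns <- vapply(nets, n_regions, 0L)
  if (length(unique(ns)) != 1)
    stop("mismatched parcellations across modalities", call. = FALSE)
  spaces <- vapply(nets, function(x) x$space, "")
  if (length(unique(spaces)) != 1)
    stop("all three networks must share the same space", call. = FALSE)
  if (min(nets$FMRI$weights) < 0)
    stop("FMRI network carries signed entries; apply absolute_correlations()",
         call. = FALSE)
  N <- ns[[1]]
  inter <- nets$DTI$weights
  if (!is.null(replica_coupling)) {
    if (replica_coupling <= 0 || replica_coupling > 1)
      stop("replica_coupling must lie in (0, 1]", call. = FALSE)
    diag(inter) <- replica_coupling
  }
  supra <- rbind(cbind(nets$GM$weights, inter),
                 cbind(t(inter), nets$FMRI$weights))
  labs <- c(paste0(nets$GM$region_labels, "|GM"),
            paste0(nets$GM$region_labels, "|FMRI"))
  net <- structure(
    list(weights = unname(supra), region_labels = labs, modality = "SUPRA",
         space = spaces[[1]]),
    class = "weighted_network")
  # replica coupling sits on the off-diagonal block's diagonal, so the supra
  # diagonal itself is still zero and the standard invariants hold
  validate_network(net)
  structure(list(network = net,
                 layer_of_node = rep(c("GM", "FMRI"), each = N),
                 anatomical_index = rep(seq_len(N), 2)),
            class = "multilayer_network")
}

#' @export
print.multilayer_network <- function(x, ...) {
  cat(sprintf("<multilayer_network> 2N = %d supra nodes (GM/FMRI layers, DTI interlinks)\n",
              length(x$layer_of_node)))
  invisible(x)
}

#' Extract the three modality blocks back out of a supra network
#'
#' @param ml A [build_supra_adjacency()] result.
#' @return List with `GM`, `FMRI` (intralayer blocks) and `DTI` (interlayer
#'   block, replica-coupling diagonal included).
#' @export
supra_blocks <- function(ml) {
  w <- ml$network$weights
  N <- length(ml$layer_of_node) / 2
  list(GM = w[1:N, 1:N], DTI = w[1:N, (N + 1):(2 * N)],
       FMRI = w[(N + 1):(2 * N), (N + 1):(2 * N)])
}

#' Invert a supra-adjacency network for persistent homology
#'
#' The multilayer complex is filtered on the inverted supra matrix; inversion
#' is applied to the assembled raw blocks as a whole, so an absent interlayer
#' link (raw 0, including the default replica coupling) becomes dissimilarity
#' 1 and enters the complex only at the final threshold.
#'
#' @param ml A raw-space [build_supra_adjacency()] result.
#' @return The `multilayer_network` with its supra network in inverted space.
#' @export
invert_supra <- function(ml) {
  ml$network <- invert_weights(ml$network)
  ml
}

#' Standard preprocessing chain for a cohort
#'
#' Applies, in order: absolute value on FMRI correlations, then (optionally)
#' edge-wise age/sex residualization. Inversion is not applied here; it is
#' performed per-use inside the homology featurizers, while graph metrics
#' consume raw weights.
#'
#' @param ch A [cohort()].
#' @param abs_fmri Apply [absolute_correlations()] to FMRI networks.
#' @param residualize Apply [residualize_edgewise()].
#' @return The preprocessed cohort.
#' @export
preprocess_cohort <- function(ch, abs_fmri = TRUE, residualize = TRUE) {
  if (abs_fmri) {
    ch$subjects <- lapply(ch$subjects, function(s) {
      s$networks$FMRI <- absolute_correlations(s$networks$FMRI)
      s
    })
  }
  if (residualize) ch <- residualize_edgewise(ch)
  ch
}
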