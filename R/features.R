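# Per-subject feature assembly: Betti-curve vectors and node-metric vectors
# for every network representation (single layers, concatenated single
# layers, multilayer supra-adjacency), plus PCA reduction and random-forest
# importance selection fitted on training rows only.

REPRESENTATIONS <- c("SL-DTI", "SL-GM", "SL-FMRI", "concat-SL", "multilayer")
ALL_METRICS <- c("degree", "strength", "local_efficiency", "betweenness",
                 "closeness")

#' Subjects-by-features table with provenance
#'
#' @param X Numeric matrix, one row per subject; column names are provenance
#'   strings uniquely identifying every feature.
#' @param subject_ids Character vector aligned with rows.
#' @param labels Group label per subject (`"HV"` / `"PwMS"`).
#' @param config_tag Configuration identifier, e.g. `"SL-DTI/betti-dims01"`.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(X, subject_ids, labels, config_tag) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(subject_ids), nrow(X) == length(labels))
  if (anyNA(X)) stop("feature matrix contains missing values", call. = FALSE)
  if (anyDuplicated(colnames(X)))
    stop("feature provenance strings must be unique", call. = FALSE)
  structure(list(X = X, subject_ids = as.character(subject_ids),
                 labels = as.character(labels), config_tag = config_tag),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %s: %d subjects x %d features\n",
              x$config_tag, nrow(x$X), ncol(x$X)))
  invisible(x)
}

# dissimilarity network(s) a representation needs, per subject
subject_complexes <- function(subject, representation, replica_coupling = NULL) {
  if (representation == "multilayer") {
    ml <- build_supra_adjacency(subject, replica_coupling = replica_coupling)
    list(ML = invert_supra(ml)$network)
  } else if (representation == "concat-SL") {
    lapply(subject$networks, invert_weights)
  } else {
    m <- sub("SL-", "", representation)
    stats::setNames(list(invert_weights(subject$networks[[m]])), m)
  }
}

#' Betti-curve features for a cohort
#'
#' For each subject, persistence diagrams of the representation's flag
#' filtration(s) are vectorized as Betti curves on a `grid_size` grid and
#' concatenated across the requested homology dimensions (and, for
#' `"concat-SL"`, across the three modalities). Column counts:
#' `grid_size * length(dims)` per single layer or multilayer,
#' `3 * grid_size * length(dims)` for `"concat-SL"`.
#'
#' @param ch A preprocessed [cohort()] in raw space (inversion is handled
#'   internally; FMRI must be non-negative).
#' @param representation One of `"SL-DTI"`, `"SL-GM"`, `"SL-FMRI"`,
#'   `"concat-SL"`, `"multilayer"`.
#' @param dims Non-empty subset of `c(0, 1, 2)`.
#' @param grid_size Betti-curve grid length (default 100).
#' @param supra_dim_cap Highest homology dimension computed on the 2N-node
#'   supra complex; dims above it are capped with a message (the supra
#'   complex is an order of magnitude larger than the single layers).
#' @param replica_coupling Passed to [build_supra_adjacency()].
#' @return A [feature_matrix()].
#' @export
betti_features <- function(ch, representation = REPRESENTATIONS,
                           dims = c(0, 1, 2), grid_size = 100,
                           supra_dim_cap = 2, replica_coupling = NULL) {
  representation <- match.arg(representation)
  if (length(dims) == 0) stop("dims must be non-empty", call. = FALSE)
  if (!all(dims %in% 0:2)) stop("dims must be a subset of {0, 1, 2}", call. = FALSE)
  dims <- sort(unique(dims))
  use_dims <- dims
  if (representation == "multilayer" && max(dims) > supra_dim_cap) {
    message(sprintf("multilayer homology capped at dimension %d (requested %d)",
                    supra_dim_cap, max(dims)))
    use_dims <- dims[dims <= supra_dim_cap]
  }
  rows <- lapply(ch$subjects, function(s) {
    nets <- subject_complexes(s, representation, replica_coupling)
    unlist(lapply(names(nets), function(nm) {
      dg <- compute_persistence(nets[[nm]], max_hom_dim = max(use_dims))
      bc <- betti_curve(dg, grid_size = grid_size, dims = use_dims)
      # capped dims (multilayer only) are emitted as zero curves so the
      # advertised column count is independent of the cap
      out <- matrix(0, length(dims), grid_size,
                    dimnames = list(paste0("dim", dims), NULL))
      out[rownames(bc), ] <- bc
      stats::setNames(as.vector(t(out)),
                      as.vector(t(outer(paste0(nm, "|betti|dim", dims),
                                        sprintf("t%03d", seq_len(grid_size)),
                                        paste, sep = "|"))))
    }))
  })
  X <- do.call(rbind, rows)
  feature_matrix(X, vapply(ch$subjects, function(s) s$subject_id, ""),
                 cohort_groups(ch),
                 sprintf("%s/betti-dims%s", representation,
                         paste(dims, collapse = "")))
}

#' Node-metric features for a cohort
#'
#' Concatenates a node metric across all regions into one vector per graph.
#' Column counts: one metric on a single layer or multilayer gives N
#' columns; `"ALL"` gives 5N; `"concat-SL"` multiplies by 3.
#'
#' @param ch A preprocessed [cohort()] (raw space; metrics consume raw
#'   weights).
#' @param representation As in [betti_features()].
#' @param metric A metric tag or `"ALL"` for all five concatenated.
#' @param degree_threshold Edge threshold for the degree metric.
#' @param distance_transform Passed to the path-based metrics.
#' @param replica_coupling Passed to [build_supra_adjacency()].
#' @return A [feature_matrix()].
#' @export
metric_features <- function(ch, representation = REPRESENTATIONS,
                            metric = c("ALL", ALL_METRICS),
                            degree_threshold = 0,
                            distance_transform = "inverse",
                            replica_coupling = NULL) {
  representation <- match.arg(representation)
  metric <- match.arg(metric)
  metrics <- if (metric == "ALL") ALL_METRICS else metric
  one_layer <- function(net, prefix) {
    unlist(lapply(metrics, function(m) {
      mv <- if (m == "degree") node_degree(net, degree_threshold)
            else node_metric(net, m, distance_transform = distance_transform)
      stats::setNames(mv$values, paste(prefix, m, mv$region_labels, sep = "|"))
    }))
  }
  rows <- lapply(ch$subjects, function(s) {
    if (representation == "multilayer") {
      ml <- build_supra_adjacency(s, replica_coupling = replica_coupling)
      unlist(lapply(metrics, function(m) {
        mv <- if (m == "degree")
                multilayer_metric(ml, "degree")
              else multilayer_metric(ml, m,
                                     distance_transform = distance_transform)
        stats::setNames(mv$values, paste("ML", m, mv$region_labels, sep = "|"))
      }))
    } else if (representation == "concat-SL") {
      unlist(lapply(c("GM", "DTI", "FMRI"), function(nm)
        one_layer(s$networks[[nm]], nm)))
    } else {
      nm <- sub("SL-", "", representation)
      one_layer(s$networks[[nm]], nm)
    }
  })
  X <- do.call(rbind, rows)
  feature_matrix(X, vapply(ch$subjects, function(s) s$subject_id, ""),
                 cohort_groups(ch),
                 sprintf("%s/metric-%s", representation, metric))
}

#' PCA reduction fitted on training rows only
#'
#' Columns are centered with training means; the projection is the leading
#' right singular vectors of the centered training matrix, applied to both
#' training and test rows. The cumulative explained-variance fraction of the
#' retained components is attached as attribute `explained_variance`.
#'
#' @param train_X,test_X [feature_matrix()] objects with matching columns.
#' @param n_components Number of components to retain (default 20); silently
#'   reduced (with a warning) when it exceeds `min(n_train - 1, n_columns)`.
#' @return List with reduced `train` and `test` feature matrices.
#' @export
pca_reduce <- function(train_X, test_X, n_components = 20) {
  Xtr <- train_X$X
  kmax <- min(nrow(Xtr) - 1L, ncol(Xtr))
  if (n_components > kmax) {
    warning("n_components reduced from ", n_components, " to ", kmax,
            call. = FALSE)
    n_components <- kmax
  }
  mu <- colMeans(Xtr)
  C <- sweep(Xtr, 2, mu)
  sv <- svd(C, nu = 0, nv = kmax)
  rot <- sv$v[, seq_len(n_components), drop = FALSE]
  evar <- sum(sv$d[seq_len(n_components)]^2) / sum(sv$d^2)
  project <- function(fm) {
    Z <- sweep(fm$X, 2, mu) %*% rot
    colnames(Z) <- sprintf("pca|pc%02d", seq_len(ncol(Z)))
    feature_matrix(Z, fm$subject_ids, fm$labels,
                   paste0(fm$config_tag, "/pca", n_components))
  }
  out <- list(train = project(train_X), test = project(test_X))
  attr(out, "explained_variance") <- evar
  out
}

#' Random-forest importance selection fitted on training rows only
#'
#' A random forest (default 100 trees, Gini impurity) is fitted on the
#' training rows; the `top_k` columns by impurity importance (ties broken by
#' column index) are kept in both training and test tables.
#'
#' @param train_X,test_X [feature_matrix()] objects with matching columns.
#' @param n_trees Number of trees (default 100).
#' @param top_k Number of columns to keep (default 100).
#' @param seed Integer seed for the forest.
#' @return List with reduced `train` and `test` feature matrices plus the
#'   selected column indices as attribute `selected`.
#' @export
rf_importance_select <- function(train_X, test_X, n_trees = 100,
                                 top_k = 100, seed = 1) {
  p <- ncol(train_X$X)
  if (top_k > p) stop("top_k exceeds column count", call. = FALSE)
  df <- data.frame(train_X$X, check.names = FALSE)
  fit <- ranger::ranger(x = df, y = factor(train_X$labels),
                        num.trees = n_trees, importance = "impurity",
                        seed = seed, num.threads = 1)
  imp <- fit$variable.importance
  sel <- sort(order(-imp, seq_along(imp))[seq_len(top_k)])
  subset_fm <- function(fm) {
    feature_matrix(fm$X[, sel, drop = FALSE], fm$subject_ids, fm$labels,
                   paste0(fm$config_tag, "/top", top_k))
  }
  out <- list(train = subset_fm(train_X), test = subset_fm(test_X))
  attr(out, "selected") <- sel
  out
}
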