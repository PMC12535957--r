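# Node-level graph metrics on raw-space weighted networks, plus the supra
# convention for multilayer versions. Path-based metrics (local efficiency,
# betweenness, closeness) use edge length 1/weight by default (a stronger
# connection is a shorter path); 1 - weight is available as an alternative.

edge_lengths <- function(w, distance_transform = c("inverse", "one_minus")) {
  distance_transform <- match.arg(distance_transform)
  len <- w
  pos <- w > 0
  len[!pos] <- 0
  len[pos] <- if (distance_transform == "inverse") 1 / w[pos] else 1 - w[pos]
  # a weight of exactly 1 under 1 - w would give length 0; keep it positive
  len[pos & len == 0] <- .Machine$double.eps
  len
}

graph_from_network <- function(net, distance_transform = "inverse") {
  len <- edge_lengths(net$weights, distance_transform)
  igraph::graph_from_adjacency_matrix(len, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

metric_vector <- function(values, metric, net, conventions) {
  structure(list(metric = metric, values = as.numeric(values),
                 region_labels = net$region_labels,
                 conventions = conventions),
            class = "node_metric_vector")
}

#' @export
print.node_metric_vector <- function(x, ...) {
  cat(sprintf("<node_metric_vector> %s over %d nodes (range %.3f-%.3f)\n",
              x$metric, length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Node degree
#'
#' Number of incident edges with weight strictly above `edge_threshold`.
#' On dense correlation-derived matrices the default threshold 0 makes the
#' degree N-1 everywhere, so the threshold is exposed.
#'
#' @param net A raw-space [weighted_network()].
#' @param edge_threshold Weight threshold in `[0, 1)`.
#' @return A `node_metric_vector`.
#' @export
node_degree <- function(net, edge_threshold = 0) {
  if (edge_threshold < 0 || edge_threshold >= 1)
    stop("edge_threshold must lie in [0, 1)", call. = FALSE)
  w <- net$weights
  metric_vector(colSums(w > edge_threshold), "degree", net,
                list(edge_threshold = edge_threshold))
}

#' Node strength (weighted degree)
#'
#' Sum of the weights of all edges incident to each node (row sums).
#'
#' @param net A raw-space [weighted_network()].
#' @return A `node_metric_vector`.
#' @export
node_strength <- function(net) {
  metric_vector(rowSums(net$weights), "strength", net, list())
}

#' Local efficiency
#'
#' For each node v, the global efficiency of the subgraph induced on v's
#' neighbors (weight > 0): the mean over ordered neighbor pairs of the
#' inverse shortest-path length, with edge length 1/weight. Pairs that are
#' unreachable inside the neighborhood contribute 0; nodes with fewer than
#' two neighbors score 0.
#'
#' @param net A raw-space [weighted_network()].
#' @param distance_transform `"inverse"` (1/w, default) or `"one_minus"`.
#' @return A `node_metric_vector`.
#' @export
local_efficiency <- function(net, distance_transform = "inverse") {
  w <- net$weights
  n <- nrow(w)
  vals <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(w[v, ] > 0)
    if (length(nb) < 2) next
    sub <- weighted_network(w[nb, nb, drop = FALSE],
                            net$region_labels[nb], net$modality, net$space)
    g <- graph_from_network(sub, distance_transform)
    d <- igraph::distances(g, weights = igraph::E(g)$weight)
    inv <- 1 / d
    diag(inv) <- 0
    inv[is.infinite(d)] <- 0
    vals[v] <- sum(inv) / (length(nb) * (length(nb) - 1))
  }
  metric_vector(vals, "local_efficiency", net,
                list(distance_transform = distance_transform))
}

#' Betweenness centrality
#'
#' Weighted shortest-path betweenness with edge length 1/weight and exact
#' shortest-path counting, normalized by `(N-1)(N-2)/2`.
#'
#' @inheritParams local_efficiency
#' @return A `node_metric_vector`.
#' @export
betweenness_centrality <- function(net, distance_transform = "inverse") {
  n <- n_regions(net)
  g <- graph_from_network(net, distance_transform)
  b <- igraph::betweenness(g, directed = FALSE,
                           weights = igraph::E(g)$weight)
  norm <- (n - 1) * (n - 2) / 2
  metric_vector(if (norm > 0) b / norm else b * 0, "betweenness", net,
                list(distance_transform = distance_transform,
                     normalization = "(N-1)(N-2)/2"))
}

#' Closeness centrality with component-size scaling
#'
#' With edge length 1/weight and `r_v` the number of nodes reachable from v,
#' `c(v) = (r_v / (N - 1)) * (r_v / sum of distances to reachable nodes)`.
#' The component-size factor keeps disconnected graphs comparable; isolated
#' nodes score 0.
#'
#' @inheritParams local_efficiency
#' @return A `node_metric_vector`.
#' @export
closeness_centrality <- function(net, distance_transform = "inverse") {
  n <- n_regions(net)
  g <- graph_from_network(net, distance_transform)
  d <- igraph::distances(g, weights = igraph::E(g)$weight)
  vals <- vapply(seq_len(n), function(v) {
    dv <- d[v, -v]
    reach <- dv[is.finite(dv)]
    r <- length(reach)
    if (r == 0 || sum(reach) == 0) return(0)
    (r / (n - 1)) * (r / sum(reach))
  }, 0)
  metric_vector(vals, "closeness", net,
                list(distance_transform = distance_transform,
                     disconnected = "component-size scaling"))
}

METRIC_FUNS <- list(degree = function(net, ...) node_degree(net),
                    strength = function(net, ...) node_strength(net),
                    local_efficiency = local_efficiency,
                    betweenness = betweenness_centrality,
                    closeness = closeness_centrality)

#' Compute one named node metric
#'
#' @param net A raw-space [weighted_network()].
#' @param metric One of `"degree"`, `"strength"`, `"local_efficiency"`,
#'   `"betweenness"`, `"closeness"`.
#' @param ... Passed to the metric function.
#' @return A `node_metric_vector`.
#' @export
node_metric <- function(net, metric, ...) {
  if (!metric %in% names(METRIC_FUNS))
    stop("unknown metric: ", metric, call. = FALSE)
  METRIC_FUNS[[metric]](net, ...)
}

#' Node metric on a multilayer network (supra convention)
#'
#' Computes the chosen single-layer metric on the 2N-node supra graph.
#' With `aggregate = "mean"`, each region's two replica values (GM layer and
#' FMRI layer) are averaged to length N; `aggregate = "none"` returns the
#' raw length-2N vector. This supra-graph treatment is this package's
#' declared multilayer convention.
#'
#' @param ml A raw-space [build_supra_adjacency()] result.
#' @param metric Metric tag as in [node_metric()].
#' @param aggregate `"mean"` or `"none"`.
#' @param ... Passed to the metric function.
#' @return A `node_metric_vector` (length N or 2N).
#' @export
multilayer_metric <- function(ml, metric, aggregate = c("mean", "none"), ...) {
  aggregate <- match.arg(aggregate)
  mv <- node_metric(ml$network, metric, ...)
  if (aggregate == "none") return(mv)
  N <- length(ml$layer_of_node) / 2
  vals <- (mv$values[1:N] + mv$values[(N + 1):(2 * N)]) / 2
  structure(list(metric = metric, values = vals,
                 region_labels = ml$network$region_labels[1:N],
                 conventions = c(mv$conventions,
                                 list(multilayer = "supra-graph, replica mean"))),
            class = "node_metric_vector")
}
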