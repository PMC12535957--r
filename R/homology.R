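# Persistent homology of weighted-graph flag filtrations.
#
# The flag (Vietoris-Rips) complex of a dissimilarity matrix contains a
# simplex for every clique of the thresholded graph; a k-simplex enters the
# filtration at the maximum of its edges' dissimilarities. Persistence pairs
# are computed by boundary-matrix column reduction over GF(2) (twist/clearing
# optimized, in C++), with simplices ordered by (value, dimension,
# lexicographic vertex tuple). Intervals follow the half-open [b, d)
# convention; zero-length pairs are dropped and infinite dim-0 bars are
# retained (and counted in Betti curves for all t >= birth).

#' Build the flag filtration of an inverted-space network
#'
#' All vertices enter at 0; edge (i, j) at its dissimilarity; k-simplices
#' (k >= 2) are cliques with value equal to the maximum of their edges.
#' Simplices are enumerated up to dimension `max_hom_dim + 1`, the highest
#' needed to resolve homology up to `max_hom_dim`. Diagonal entries are
#' ignored.
#'
#' @param net An inverted-space [weighted_network()] (dissimilarities).
#' @param max_hom_dim Highest homology dimension requested (0, 1 or 2).
#' @return An object of class `flag_filtration` with per-dimension simplex
#'   tables (`vertices` matrices, 1-based, rows sorted ascending; `values`).
#' @export
build_flag_filtration <- function(net, max_hom_dim = 2) {
  if (net$space != "inverted")
    stop("flag filtration requires an inverted-space (dissimilarity) network",
         call. = FALSE)
  if (!max_hom_dim %in% 0:2)
    stop("max_hom_dim must be 0, 1 or 2", call. = FALSE)
  simp <- cpp_flag_simplices(net$weights, max_hom_dim + 1L)
  structure(list(simplices = simp, max_hom_dim = as.integer(max_hom_dim),
                 weights = net$weights, n_vertices = nrow(net$weights)),
            class = "flag_filtration")
}

#' @export
print.flag_filtration <- function(x, ...) {
  counts <- vapply(x$simplices, function(s) length(s$values), 0)
  cat(sprintf("<flag_filtration> %d vertices, simplex counts by dim: %s\n",
              x$n_vertices, paste(counts, collapse = ", ")))
  invisible(x)
}

# every face must enter no later than its cofaces
check_monotone <- function(filtration) {
  simp <- filtration$simplices
  for (d in seq_along(simp)[-1]) {
    V <- simp[[d]]$vertices
    v <- simp[[d]]$values
    ed <- simp[[2]]$vertices
    edge_val <- matrix(NA_real_, filtration$n_vertices, filtration$n_vertices)
    edge_val[ed] <- simp[[2]]$values
    edge_val[ed[, 2:1, drop = FALSE]] <- simp[[2]]$values
    if (d >= 3) {
      for (i in seq_len(nrow(V))) {
        pairs <- combn(V[i, ], 2)
        if (v[i] < max(edge_val[cbind(pairs[1, ], pairs[2, ])]) - 1e-12)
          stop("non-monotone filtration: a simplex enters before one of its faces",
               call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Compute the persistence diagram of a flag filtration
#'
#' Standard boundary-matrix column reduction over the two-element field.
#' Paired simplices (sigma, tau) yield intervals (value(sigma), value(tau))
#' in dim(sigma); unpaired simplices of dimension at most `max_hom_dim`
#' yield infinite intervals. Zero-length intervals are dropped.
#'
#' @param x A [build_flag_filtration()] result, or an inverted-space
#'   [weighted_network()] (the filtration is then built internally without
#'   materializing the simplex tables, which is faster for large networks).
#' @param max_hom_dim Highest homology dimension (used when `x` is a
#'   network; a filtration carries its own).
#' @return A data frame of class `persistence_diagram` with columns
#'   `dimension`, `birth`, `death` (`Inf` allowed).
#' @export
compute_persistence <- function(x, max_hom_dim = 2) {
  if (inherits(x, "flag_filtration")) {
    check_monotone(x)
    D <- x$weights
    max_hom_dim <- x$max_hom_dim
  } else if (inherits(x, "weighted_network")) {
    if (x$space != "inverted")
      stop("persistence requires an inverted-space network", call. = FALSE)
    D <- x$weights
  } else stop("x must be a flag_filtration or weighted_network", call. = FALSE)
  m <- cpp_persistence(D, as.integer(max_hom_dim))
  dg <- data.frame(dimension = as.integer(m[, 1]), birth = m[, 2],
                   death = m[, 3])
  dg <- dg[order(dg$dimension, dg$birth, dg$death), , drop = FALSE]
  rownames(dg) <- NULL
  class(dg) <- c("persistence_diagram", "data.frame")
  attr(dg, "max_hom_dim") <- as.integer(max_hom_dim)
  dg
}

#' Sample Betti curves from a persistence diagram
#'
#' `beta_k(t)` counts intervals of dimension k with `birth <= t < death`;
#' infinite deaths count for every `t >= birth`. The grid is `grid_size`
#' equally spaced values on `[0, 1]`, endpoints included.
#'
#' @param diagram A [compute_persistence()] result.
#' @param grid_size Number of grid points (default 100).
#' @param dims Homology dimensions to report (default all up to the
#'   diagram's `max_hom_dim`).
#' @return A matrix with one row per requested dimension (rownames
#'   `"dim0"`...) and `grid_size` columns; attribute `grid` carries t.
#' @export
betti_curve <- function(diagram, grid_size = 100,
                        dims = 0:attr(diagram, "max_hom_dim")) {
  if (grid_size < 2) stop("grid_size must be at least 2", call. = FALSE)
  grid <- seq(0, 1, length.out = grid_size)
  out <- matrix(0L, length(dims), grid_size,
                dimnames = list(paste0("dim", dims), NULL))
  for (i in seq_along(dims)) {
    sub <- diagram[diagram$dimension == dims[i], , drop = FALSE]
    if (nrow(sub) == 0) next
    out[i, ] <- vapply(grid, function(t)
      sum(sub$birth <= t & t < sub$death), 0L)
  }
  attr(out, "grid") <- grid
  out
}

## ---- independent rank-based oracle -------------------------------------

# rank of a logical matrix over GF(2) by Gaussian elimination
gf2_rank <- function(M) {
  if (length(M) == 0 || nrow(M) == 0 || ncol(M) == 0) return(0L)
  M <- M != 0
  r <- 0L
  nr <- nrow(M)
  for (j in seq_len(ncol(M))) {
    piv <- which(M[, j])
    piv <- piv[piv > r]
    if (length(piv) == 0) next
    r <- r + 1L
    if (piv[1] != r) M[c(r, piv[1]), ] <- M[c(piv[1], r), ]
    hit <- which(M[, j])
    hit <- hit[hit != r]
    if (length(hit))
      M[hit, ] <- xor(M[hit, , drop = FALSE],
                      matrix(M[r, ], length(hit), ncol(M), byrow = TRUE))
    if (r == nr) break
  }
  r
}

# cliques of size k (as a k x m matrix of columns) among given vertices
threshold_cliques <- function(adj, k) {
  n <- nrow(adj)
  if (n < k) return(matrix(integer(0), k, 0))
  cmb <- combn(n, k)
  if (k == 1) return(cmb)
  keep <- apply(cmb, 2, function(v) {
    pr <- combn(v, 2)
    all(adj[cbind(pr[1, ], pr[2, ])])
  })
  cmb[, keep, drop = FALSE]
}

#' Brute-force Betti number at one threshold (independent oracle)
#'
#' Builds the full flag complex at threshold `t` (edges with dissimilarity
#' `<= t`) up to dimension `k + 1` and returns
#' `beta_k = n_k - rank(boundary_k) - rank(boundary_{k+1})`, with ranks
#' computed by Gaussian elimination over the two-element field. Entirely
#' independent of the reduction pipeline; intended for verification on small
#' networks.
#'
#' @param net An inverted-space [weighted_network()].
#' @param t Threshold in `[0, 1]`.
#' @param k Homology dimension (0, 1 or 2).
#' @return Integer Betti number.
#' @export
betti_bruteforce_oracle <- function(net, t, k) {
  n <- n_regions(net)
  if ((k >= 2 && n > 12) || (k < 2 && n > 20))
    stop("oracle size guard exceeded (N <= 12 for k = 2, N <= 20 for k <= 1)",
         call. = FALSE)
  adj <- net$weights <= t
  diag(adj) <- FALSE
  simplices <- lapply(1:(k + 2), function(sz) threshold_cliques(adj, sz))
  nk <- ncol(simplices[[k + 1]])
  # boundary_d maps d-simplices (columns) to (d-1)-simplices (rows)
  boundary_rank <- function(d) {
    cols <- simplices[[d + 1]]
    rows <- simplices[[d]]
    if (ncol(cols) == 0 || ncol(rows) == 0) return(0L)
    key <- function(m) apply(m, 2, paste, collapse = "-")
    row_idx <- stats::setNames(seq_len(ncol(rows)), key(rows))
    B <- matrix(FALSE, ncol(rows), ncol(cols))
    for (j in seq_len(ncol(cols))) {
      v <- cols[, j]
      for (drop in seq_along(v)) {
        face <- paste(v[-drop], collapse = "-")
        B[row_idx[[face]], j] <- TRUE
      }
    }
    gf2_rank(B)
  }
  rk <- if (k >= 1) boundary_rank(k) else 0L
  rk1 <- boundary_rank(k + 1)
  as.integer(nk - rk - rk1)
}

#' Euler characteristic of the truncated flag complex at a threshold
#'
#' Returns both sides of the Euler identity on the complex truncated at
#' dimension `max_dim`: the alternating sum of simplex counts and the
#' alternating sum of oracle Betti numbers (where the top dimension's
#' "Betti" is the count of top-dimensional cycles, `n_top - rank(boundary_top)`,
#' as no higher boundaries exist in the truncation).
#'
#' @param net Inverted-space network (small; oracle size guards apply).
#' @param t Threshold.
#' @param max_dim Truncation dimension (simplices of dims `0..max_dim`).
#' @return List with `simplex_side` and `betti_side`.
#' @export
euler_identity <- function(net, t, max_dim = 3) {
  adj <- net$weights <= t
  diag(adj) <- FALSE
  simplices <- lapply(1:(max_dim + 1), function(sz) threshold_cliques(adj, sz))
  counts <- vapply(simplices, ncol, 0L)
  simplex_side <- sum((-1)^(0:max_dim) * counts)
  ranks <- vapply(1:max_dim, function(d) {
    cols <- simplices[[d + 1]]
    rows <- simplices[[d]]
    if (ncol(cols) == 0 || ncol(rows) == 0) return(0L)
    key <- function(m) apply(m, 2, paste, collapse = "-")
    row_idx <- stats::setNames(seq_len(ncol(rows)), key(rows))
    B <- matrix(FALSE, ncol(rows), ncol(cols))
    for (j in seq_len(ncol(cols))) {
      v <- cols[, j]
      for (drop in seq_along(v)) {
        face <- paste(v[-drop], collapse = "-")
        B[row_idx[[face]], j] <- TRUE
      }
    }
    gf2_rank(B)
  }, 0L)
  # beta_d = n_d - rank(B_d) - rank(B_{d+1}); rank(B_0) = rank(B_{max+1}) = 0
  ranks_full <- c(0L, ranks, 0L)
  betti <- counts - ranks_full[1:(max_dim + 1)] - ranks_full[2:(max_dim + 2)]
  list(simplex_side = simplex_side,
       betti_side = sum((-1)^(0:max_dim) * betti),
       betti = betti, counts = counts)
}

#' Export Betti curves as CSV (one row per dimension)
#'
#' @param curves A [betti_curve()] matrix.
#' @param path Output path.
#' @export
write_betti_curves <- function(curves, path) {
  df <- data.frame(dim = rownames(curves), curves, check.names = FALSE)
  colnames(df) <- c("dim", sprintf("t%03d", seq_len(ncol(curves))))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
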