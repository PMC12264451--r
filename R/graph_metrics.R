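#' Binarize a weighted network at a target sparsity
#'
#' Keeps the `round(sparsity * P)` strongest edges by absolute weight
#' (P = n(n-1)/2 node pairs), sets them to 1 and all others to 0. Ties in
#' |weight| are broken by fixed lexicographic (i, j) order so the result is
#' deterministic.
#'
#' @param net An `individual_network` (or a bare symmetric matrix).
#' @param sparsity Fraction of retained edges, in (0, 1).
#' @return Object of class `binary_graph`: `adjacency` (0/1 symmetric, zero
#'   diagonal), `sparsity`, `n_edges`.
#' @export
threshold_by_sparsity <- function(net, sparsity) {
  W <- if (inherits(net, "individual_network")) net$W else as.matrix(net)
  if (sparsity <= 0 || sparsity >= 1) stop("sparsity must lie in (0, 1)")
  n <- nrow(W)
  ut <- which(upper.tri(W), arr.ind = TRUE)      # i < j
  ord <- order(-abs(W[ut]), ut[, 1], ut[, 2])
  k <- round(sparsity * nrow(ut))
  keep <- ut[ord[seq_len(k)], , drop = FALSE]
  A <- matrix(0L, n, n, dimnames = dimnames(W))
  A[keep] <- 1L
  A <- A + t(A)
  structure(list(adjacency = A, sparsity = sparsity, n_edges = k),
            class = "binary_graph")
}

as_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected",
                                      diag = FALSE)
}

#' Nodal degree centrality and clustering coefficient
#'
#' @param g A `binary_graph`.
#' @param nodes Integer node indices (default all).
#' @return data.frame with `node`, `dc` (degree), `ncf` (local clustering,
#'   0 for degree < 2).
#' @export
nodal_metrics <- function(g, nodes = seq_len(nrow(g$adjacency))) {
  A <- g$adjacency
  dc <- rowSums(A)[nodes]
  ncf <- vapply(nodes, function(i) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    sum(A[nb, nb]) / (k * (k - 1))   # 2*triangles / (k*(k-1))
  }, numeric(1))
  data.frame(node = nodes, dc = as.numeric(dc), ncf = ncf)
}

# Global efficiency of an adjacency matrix: mean over ordered pairs of
# 1/d(i,j), with 1/Inf = 0. Returns 0 for graphs with < 2 nodes.
adj_global_efficiency <- function(A) {
  n <- nrow(A)
  if (n < 2) return(0)
  ig <- igraph::graph_from_adjacency_matrix(A, mode = "undirected", diag = FALSE)
  d <- igraph::distances(ig)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Global graph metrics
#'
#' Characteristic path length is averaged over connected pairs only, so
#' low-sparsity disconnected graphs do not yield infinities; disconnected
#' pairs contribute 0 to global efficiency.
#'
#' @param g A `binary_graph`.
#' @return Named list: `c_mean` (mean local clustering), `l_char`
#'   (characteristic path length), `e_global`, `e_local`.
#' @export
global_metrics <- function(g) {
  A <- g$adjacency
  n <- nrow(A)
  ig <- as_igraph(g)
  d <- igraph::distances(ig)
  finite_off <- is.finite(d) & row(d) != col(d)
  l_char <- if (any(finite_off)) mean(d[finite_off]) else NA_real_
  inv <- 1 / d; diag(inv) <- 0; inv[!is.finite(inv)] <- 0
  e_global <- sum(inv) / (n * (n - 1))
  cc <- igraph::transitivity(ig, type = "local")
  cc[!is.finite(cc)] <- 0
  e_local <- mean(vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) return(0)
    adj_global_efficiency(A[nb, nb, drop = FALSE])
  }, numeric(1)))
  list(c_mean = mean(cc), l_char = l_char, e_global = e_global,
       e_local = e_local)
}

#' Degree-preserving random reference graph
#'
#' Randomizes the edge set by Maslov-Sneppen double-edge swaps while keeping
#' every node's degree fixed; used to normalize the small-world indices.
#'
#' @param g A `binary_graph`.
#' @param n_rewires Number of attempted swaps (default `10 * n_edges`).
#' @param seed Integer seed.
#' @return A `binary_graph` with the same degree sequence; carries attribute
#'   `rewire_warning = TRUE` if the graph had too few independent edge pairs
#'   to swap (returned unchanged).
#' @export
random_reference_graph <- function(g, n_rewires = 10 * g$n_edges, seed) {
  ig <- as_igraph(g)
  m <- igraph::ecount(ig)
  n <- nrow(g$adjacency)
  if (m < 2 || m == n * (n - 1) / 2) {
    out <- g
    attr(out, "rewire_warning") <- TRUE
    return(out)
  }
  rg <- with_seed(seed, igraph::rewire(ig, igraph::keeping_degseq(niter = n_rewires)))
  A <- as.matrix(igraph::as_adjacency_matrix(rg, sparse = FALSE))
  storage.mode(A) <- "integer"
  dimnames(A) <- dimnames(g$adjacency)
  structure(list(adjacency = A, sparsity = g$sparsity, n_edges = g$n_edges),
            class = "binary_graph")
}

# Clustering and path length only (what the random ensemble needs);
# accepts a binary_graph or a bare igraph object.
c_l_metrics <- function(g) {
  ig <- if (inherits(g, "igraph")) g else as_igraph(g)
  d <- igraph::distances(ig)
  finite_off <- is.finite(d) & row(d) != col(d)
  cc <- igraph::transitivity(ig, type = "local")
  cc[!is.finite(cc)] <- 0
  list(c_mean = mean(cc),
       l_char = if (any(finite_off)) mean(d[finite_off]) else NA_real_)
}

#' Small-world indices against a degree-matched random ensemble
#'
#' `gamma` is the clustering ratio, `lambda` the path-length ratio, and
#' `sigma = gamma / lambda`; the ensemble consists of `n_rand`
#' degree-preserving rewirings of `g`.
#'
#' @param g A `binary_graph`.
#' @param n_rand Ensemble size.
#' @param seed Integer seed.
#' @return Named list `gamma`, `lambda`, `sigma` (gamma/sigma are `NA` with
#'   a warning if the random ensemble has zero clustering).
#' @export
small_world_indices <- function(g, n_rand = 100, seed) {
  gm <- c_l_metrics(g)
  seeds <- split_seed(seed, n_rand)
  ig <- as_igraph(g)
  n <- nrow(g$adjacency)
  swappable <- g$n_edges >= 2 && g$n_edges < n * (n - 1) / 2
  rnd <- vapply(seq_len(n_rand), function(i) {
    rg <- if (swappable) {
      with_seed(seeds[i],
                igraph::rewire(ig, igraph::keeping_degseq(niter = 10 * g$n_edges)))
    } else ig
    rm <- c_l_metrics(rg)
    c(rm$c_mean, rm$l_char)
  }, numeric(2))
  c_rand <- mean(rnd[1, ])
  l_rand <- mean(rnd[2, ], na.rm = TRUE)
  lambda <- gm$l_char / l_rand
  if (c_rand <= 0) {
    warning("random ensemble has zero clustering; gamma undefined")
    return(list(gamma = NA_real_, lambda = lambda, sigma = NA_real_))
  }
  gamma <- gm$c_mean / c_rand
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda)
}

#' Default sparsity grid
#'
#' @return `seq(0.20, 0.65, by = 0.05)` (10 points).
#' @export
sparsity_grid <- function() seq(0.20, 0.65, by = 0.05)

# Normalized trapezoid aggregation of a metric across the sparsity grid:
# area under the metric-vs-sparsity curve divided by the grid span, so a
# constant metric aggregates to itself. A single grid point returns itself.
trapezoid_aggregate <- function(grid, y) {
  if (length(grid) == 1L) return(y)
  o <- order(grid)
  grid <- grid[o]; y <- y[o]
  area <- sum(diff(grid) * (head(y, -1) + tail(y, -1)) / 2)
  area / (max(grid) - min(grid))
}

#' Sparsity-aggregated graph feature profile of one network
#'
#' Evaluates all metrics at every grid sparsity, then reduces each
#' metric-vs-sparsity curve to one scalar by normalized trapezoid area (the
#' curve's average height). Returns the 9 features used downstream.
#'
#' @param net An `individual_network`.
#' @param grid Sparsity grid (default [sparsity_grid()]).
#' @param insula Named indices `c(aIns =, pIns =)`; default resolved from
#'   the network's labels.
#' @param n_rand Random references per grid point for the small-world
#'   normalization.
#' @param seed Integer seed.
#' @return Named numeric vector of length 9:
#'   `sigma, gamma, lambda, e_global, e_local, dc_aIns, dc_pIns, ncf_aIns,
#'   ncf_pIns`; attribute `"per_sparsity"` keeps the full metric-by-grid
#'   matrix for inspection.
#' @export
graph_feature_profile <- function(net, grid = sparsity_grid(),
                                  insula = insula_nodes(net$region_labels),
                                  n_rand = 100, seed) {
  stopifnot(length(grid) >= 1)
  seeds <- split_seed(seed, length(grid))
  per <- vapply(seq_along(grid), function(k) {
    g <- threshold_by_sparsity(net, grid[k])
    gm <- global_metrics(g)
    sw <- small_world_indices(g, n_rand = n_rand, seed = seeds[k])
    nm <- nodal_metrics(g, nodes = insula)
    c(sigma = sw$sigma, gamma = sw$gamma, lambda = sw$lambda,
      e_global = gm$e_global, e_local = gm$e_local,
      dc_aIns = nm$dc[1], dc_pIns = nm$dc[2],
      ncf_aIns = nm$ncf[1], ncf_pIns = nm$ncf[2])
  }, numeric(9))
  out <- apply(per, 1, function(y) trapezoid_aggregate(grid, y))
  attr(out, "per_sparsity") <- per
  out
}

#' Insula-only nodal features across the sparsity grid
#'
#' Fast path used by large simulation studies: skips the random-ensemble
#' small-world normalization and returns only the aggregated insular degree
#' and clustering features.
#'
#' @inheritParams graph_feature_profile
#' @return Named numeric vector `dc_aIns, dc_pIns, ncf_aIns, ncf_pIns`.
#' @export
insula_feature_profile <- function(net, grid = sparsity_grid(),
                                   insula = insula_nodes(net$region_labels)) {
  per <- vapply(grid, function(s) {
    g <- threshold_by_sparsity(net, s)
    nm <- nodal_metrics(g, nodes = insula)
    c(dc_aIns = nm$dc[1], dc_pIns = nm$dc[2],
      ncf_aIns = nm$ncf[1], ncf_pIns = nm$ncf[2])
  }, numeric(4))
  apply(per, 1, function(y) trapezoid_aggregate(grid, y))
}
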