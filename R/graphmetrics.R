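#' Weight-based graph density (plus standard connection density)
#'
#' The headline value is the mean of all off-diagonal weights multiplied by
#' the maximum weight of the network — the density definition used as the
#' covariate in the group statistics. The usual connection density (fraction
#' of nonzero off-diagonal entries) is attached as attribute
#' `"connection_density"` for diagnostics.
#'
#' @param net square weight matrix.
#' @return numeric density with attribute `connection_density`.
#' @export
graph_density <- function(net) {
  check_square_matrix(net)
  n <- nrow(net)
  off <- net[row(net) != col(net)]
  d <- if (length(off) && any(off != 0)) mean(off) * max(net) else 0
  structure(d, connection_density = if (length(off)) mean(off != 0) else 0)
}

#' Convert weights to lengths for shortest-path measures
#'
#' `length(i, j) = 1 / weight(i, j)` for positive weights, `Inf` otherwise:
#' strong connections are short.
#'
#' @param net square weight matrix (non-negative).
#' @return matrix of edge lengths.
#' @export
to_length_graph <- function(net) {
  check_square_matrix(net)
  if (any(net < 0)) stop_param("weights must be non-negative")
  out <- ifelse(net > 0, 1 / net, Inf)
  diag(out) <- 0
  out
}

graph_from_weights <- function(net) {
  g <- igraph::graph_from_adjacency_matrix(net, mode = "directed",
                                           weighted = TRUE, diag = FALSE)
  list(g = g, lengths = 1 / igraph::E(g)$weight)
}

distance_matrix <- function(net) {
  if (all(net[row(net) != col(net)] == 0)) {
    d <- matrix(Inf, nrow(net), ncol(net)); diag(d) <- 0
    return(d)
  }
  gw <- graph_from_weights(net)
  igraph::distances(gw$g, mode = "out", weights = gw$lengths)
}

#' Global efficiency
#'
#' Mean inverse weighted shortest-path distance over ordered node pairs;
#' unreachable pairs contribute zero. Distances are computed on the length
#' graph (`1 / weight`).
#'
#' @param net square weight matrix.
#' @return numeric global efficiency.
#' @export
global_efficiency <- function(net) {
  check_square_matrix(net)
  n <- nrow(net)
  if (n < 2) stop_param("need at least 2 nodes")
  d <- distance_matrix(net)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Characteristic path length
#'
#' Mean weighted shortest-path distance over ordered *reachable* node pairs;
#' unreachable pairs are excluded and their count attached as attribute
#' `"n_unreachable"`.
#'
#' @param net square weight matrix.
#' @return numeric CPL with attribute `n_unreachable`.
#' @export
characteristic_path_length <- function(net) {
  check_square_matrix(net)
  if (nrow(net) < 2) stop_param("need at least 2 nodes")
  d <- distance_matrix(net)
  off <- d[row(d) != col(d)]
  fin <- is.finite(off)
  if (!any(fin)) stop_param("no finite paths: graph has no edges")
  structure(mean(off[fin]), n_unreachable = sum(!fin))
}

# symmetrized weights (mean of the two directions), normalized to max 1,
# with the elementwise cube root used by the geometric-mean triangle rule.
clustering_parts <- function(net) {
  s <- (net + t(net)) / 2
  diag(s) <- 0
  mx <- max(s)
  if (mx == 0) return(NULL)
  w3 <- (s / mx)^(1 / 3)
  tri <- diag(w3 %*% w3 %*% w3)          # 2 x triangle intensity per node
  k <- rowSums(s > 0)
  list(tri = tri, denom = k * (k - 1))
}

#' Weighted transitivity
#'
#' Ratio of closed triplet intensity to all triplets, computed on the
#' symmetrized graph with the geometric-mean (Onnela) triangle weight; it
#' reduces to the classic closed/total triplet ratio on binary graphs.
#'
#' @param net square weight matrix.
#' @return numeric transitivity in \[0, 1\] for normalized weights.
#' @export
graph_transitivity <- function(net) {
  check_square_matrix(net)
  if (nrow(net) < 3) stop_param("need at least 3 nodes")
  cp <- clustering_parts(net)
  if (is.null(cp) || sum(cp$denom) == 0) return(0)
  sum(cp$tri) / sum(cp$denom)
}

#' Weighted local clustering coefficients
#'
#' Per node, the geometric-mean triangle intensity divided by
#' `degree * (degree - 1)` on the symmetrized graph; isolated and degree-1
#' nodes get 0.
#'
#' @param net square weight matrix.
#' @return numeric vector, one coefficient per node.
#' @export
local_clustering <- function(net) {
  check_square_matrix(net)
  cp <- clustering_parts(net)
  if (is.null(cp)) return(numeric(nrow(net)))
  out <- ifelse(cp$denom > 0, cp$tri / cp$denom, 0)
  names(out) <- rownames(net)
  out
}

#' Betweenness centrality on the weighted directed graph
#'
#' Fraction of weighted shortest paths passing through each node (Brandes
#' accumulation on the length graph). Returned raw, with the normalized
#' version (`raw / ((n-1)(n-2))`) as attribute `"normalized"`.
#'
#' @param net square weight matrix.
#' @return numeric vector of raw betweenness values with attribute
#'   `normalized`.
#' @export
betweenness_centrality <- function(net) {
  check_square_matrix(net)
  n <- nrow(net)
  if (n < 3) stop_param("need at least 3 nodes")
  if (all(net[row(net) != col(net)] == 0)) {
    raw <- numeric(n)
  } else {
    gw <- graph_from_weights(net)
    raw <- igraph::betweenness(gw$g, directed = TRUE, weights = gw$lengths)
  }
  names(raw) <- rownames(net)
  structure(raw, normalized = raw / ((n - 1) * (n - 2)))
}

#' Degree centrality
#'
#' Counts of nonzero incident edges per node.
#'
#' @param net square weight matrix.
#' @return data frame with `in_degree`, `out_degree` and `total`.
#' @export
degree_centrality <- function(net) {
  check_square_matrix(net)
  a <- net != 0
  diag(a) <- FALSE
  data.frame(node = rownames(net) %||% as.character(seq_len(nrow(net))),
             in_degree = colSums(a), out_degree = rowSums(a),
             total = colSums(a) + rowSums(a))
}

#' Degree-preserving randomization by directed double-edge swaps
#'
#' Repeatedly swaps the targets of two randomly chosen directed edges,
#' rejecting swaps that would create self-loops or duplicate edges, until
#' `swaps_per_edge * n_edges` attempts have been made. Weights travel with
#' their source edge, and both the in- and out-degree sequences are
#' preserved exactly. Attempt statistics are attached as attributes
#' (`swaps_done`, `attempts`).
#'
#' @param net square weight matrix.
#' @param swaps_per_edge attempted swaps per edge (reference setting 100).
#' @param seed integer seed.
#' @return rewired weight matrix.
#' @export
degree_preserving_randomize <- function(net, swaps_per_edge = 100,
                                        seed = 1L) {
  check_square_matrix(net)
  check_scalar(swaps_per_edge, "swaps_per_edge", lower = 1)
  check_scalar(seed, "seed", integerish = TRUE)
  n <- nrow(net)
  idx <- which(net != 0 & row(net) != col(net))
  if (length(idx) < 2)
    stop_param("need at least 2 edges to swap")
  edges <- cbind(((idx - 1L) %% n) + 1L, ((idx - 1L) %/% n) + 1L)
  set.seed(seed)
  new_edges <- cpp_edge_swap(edges, n, swaps_per_edge * length(idx))
  out <- matrix(0, n, n, dimnames = dimnames(net))
  out[cbind(new_edges[, 1], new_edges[, 2])] <- net[idx]
  attr(out, "swaps_done") <- attr(new_edges, "swaps_done")
  attr(out, "attempts") <- attr(new_edges, "attempts")
  out
}

#' Small-worldness sigma
#'
#' `sigma = (C / C_rand) / (L / L_rand)` with `C` the mean local clustering
#' coefficient, `L` the characteristic path length, and the null values
#' taken from degree-preserving randomizations of the network. One sigma is
#' computed against each random network and the values are averaged. A
#' network is conventionally called small-world when `sigma > 1`.
#'
#' @param net square weight matrix.
#' @param n_random number of null networks (reference setting 100).
#' @param swaps_per_edge swap attempts per edge in each null.
#' @param seed integer seed.
#' @return numeric sigma with attributes `c_ratio` (`C / mean(C_rand)`),
#'   `l_ratio` (`L / mean(L_rand)`), and `per_null` (the individual sigmas).
#' @export
small_worldness_sigma <- function(net, n_random = 100, swaps_per_edge = 100,
                                  seed = 1L) {
  check_square_matrix(net)
  check_scalar(n_random, "n_random", lower = 1, integerish = TRUE)
  C <- mean(local_clustering(net))
  L <- as.numeric(characteristic_path_length(net))
  cr <- lr <- numeric(n_random)
  for (k in seq_len(n_random)) {
    rnet <- degree_preserving_randomize(net, swaps_per_edge,
                                        seed = derive_seed(seed, k))
    cr[k] <- mean(local_clustering(rnet))
    lr[k] <- as.numeric(characteristic_path_length(rnet))
  }
  if (any(cr == 0) || any(!is.finite(lr)) || any(lr == 0))
    stop_param(paste0("degenerate null networks: %d with zero clustering, ",
                      "%d with undefined path length"),
               sum(cr == 0), sum(!is.finite(lr) | lr == 0))
  per_null <- (C / cr) / (L / lr)
  structure(mean(per_null), c_ratio = C / mean(cr), l_ratio = L / mean(lr),
            per_null = per_null)
}

#' All global and local graph measures for one network
#'
#' Convenience wrapper used by the pipeline: density, global efficiency,
#' transitivity, characteristic path length, local clustering, betweenness
#' and degrees, optionally small-worldness sigma (expensive).
#'
#' @param net square weight matrix.
#' @param include_sigma compute [small_worldness_sigma()] too.
#' @param n_random,swaps_per_edge,seed passed to the sigma computation.
#' @return list of class `graph_metrics`.
#' @export
graph_metrics <- function(net, include_sigma = FALSE, n_random = 100,
                          swaps_per_edge = 100, seed = 1L) {
  check_square_matrix(net)
  dens <- graph_density(net)
  # a fully pruned (edgeless) network has no finite paths; report NA rather
  # than aborting a whole cohort run
  cpl <- tryCatch(characteristic_path_length(net), error = function(e)
    structure(NA_real_, n_unreachable = nrow(net) * (nrow(net) - 1)))
  out <- list(
    density = as.numeric(dens),
    connection_density = attr(dens, "connection_density"),
    global_efficiency = global_efficiency(net),
    transitivity = graph_transitivity(net),
    characteristic_path_length = as.numeric(cpl),
    n_unreachable = attr(cpl, "n_unreachable"),
    clustering = local_clustering(net),
    betweenness = betweenness_centrality(net),
    degree = degree_centrality(net))
  if (include_sigma)
    out$sigma <- small_worldness_sigma(net, n_random, swaps_per_edge, seed)
  class(out) <- "graph_metrics"
  out
}

#' @export
print.graph_metrics <- function(x, ...) {
  cat(sprintf(
    "<graph_metrics> density %.4g, GE %.4g, TS %.4g, CPL %.4g%s\n",
    x$density, x$global_efficiency, x$transitivity,
    x$characteristic_path_length,
    if (!is.null(x$sigma)) sprintf(", sigma %.4g", as.numeric(x$sigma))
    else ""))
  invisible(x)
}
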