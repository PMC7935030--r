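sym_graph <- function(net) {
  s <- (net + t(net)) / 2
  diag(s) <- 0
  igraph::graph_from_adjacency_matrix(s, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Repeated single-level Louvain community detection
#'
#' Runs the Louvain modularity optimizer `n_iterations` times on the
#' symmetrized weighted graph, each run under a random node order, and
#' returns every partition with its modularity. Resolution is fixed at 1;
#' multiscale structure is obtained by recursion
#' ([multiscale_communities()]), not resolution sweeps.
#'
#' @param net square weight matrix (n >= 2).
#' @param n_iterations number of independent runs (reference setting 100).
#' @param seed integer seed.
#' @return list of runs, each a list with `membership` (integer vector) and
#'   `modularity`.
#' @export
louvain_single_level <- function(net, n_iterations = 100, seed = 1L) {
  check_square_matrix(net)
  n <- nrow(net)
  if (n < 2) stop_param("need at least 2 nodes")
  check_scalar(n_iterations, "n_iterations", lower = 1, integerish = TRUE)
  check_scalar(seed, "seed", integerish = TRUE)
  set.seed(seed)
  g_full <- sym_graph(net)
  w_full <- igraph::E(g_full)$weight
  lapply(seq_len(n_iterations), function(run) {
    perm <- sample.int(n)                  # random node order for this run
    gp <- sym_graph(net[perm, perm, drop = FALSE])
    cl <- igraph::cluster_louvain(gp, weights = igraph::E(gp)$weight)
    memb <- integer(n)
    memb[perm] <- igraph::membership(cl)
    memb <- match(memb, unique(memb))      # canonical labels
    list(membership = memb,
         modularity = igraph::modularity(g_full, memb, weights = w_full))
  })
}

#' Normalized mutual information between two partitions
#'
#' `NMI = 2 I(p1; p2) / (H(p1) + H(p2))`, in \[0, 1\]. When both partitions
#' are single-community (both entropies zero) the partitions are identical
#' and NMI is defined as 1; when exactly one has zero entropy it is 0.
#'
#' @param p1,p2 community membership vectors over the same node set.
#' @return numeric NMI.
#' @export
normalized_mutual_information <- function(p1, p2) {
  if (length(p1) != length(p2))
    stop_param("partitions must cover the same node set")
  n <- length(p1)
  tab <- table(p1, p2)
  pij <- tab / n
  pi_ <- rowSums(pij)
  pj_ <- colSums(pij)
  h1 <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
  h2 <- -sum(pj_[pj_ > 0] * log(pj_[pj_ > 0]))
  if (h1 == 0 && h2 == 0) return(1)
  if (h1 == 0 || h2 == 0) return(0)
  mi <- 0
  for (i in seq_along(pi_)) for (j in seq_along(pj_)) {
    if (pij[i, j] > 0)
      mi <- mi + pij[i, j] * log(pij[i, j] / (pi_[i] * pj_[j]))
  }
  as.numeric(2 * mi / (h1 + h2))
}

#' Representative partition of a set of Louvain runs
#'
#' Returns the member partition maximizing the mean NMI to all other
#' members; ties are broken by higher modularity, then by fewer
#' communities, then by run order.
#'
#' @param runs output of [louvain_single_level()] (or a list of lists with
#'   `membership` and optionally `modularity`).
#' @return the chosen run's membership vector, with attributes `index`,
#'   `modularity` and `mean_nmi`.
#' @export
representative_partition <- function(runs) {
  if (!length(runs)) stop_param("no partitions supplied")
  memb <- lapply(runs, `[[`, "membership")
  mods <- vapply(runs, function(r) r$modularity %||% NA_real_, numeric(1))
  m <- length(memb)
  if (m == 1)
    return(structure(memb[[1]], index = 1L, modularity = mods[1],
                     mean_nmi = 1))
  nmi <- matrix(1, m, m)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    nmi[i, j] <- nmi[j, i] <-
      normalized_mutual_information(memb[[i]], memb[[j]])
  }
  mean_nmi <- (rowSums(nmi) - 1) / (m - 1)
  ncomm <- vapply(memb, function(p) length(unique(p)), integer(1))
  ord <- order(-mean_nmi, -ifelse(is.na(mods), -Inf, mods), ncomm)
  best <- ord[1]
  structure(memb[[best]], index = best, modularity = mods[best],
            mean_nmi = mean_nmi[best])
}

#' Multiscale hierarchical community detection
#'
#' Applies Louvain recursively: level 1 is the representative partition of
#' the whole graph (over `n_iterations` runs, selected by NMI); each
#' community's induced subgraph is then re-clustered, and so on. Recursion
#' stops when a subgraph yields a single community or has fewer than 3
#' nodes. Nodes whose community does not subdivide carry it forward, so
#' each level's communities nest within the previous level's.
#'
#' @param net square weight matrix.
#' @param n_iterations Louvain runs per (sub)graph.
#' @param seed integer seed.
#' @return object of class `hierarchical_partition`: `levels` (list of
#'   membership vectors, level 1 coarsest), `n_communities`, `modularity`
#'   per level (on the full graph), and `paths` (community path label per
#'   node, e.g. `"2.3.1"`).
#' @export
multiscale_communities <- function(net, n_iterations = 100, seed = 1L) {
  check_square_matrix(net)
  n <- nrow(net)
  if (n < 2) stop_param("need at least 2 nodes")
  paths <- rep("", n)

  recurse <- function(idx, prefix) {
    if (length(idx) < 3) {
      paths[idx] <<- prefix
      return(invisible(NULL))
    }
    sub <- net[idx, idx, drop = FALSE]
    runs <- louvain_single_level(sub, n_iterations,
                                 seed = derive_seed(seed, length(idx),
                                                    idx[1]))
    memb <- representative_partition(runs)
    k <- length(unique(memb))
    if (k == 1) {
      paths[idx] <<- prefix
      return(invisible(NULL))
    }
    for (c in seq_len(k)) {
      sel <- idx[memb == c]
      child <- if (nzchar(prefix)) paste0(prefix, ".", c) else as.character(c)
      paths[sel] <<- child
      recurse(sel, child)
    }
  }
  recurse(seq_len(n), "")
  if (all(!nzchar(paths))) paths <- rep("1", n)

  depth <- max(lengths(strsplit(paths, ".", fixed = TRUE)))
  g <- sym_graph(net)
  w <- igraph::E(g)$weight
  levels <- lapply(seq_len(depth), function(l) {
    lab <- vapply(strsplit(paths, ".", fixed = TRUE), function(parts)
      paste(head(parts, min(l, length(parts))), collapse = "."),
      character(1))
    match(lab, unique(lab))
  })
  structure(list(
    levels = levels,
    n_communities = vapply(levels, function(m) length(unique(m)),
                           integer(1)),
    modularity = vapply(levels, function(m)
      igraph::modularity(g, m, weights = w), numeric(1)),
    paths = paths),
    class = "hierarchical_partition")
}

#' @export
print.hierarchical_partition <- function(x, ...) {
  cat(sprintf("<hierarchical_partition> %d level%s; communities per level: %s\n",
              length(x$levels), if (length(x$levels) == 1) "" else "s",
              paste(x$n_communities, collapse = ", ")))
  invisible(x)
}
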