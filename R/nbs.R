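#' Edgewise paired t statistics between two network conditions
#'
#' For each directed edge, computes the paired t statistic of post minus pre
#' across subjects: `t = mean(d) / (sd(d) / sqrt(n))`. Edges with zero
#' difference variance (including the diagonal) get `t = 0`; their count is
#' reported via a message.
#'
#' @param pre,post lists of equally shaped weight matrices, one per subject,
#'   in matching subject order (>= 2 subjects).
#' @param quiet suppress the zero-variance note.
#' @return matrix of t statistics with the networks' dimnames.
#' @export
edgewise_paired_t <- function(pre, post, quiet = FALSE) {
  D <- paired_differences(pre, post)
  n <- nrow(D)
  m <- colMeans(D)
  v <- (colSums(D^2) - n * m^2) / (n - 1)
  v[v < 0] <- 0
  t <- ifelse(v > 0, m / sqrt(v / n), 0)
  nzv <- sum(v == 0) - nrow(pre[[1]])      # diagonal is always zero-variance
  if (!quiet && nzv > 0)
    message(sprintf("%d off-diagonal edges had zero variance; t set to 0",
                    nzv))
  out <- matrix(t, nrow(pre[[1]]), ncol(pre[[1]]))
  dimnames(out) <- dimnames(pre[[1]])
  out
}

# subjects x edges difference matrix (column-major edge order)
paired_differences <- function(pre, post) {
  if (length(pre) != length(post) || length(pre) < 2)
    stop_param("need >= 2 subjects with matching pre/post networks")
  dims <- lapply(c(pre, post), dim)
  if (length(unique(dims)) != 1)
    stop_param("all networks must share the same shape")
  t(vapply(seq_along(pre), function(s) as.numeric(post[[s]] - pre[[s]]),
           numeric(length(pre[[1]]))))
}

# union-find over the undirected support of an edge index set; returns the
# root of each edge's component.
edge_component_roots <- function(ei, ej, n) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_along(ei)) {
    ri <- find(ei[k]); rj <- find(ej[k])
    if (ri != rj) parent[rj] <- ri
  }
  vapply(ei, find, integer(1))
}

max_component_edges <- function(ei, ej, n) {
  if (!length(ei)) return(0L)
  if (length(ei) == 1L) return(1L)
  roots <- edge_component_roots(ei, ej, n)
  max(tabulate(match(roots, unique(roots))))
}

tail_pass <- function(t, threshold, tail) {
  switch(tail,
         positive = t > threshold,
         negative = t < -threshold,
         two_sided = abs(t) > threshold)
}

#' Connected components of the suprathreshold graph
#'
#' Binarizes edges whose t statistic passes the tailed threshold and finds
#' connected components, treating the suprathreshold edge set as undirected
#' for connectivity while reporting the directed edges. Component size is
#' the number of suprathreshold (directed) edges.
#'
#' @param tmat edgewise t-statistic matrix.
#' @param t_threshold positive threshold.
#' @param tail `"positive"` (post > pre), `"negative"`, or `"two_sided"`.
#' @return list of components, each a list with `edges` (two-column index
#'   matrix), `nodes`, `n_edges`, `n_nodes`; ordered by decreasing size.
#' @export
suprathreshold_components <- function(tmat, t_threshold,
                                      tail = c("positive", "negative",
                                               "two_sided")) {
  check_square_matrix(tmat, "tmat")
  check_scalar(t_threshold, "t_threshold", lower = 1e-12)
  tail <- match.arg(tail)
  n <- nrow(tmat)
  pass <- tail_pass(tmat, t_threshold, tail)
  diag(pass) <- FALSE
  idx <- which(pass)
  if (!length(idx)) return(list())
  ei <- ((idx - 1L) %% n) + 1L
  ej <- ((idx - 1L) %/% n) + 1L
  roots <- edge_component_roots(ei, ej, n)
  comps <- lapply(unique(roots), function(r) {
    sel <- roots == r
    edges <- cbind(from = ei[sel], to = ej[sel])
    list(edges = edges, nodes = sort(unique(c(edges))),
         n_edges = sum(sel), n_nodes = length(unique(c(edges))))
  })
  comps[order(vapply(comps, `[[`, integer(1), "n_edges"),
              decreasing = TRUE)]
}

#' Network-based statistics by paired max-component permutation
#'
#' Tests whether any connected set of edges strengthens (or weakens)
#' between paired conditions. The observed suprathreshold components are
#' compared against a permutation null of maximal component size, obtained
#' by independently exchanging each subject's pre/post labels (sign flips of
#' the paired differences), recomputing the t statistics, thresholding, and
#' recording the largest component. Corrected
#' `p = (1 + #\{perm max >= observed size\}) / (1 + n_permutations)`.
#'
#' @param pre,post lists of weight matrices, one per subject.
#' @param t_threshold primary edge threshold on the paired t statistic.
#' @param n_permutations permutation count (reference setting 5,000).
#' @param seed integer seed for the permutation draws.
#' @param tail `"positive"`, `"negative"`, or `"two_sided"`.
#' @return object of class `nbs_result`: `t`, `components`, `p`,
#'   `null_max_size`, and `params`.
#' @export
nbs_permutation_test <- function(pre, post, t_threshold = 3,
                                 n_permutations = 5000, seed = 1L,
                                 tail = c("positive", "negative",
                                          "two_sided")) {
  tail <- match.arg(tail)
  check_scalar(t_threshold, "t_threshold", lower = 1e-12)
  check_scalar(n_permutations, "n_permutations", lower = 100,
               integerish = TRUE)
  check_scalar(seed, "seed", integerish = TRUE)

  D <- paired_differences(pre, post)
  n_sub <- nrow(D)
  n <- nrow(pre[[1]])
  tmat <- edgewise_paired_t(pre, post, quiet = TRUE)
  comps <- suprathreshold_components(tmat, t_threshold, tail)

  SS <- colSums(D^2)
  set.seed(seed)
  null_max <- integer(n_permutations)
  block <- 500L
  done <- 0L
  while (done < n_permutations) {
    nb <- min(block, n_permutations - done)
    S <- matrix(sample(c(-1, 1), nb * n_sub, replace = TRUE), nb, n_sub)
    M <- (S %*% D) / n_sub
    V <- (rep(1, nb) %o% SS - n_sub * M^2) / (n_sub - 1)
    V[V < 0] <- 0
    Tm <- ifelse(V > 0, M / sqrt(V / n_sub), 0)
    pass <- tail_pass(Tm, t_threshold, tail)
    for (b in seq_len(nb)) {
      idx <- which(pass[b, ])
      idx <- idx[((idx - 1L) %% n) != ((idx - 1L) %/% n)]  # drop diagonal
      null_max[done + b] <- max_component_edges(
        ((idx - 1L) %% n) + 1L, ((idx - 1L) %/% n) + 1L, n)
    }
    done <- done + nb
  }

  p <- vapply(comps, function(cp)
    (1 + sum(null_max >= cp$n_edges)) / (1 + n_permutations), numeric(1))
  structure(list(t = tmat, components = comps, p = p,
                 null_max_size = null_max,
                 params = list(t_threshold = t_threshold,
                               n_permutations = n_permutations,
                               seed = seed, tail = tail,
                               n_subjects = n_sub)),
            class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf(
    "<nbs_result> paired NBS, %d subjects, t-threshold %g, %d permutations (%s tail)\n",
    x$params$n_subjects, x$params$t_threshold, x$params$n_permutations,
    x$params$tail))
  if (!length(x$components)) {
    cat("no suprathreshold components\n")
  } else {
    for (k in seq_along(x$components)) {
      cp <- x$components[[k]]
      cat(sprintf("  component %d: %d edges, %d nodes, corrected p = %.4g\n",
                  k, cp$n_edges, cp$n_nodes, x$p[k]))
    }
  }
  invisible(x)
}

#' Tabulate an NBS result
#'
#' @param object an `nbs_result`.
#' @param ... unused.
#' @return data frame with one row per component (id, n_edges, n_nodes, p).
#' @export
summary.nbs_result <- function(object, ...) {
  if (!length(object$components))
    return(data.frame(id = integer(), n_edges = integer(),
                      n_nodes = integer(), p = numeric()))
  data.frame(
    id = seq_along(object$components),
    n_edges = vapply(object$components, `[[`, integer(1), "n_edges"),
    n_nodes = vapply(object$components, `[[`, integer(1), "n_nodes"),
    p = object$p)
}
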