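# Independent brute-force oracles used to validate the package's metrics.
# These are deliberately naive (enumeration, direct summation) and share no
# code with the implementations they check.

# all-pairs shortest-path distances on the 1/weight length graph,
# Floyd-Warshall
fw_distances <- function(net) {
  n <- nrow(net)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && net[i, j] > 0) d[i, j] <- 1 / net[i, j]
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_global_efficiency <- function(net) {
  d <- fw_distances(net)
  n <- nrow(net)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && is.finite(d[i, j])) s <- s + 1 / d[i, j]
  s / (n * (n - 1))
}

oracle_cpl <- function(net) {
  d <- fw_distances(net)
  off <- d[row(d) != col(d)]
  mean(off[is.finite(off)])
}

# enumerate all simple paths to count shortest paths through each node
oracle_betweenness <- function(net, tol = 1e-9) {
  n <- nrow(net)
  len <- ifelse(net > 0, 1 / net, Inf)
  bc <- numeric(n)
  paths_between <- function(s, t) {
    out <- list()
    walk <- function(path, total) {
      last <- path[length(path)]
      if (last == t) {
        out[[length(out) + 1]] <<- list(path = path, len = total)
        return(invisible(NULL))
      }
      for (v in seq_len(n)) {
        if (!(v %in% path) && is.finite(len[last, v]))
          walk(c(path, v), total + len[last, v])
      }
    }
    walk(s, 0)
    out
  }
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t) next
    ps <- paths_between(s, t)
    if (!length(ps)) next
    lens <- vapply(ps, `[[`, numeric(1), "len")
    dmin <- min(lens)
    short <- ps[lens <= dmin + tol]
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      thru <- sum(vapply(short, function(p) v %in% p$path, logical(1)))
      bc[v] <- bc[v] + thru / length(short)
    }
  }
  bc
}

# geometric-mean weighted clustering / transitivity by direct triple loops
oracle_clustering <- function(net) {
  s <- (net + t(net)) / 2
  diag(s) <- 0
  n <- nrow(s)
  if (max(s) == 0) return(numeric(n))
  w <- s / max(s)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    tri <- 0
    for (j in seq_len(n)) for (k in seq_len(n)) {
      if (j != i && k != i && j != k)
        tri <- tri + (w[i, j] * w[i, k] * w[j, k])^(1 / 3)
    }
    deg <- sum(s[i, ] > 0)
    cc[i] <- if (deg > 1) tri / (deg * (deg - 1)) else 0
  }
  cc
}

oracle_transitivity <- function(net) {
  s <- (net + t(net)) / 2
  diag(s) <- 0
  if (max(s) == 0) return(0)
  w <- s / max(s)
  n <- nrow(s)
  num <- 0
  den <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) for (k in seq_len(n)) {
      if (j != i && k != i && j != k)
        num <- num + (w[i, j] * w[i, k] * w[j, k])^(1 / 3)
    }
    deg <- sum(s[i, ] > 0)
    den <- den + deg * (deg - 1)
  }
  if (den == 0) 0 else num / den
}

# transfer entropy straight from the defining conditional probabilities
oracle_te <- function(bx, by, B, d) {
  m <- length(by) - d
  yf <- by[(1 + d):(m + d)]
  yp <- by[1:m]
  xp <- bx[1:m]
  te <- 0
  for (a in 1:B) for (b in 1:B) for (c in 1:B) {
    n3 <- sum(yf == a & yp == b & xp == c)
    if (n3 == 0) next
    n_yx <- sum(yp == b & xp == c)
    n_fy <- sum(yf == a & yp == b)
    n_y <- sum(yp == b)
    te <- te + (n3 / m) * log((n3 / n_yx) / (n_fy / n_y))
  }
  te
}

bin_phase_vec <- function(p, B) {
  b <- floor((p + pi) / (2 * pi) * B)
  pmin(pmax(b, 0), B - 1) + 1
}

# Benjamini-Hochberg by exhaustive search over step-up cutoffs
oracle_bh_mask <- function(p, q) {
  n <- length(p)
  ord <- order(p)
  ps <- p[ord]
  kmax <- 0
  for (k in seq_len(n)) if (ps[k] <= k / n * q) kmax <- k
  mask <- rep(FALSE, n)
  if (kmax > 0) mask[ord[seq_len(kmax)]] <- TRUE
  mask
}

# circular (phase) correlation at a given shift of x relative to y
circular_corr <- function(phx, phy, shift) {
  n <- length(phx)
  if (shift > 0) {
    x <- phx[1:(n - shift)]
    y <- phy[(1 + shift):n]
  } else {
    x <- phx[(1 - shift):n]
    y <- phy[1:(n + shift)]
  }
  sx <- sin(x - mean.circular(x))
  sy <- sin(y - mean.circular(y))
  sum(sx * sy) / sqrt(sum(sx^2) * sum(sy^2))
}

mean.circular <- function(p) atan2(mean(sin(p)), mean(cos(p)))

# direct-summation cross-correlation over all lags
max_abs_crosscorr <- function(x, y, max_lag = 50) {
  x <- (x - mean(x)) / sd(x)
  y <- (y - mean(y)) / sd(y)
  n <- length(x)
  worst <- 0
  for (l in -max_lag:max_lag) {
    if (l >= 0) v <- sum(x[1:(n - l)] * y[(1 + l):n]) / (n - l)
    else v <- sum(x[(1 - l):n] * y[1:(n + l)]) / (n + l)
    worst <- max(worst, abs(v))
  }
  worst
}

band_noise <- function(n, seed, fs = 256, band = c(0.53, 35)) {
  set.seed(seed)
  ptenet:::band_limit_fft(rnorm(n), fs, band)
}

# small fixtures
toy_path_graph <- function() {
  a <- matrix(0, 3, 3)
  a[1, 2] <- a[2, 1] <- a[2, 3] <- a[3, 2] <- 1
  a
}

complete_graph <- function(n) {
  a <- matrix(1, n, n)
  diag(a) <- 0
  a
}

random_digraph <- function(n, seed, p = 0.6) {
  set.seed(seed)
  a <- matrix(runif(n * n), n, n) * (matrix(runif(n * n), n, n) < p)
  diag(a) <- 0
  a
}
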