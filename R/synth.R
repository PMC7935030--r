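#' Describe a set of coupled band-limited oscillatory sources
#'
#' A source model specifies `n_nodes` oscillators whose content is confined
#' to a frequency band, an optional set of directed, lagged phase couplings
#' between them, and additive white measurement noise. It is the ground-truth
#' object from which synthetic recordings are generated.
#'
#' Couplings are given as a data frame with columns `from`, `to` (1-based
#' node indices), `lag` (samples, >= 1) and `strength` (mixing proportion in
#' \[0, 1\]): the target node's instantaneous phase is pulled toward the
#' source node's phase delayed by `lag`, with weight `strength`.
#'
#' @param n_nodes number of sources (>= 1).
#' @param fs sampling rate in Hz.
#' @param band numeric length-2, oscillatory band (Hz); must lie in
#'   (0, fs/2).
#' @param couplings data frame (`from`, `to`, `lag`, `strength`) or `NULL`
#'   for independent sources. Self-couplings are rejected.
#' @param noise_sd standard deviation of additive white noise (signals are
#'   scaled to unit variance before noise is added).
#' @param seed integer seed; all randomness in the generator flows from it.
#' @return an object of class `source_model`.
#' @export
source_model <- function(n_nodes, fs = 256, band = c(0.53, 35),
                         couplings = NULL, noise_sd = 0.5, seed = 1L) {
  check_scalar(n_nodes, "n_nodes", lower = 1, integerish = TRUE)
  check_scalar(fs, "fs", lower = 1e-12)
  if (!is.numeric(band) || length(band) != 2L)
    stop_param("`band` must be numeric of length 2")
  if (band[1] <= 0 || band[2] >= fs / 2 || band[1] >= band[2])
    stop_param("`band` must satisfy 0 < low < high < fs/2")
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(seed, "seed", integerish = TRUE)
  if (is.null(couplings)) {
    couplings <- data.frame(from = integer(), to = integer(),
                            lag = integer(), strength = numeric())
  }
  couplings <- as.data.frame(couplings)
  need <- c("from", "to", "lag", "strength")
  if (!all(need %in% names(couplings)))
    stop_param("`couplings` needs columns from, to, lag, strength")
  if (nrow(couplings)) {
    if (any(couplings$from == couplings$to))
      stop_param("self-couplings are not allowed")
    if (any(couplings$from < 1 | couplings$from > n_nodes |
            couplings$to < 1 | couplings$to > n_nodes))
      stop_param("coupling endpoints must be node indices in 1..n_nodes")
    if (any(couplings$lag < 1 | couplings$lag != round(couplings$lag)))
      stop_param("coupling `lag` must be an integer >= 1")
    if (any(couplings$strength < 0 | couplings$strength > 1))
      stop_param("coupling `strength` must lie in [0, 1]")
    tot <- tapply(couplings$strength, couplings$to, sum)
    if (any(tot > 1 + 1e-12))
      stop_param(paste0("total incoming coupling strength exceeds 1 for ",
                        "node %s; the phase mixture is only identified up ",
                        "to total weight 1"),
                 names(tot)[which.max(tot)])
  }
  structure(list(n_nodes = as.integer(n_nodes), fs = fs, band = band,
                 couplings = couplings, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "source_model")
}

# Ideal band-limitation by FFT masking: keeps exactly the bins whose
# frequency falls inside [low, high]. Used for generation only (the
# preprocessing module uses IIR filters, as an acquisition pipeline would).
band_limit_fft <- function(x, fs, band) {
  n <- length(x)
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)                      # two-sided frequency axis
  keep <- f >= band[1] & f <= band[2]
  Re(fft(fft(x) * keep, inverse = TRUE)) / n
}

analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

#' Generate one multichannel recording from a source model
#'
#' Each node starts as unit-variance band-limited Gaussian noise. For every
#' coupling (i -> j, lag, strength s) the target's instantaneous phase is
#' replaced by the argument of the circular mixture
#' `(1 - S) exp(i phi_j) + s exp(i phi_i(t - lag))` (summed over j's
#' incoming couplings, S = total incoming strength), so the planted effect
#' lives in exactly the quantity phase transfer entropy measures. The mixed
#' signal keeps the target's own amplitude envelope, is re-band-limited, and
#' white noise of `noise_sd` is added.
#'
#' Coupling sources contribute their *uncoupled* base phase, so chains
#' A -> B -> C plant both pairwise effects without feedback ambiguity.
#' Lagged phases are circularly shifted (the sources are stationary noise).
#'
#' @param model a [source_model()].
#' @param duration_s recording length in seconds; `duration_s * fs` must be
#'   at least twice the largest coupling lag.
#' @return a `recording`: list with `data` (n_nodes x n_samples matrix),
#'   `fs`, and `labels`.
#' @export
generate_coupled_timeseries <- function(model, duration_s) {
  stopifnot(inherits(model, "source_model"))
  check_scalar(duration_s, "duration_s", lower = 1e-12)
  n_samp <- round(duration_s * model$fs)
  max_lag <- if (nrow(model$couplings)) max(model$couplings$lag) else 0L
  if (n_samp < 2 * max_lag || n_samp < 2)
    stop_param("duration too short: %d samples for max lag %d",
               n_samp, max_lag)

  set.seed(model$seed)
  n <- model$n_nodes
  base <- matrix(rnorm(n * n_samp), nrow = n)
  for (k in seq_len(n)) {
    b <- band_limit_fft(base[k, ], model$fs, model$band)
    base[k, ] <- b / sd(b)
  }
  base_phase <- matrix(0, n, n_samp)
  base_env <- matrix(0, n, n_samp)
  for (k in seq_len(n)) {
    a <- analytic_signal(base[k, ])
    base_phase[k, ] <- Arg(a)
    base_env[k, ] <- Mod(a)
  }

  out <- base
  cpl <- model$couplings
  for (j in unique(cpl$to)) {
    rows <- cpl[cpl$to == j, , drop = FALSE]
    s_tot <- sum(rows$strength)
    w_own <- max(1 - s_tot, 0)
    mix <- w_own * exp(1i * base_phase[j, ])
    for (r in seq_len(nrow(rows))) {
      src <- rows$from[r]
      lag <- rows$lag[r]
      shifted <- c(tail(base_phase[src, ], lag),
                   head(base_phase[src, ], n_samp - lag))
      mix <- mix + rows$strength[r] * exp(1i * shifted)
    }
    sig <- base_env[j, ] * cos(Arg(mix))
    sig <- band_limit_fft(sig, model$fs, model$band)
    out[j, ] <- sig / sd(sig)
  }

  if (model$noise_sd > 0)
    out <- out + matrix(rnorm(n * n_samp, sd = model$noise_sd), nrow = n)
  recording(out, model$fs, labels = paste0("node", seq_len(n)))
}

#' Construct a recording object
#'
#' @param data numeric matrix, nodes x samples.
#' @param fs sampling rate (Hz).
#' @param labels node labels (defaults to `node1..nodeN`).
#' @return list of class `recording`.
#' @export
recording <- function(data, fs, labels = NULL) {
  if (!is.matrix(data) || !is.numeric(data))
    stop_param("`data` must be a numeric matrix (nodes x samples)")
  check_scalar(fs, "fs", lower = 1e-12)
  if (is.null(labels)) labels <- paste0("node", seq_len(nrow(data)))
  if (length(labels) != nrow(data))
    stop_param("`labels` must have one entry per node")
  structure(list(data = data, fs = fs, labels = as.character(labels)),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d nodes x %d samples @ %g Hz\n",
              nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}

#' Describe a paired pre/post cohort with a planted session effect
#'
#' Each subject receives its own coupling strengths, drawn from a truncated
#' normal around the base model's strengths (`jitter_sd`), shared between
#' that subject's pre and post recordings. Post recordings additionally
#' strengthen the `planted` edges by `delta` (clipped to \[0, 1\] with a
#' warning), emulating a paired intervention design.
#'
#' @param n_subjects number of subjects (>= 2; paired tests need pairs).
#' @param model base [source_model()].
#' @param planted data frame (`from`, `to`, `lag`) of directed edges whose
#'   strength increases pre -> post; edges absent from the base couplings
#'   enter the post model with strength `delta`. `lag` defaults to 4.
#' @param delta pre -> post strength increment.
#' @param jitter_sd sd of the between-subject strength jitter.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 12, model, planted = NULL, delta = 0.4,
                        jitter_sd = 0.05) {
  check_scalar(n_subjects, "n_subjects", lower = 2, integerish = TRUE)
  stopifnot(inherits(model, "source_model"))
  check_scalar(delta, "delta", lower = 0, upper = 1)
  check_scalar(jitter_sd, "jitter_sd", lower = 0)
  if (is.null(planted)) {
    planted <- data.frame(from = integer(), to = integer(), lag = integer())
  }
  planted <- as.data.frame(planted)
  if (!all(c("from", "to") %in% names(planted)))
    stop_param("`planted` needs columns from, to")
  if (is.null(planted$lag)) planted$lag <- rep(4L, nrow(planted))
  if (nrow(planted) && any(planted$from == planted$to))
    stop_param("planted edges cannot be self-couplings")
  structure(list(n_subjects = as.integer(n_subjects), model = model,
                 planted = planted, delta = delta, jitter_sd = jitter_sd),
            class = "cohort_spec")
}

# strengths ~ truncated normal on [0,1] centred at base (rejection sampling,
# falling back to clipping after 100 rounds for extreme jitter).
jitter_strengths <- function(base, sd) {
  if (sd == 0 || !length(base)) return(base)
  out <- rnorm(length(base), base, sd)
  for (i in seq_len(100)) {
    bad <- out < 0 | out > 1
    if (!any(bad)) break
    out[bad] <- rnorm(sum(bad), base[bad], sd)
  }
  pmin(pmax(out, 0), 1)
}

#' Generate a paired pre/post cohort of recordings
#'
#' All randomness derives from `spec$model$seed` through a documented rule
#' (master, subject index, session index), so each subject/session is
#' independently reproducible.
#'
#' @param spec a [cohort_spec()].
#' @param duration_s recording length per session (seconds). The default
#'   emulates a five-minute resting-state recording.
#' @return object of class `cohort`: list `subjects`, each with `pre` and
#'   `post` recordings, plus the generating `spec`.
#' @export
generate_cohort <- function(spec, duration_s = 300) {
  stopifnot(inherits(spec, "cohort_spec"))
  model <- spec$model
  subjects <- vector("list", spec$n_subjects)
  clipped <- FALSE
  rescaled <- FALSE
  for (s in seq_len(spec$n_subjects)) {
    set.seed(derive_seed(model$seed, s, 0L))
    cpl <- model$couplings
    cpl$strength <- jitter_strengths(cpl$strength, spec$jitter_sd)
    if (nrow(cpl)) {
      tot <- tapply(cpl$strength, cpl$to, sum)
      for (nd in names(tot)[tot > 1]) {   # jitter can nudge a full mixture
        sel <- cpl$to == as.integer(nd)
        cpl$strength[sel] <- cpl$strength[sel] / tot[[nd]]
      }
    }

    post_cpl <- cpl
    for (r in seq_len(nrow(spec$planted))) {
      i <- spec$planted$from[r]; j <- spec$planted$to[r]
      hit <- which(post_cpl$from == i & post_cpl$to == j)
      if (length(hit)) {
        post_cpl$strength[hit] <- post_cpl$strength[hit] + spec$delta
      } else {
        post_cpl <- rbind(post_cpl, data.frame(
          from = i, to = j, lag = spec$planted$lag[r],
          strength = spec$delta))
      }
    }
    if (any(post_cpl$strength > 1)) {
      clipped <- TRUE
      post_cpl$strength <- pmin(post_cpl$strength, 1)
    }
    tot <- tapply(post_cpl$strength, post_cpl$to, sum)
    over <- names(tot)[tot > 1]
    if (length(over)) {
      rescaled <- TRUE
      for (nd in over) {
        sel <- post_cpl$to == as.integer(nd)
        post_cpl$strength[sel] <- post_cpl$strength[sel] / tot[[nd]]
      }
    }

    pre_model <- model
    pre_model$couplings <- cpl
    pre_model$seed <- derive_seed(model$seed, s, 1L)
    post_model <- model
    post_model$couplings <- post_cpl
    post_model$seed <- derive_seed(model$seed, s, 2L)

    subjects[[s]] <- list(pre = generate_coupled_timeseries(pre_model, duration_s),
                          post = generate_coupled_timeseries(post_model, duration_s))
  }
  if (clipped)
    warning("planted delta pushed coupling strength above 1; clipped",
            call. = FALSE)
  if (rescaled)
    warning("total incoming strength above 1 after planting; rescaled",
            call. = FALSE)
  structure(list(subjects = subjects, spec = spec), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects x {pre, post}, %d nodes @ %g Hz\n",
              length(x$subjects), x$spec$model$n_nodes, x$spec$model$fs))
  invisible(x)
}

#' Reference graphs with known structure
#'
#' Generates small weighted digraphs used to validate graph metrics and
#' community detection: ring lattices, Watts-Strogatz small worlds,
#' Erdos-Renyi random graphs, a nested stochastic block hierarchy (cliques
#' inside blocks inside the whole graph), and two disconnected cliques.
#' Undirected kinds populate both directions of the adjacency matrix.
#'
#' @param kind one of `"lattice"`, `"watts_strogatz"`, `"erdos_renyi"`,
#'   `"hierarchical_blocks"`, `"two_cliques"`.
#' @param params named list; per kind:
#'   * lattice: `n`, `k` (even neighbourhood size)
#'   * watts_strogatz: `n`, `k`, `p` (rewiring probability)
#'   * erdos_renyi: `n`, `p`
#'   * hierarchical_blocks: `n_blocks`, `n_sub`, `sub_size`, `p_mid`,
#'     `p_out` (edge probabilities between sub-blocks of the same block and
#'     between blocks; sub-blocks are cliques)
#'   * two_cliques: `size`
#' @param seed integer seed for the random kinds.
#' @return square numeric weight matrix (entry `[i, j]` = edge i -> j).
#' @export
generate_reference_graph <- function(kind, params = list(), seed = 1L) {
  check_scalar(seed, "seed", integerish = TRUE)
  set.seed(seed)
  p <- params
  sym <- function(g) {
    a <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
    storage.mode(a) <- "double"
    diag(a) <- 0
    a
  }
  switch(kind,
    lattice = {
      g <- igraph::make_lattice(length = p$n, dim = 1, nei = p$k / 2,
                                periodic = TRUE)
      sym(g)
    },
    watts_strogatz = {
      g <- igraph::sample_smallworld(1, p$n, p$k / 2, p$p)
      g <- igraph::simplify(g)
      sym(g)
    },
    erdos_renyi = {
      g <- igraph::sample_gnp(p$n, p$p)
      sym(g)
    },
    hierarchical_blocks = {
      nb <- p$n_blocks %||% 2L
      ns <- p$n_sub %||% 3L
      sz <- p$sub_size %||% 8L
      p_mid <- p$p_mid %||% 0.35
      p_out <- p$p_out %||% 0.02
      n <- nb * ns * sz
      block <- rep(seq_len(nb), each = ns * sz)
      sub <- rep(seq_len(nb * ns), each = sz)
      a <- matrix(0, n, n)
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        pe <- if (sub[i] == sub[j]) 1
              else if (block[i] == block[j]) p_mid
              else p_out
        if (runif(1) < pe) a[i, j] <- a[j, i] <- 1
      }
      attr(a, "block") <- block
      attr(a, "sub") <- sub
      a
    },
    two_cliques = {
      m <- p$size %||% 5L
      a <- matrix(0, 2 * m, 2 * m)
      a[seq_len(m), seq_len(m)] <- 1
      a[m + seq_len(m), m + seq_len(m)] <- 1
      diag(a) <- 0
      a
    },
    stop_param("unknown reference graph kind '%s'", kind)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
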