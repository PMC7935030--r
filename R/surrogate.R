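#' Phase-randomized surrogate of a recording
#'
#' Per node: Fourier transform, replacement of the positive-frequency phases
#' by i.i.d. uniform draws on `[0, 2*pi)` (negative frequencies conjugate
#' symmetric; DC and Nyquist untouched), inverse transform. The surrogate
#' shares each channel's amplitude spectrum — hence autocorrelation — with
#' the original but destroys genuine cross-channel coupling.
#'
#' @param rec a [recording()].
#' @param seed integer seed.
#' @return phase-randomized `recording` of the same shape.
#' @export
phase_randomize <- function(rec, seed = 1L) {
  stopifnot(inherits(rec, "recording"))
  check_scalar(seed, "seed", integerish = TRUE)
  set.seed(seed)
  n <- ncol(rec$data)
  nn <- nrow(rec$data)
  half <- if (n %% 2 == 0) n / 2 - 1 else (n - 1) / 2
  if (half < 1) return(rec)
  f <- mvfft(t(rec$data))                       # samples x nodes
  idx <- 2:(half + 1)
  # uniform phases drawn as normalized Gaussian pairs, node by node (the
  # same stream the fast in-spectrum surrogate path consumes)
  for (cc in seq_len(nn)) {
    v <- rnorm(2 * half)
    u <- complex(real = v[c(TRUE, FALSE)], imaginary = v[c(FALSE, TRUE)])
    mu <- Mod(u)
    u[mu == 0] <- 1
    mu[mu == 0] <- 1
    f[idx, cc] <- Mod(f[idx, cc]) * (u / mu)
  }
  f[n + 2 - idx, ] <- Conj(f[idx, , drop = FALSE])
  out <- t(Re(mvfft(f, inverse = TRUE)) / n)
  recording(out, rec$fs, rec$labels)
}

# Instantaneous phases of a phase-randomized recording in one inverse FFT:
# randomizing the positive-frequency phases and applying the Hilbert mask in
# the same spectrum yields the surrogate's analytic signal directly. The
# forward spectrum of the data is surrogate-independent, so callers building
# ensembles compute it once. Equivalent to
# instantaneous_phase(phase_randomize(rec, seed)$data), verified in the test
# suite.
surrogate_phases_spec <- function(f_fwd, n, seed) {
  set.seed(seed)
  half <- if (n %% 2 == 0) n / 2 - 1 else (n - 1) / 2
  a <- mvfft(cpp_surrogate_spectrum(f_fwd, half, n %% 2 == 0),
             inverse = TRUE)
  # Arg lies in (-pi, pi]; the histogram stage treats pi and -pi as the
  # same (wrapped) bin, so no explicit rewrap is needed on this path
  Arg(a)                                 # samples x nodes
}

surrogate_phases <- function(data, seed) {
  surrogate_phases_spec(mvfft(t(data)), ncol(data), seed)
}

#' Surrogate ensemble of connectivity networks
#'
#' Each surrogate phase-randomizes the (already filtered) recording and then
#' runs the identical segmentation / phase / PTE / averaging path as the
#' real data ([subject_network()]), so the ensemble captures the
#' estimator's noise floor under the null of no cross-channel coupling.
#'
#' @param rec the filtered, analysis-band recording the real network came
#'   from.
#' @param n_surrogates ensemble size (the reference setup uses 1,000 per
#'   subject per session; tests use 100-200 for runtime).
#' @param pte_params a [pte_params()].
#' @param segment_length_s,n_segments,segment_seed the segmentation settings
#'   used for the real network.
#' @param seed master seed; surrogate `k` uses a sub-seed derived from it.
#' @return object of class `surrogate_ensemble`: list with `networks` (list
#'   of averaged weight matrices, provenance `"surrogate"`) and
#'   `n_surrogates`.
#' @export
build_surrogate_ensemble <- function(rec, n_surrogates,
                                     pte_params = pte_params(),
                                     segment_length_s = 4, n_segments = 15,
                                     segment_seed = 1L, seed = 1L) {
  stopifnot(inherits(rec, "recording"))
  check_scalar(n_surrogates, "n_surrogates", lower = 1, integerish = TRUE)
  seg_len <- round(segment_length_s * rec$fs)
  starts <- epoch_and_select(rec, segment_length_s, n_segments,
                             seed = segment_seed)$starts
  f_fwd <- mvfft(t(rec$data))            # shared by every surrogate
  networks <- vector("list", n_surrogates)
  for (k in seq_len(n_surrogates)) {
    ph <- surrogate_phases_spec(f_fwd, ncol(rec$data),
                                seed = derive_seed(seed, k))
    m <- tryCatch(
      pte_over_segments(ph, starts, seg_len, pte_params, rec$fs),
      error = function(e)
        stop_param("surrogate %d: %s", k, conditionMessage(e)))
    dimnames(m) <- list(rec$labels, rec$labels)
    attr(m, "provenance") <- "surrogate"
    networks[[k]] <- m
  }
  structure(list(networks = networks, n_surrogates = n_surrogates),
            class = "surrogate_ensemble")
}

#' Prune noise edges against a surrogate ensemble
#'
#' For each edge, counts the surrogate networks whose corresponding edge
#' weight exceeds the real weight by more than `tolerance`; if that count
#' exceeds `floor(alpha * n_surrogates)` the edge is considered
#' indistinguishable from estimator noise and zeroed, otherwise it is kept
#' unchanged. With 1,000 surrogates at the 5% level the removal criterion is
#' the classic "worse than more than 50 surrogates"; weight differences
#' below `tolerance` (default 1e-3) are ignored so ties favour retention.
#'
#' @param real averaged weight matrix (the subject's network).
#' @param ensemble a [build_surrogate_ensemble()] result, or a list of
#'   equally shaped weight matrices.
#' @param alpha significance level in (0, 1).
#' @param tolerance additive tolerance applied before counting.
#' @return object of class `pruned_network`: list with `network` (weights,
#'   provenance `"pruned"`), `retained` (logical matrix), `n_retained`,
#'   `critical_count`, `alpha`, `tolerance`.
#' @export
prune_network <- function(real, ensemble, alpha = 0.05, tolerance = 1e-3) {
  check_square_matrix(real, "real")
  nets <- if (inherits(ensemble, "surrogate_ensemble")) ensemble$networks
          else ensemble
  if (!length(nets)) stop_param("empty surrogate ensemble")
  if (!all(vapply(nets, function(m) identical(dim(m), dim(real)),
                  logical(1))))
    stop_param("surrogate networks must match the real network's shape")
  check_scalar(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  check_scalar(tolerance, "tolerance", lower = 0)

  n_sur <- length(nets)
  crit <- floor(alpha * n_sur)
  exceed <- matrix(0L, nrow(real), ncol(real))
  for (m in nets) exceed <- exceed + (m > real + tolerance)
  keep <- exceed <= crit
  diag(keep) <- FALSE
  out <- ifelse(keep, real, 0)
  diag(out) <- 0
  dimnames(out) <- dimnames(real)
  attr(out, "provenance") <- "pruned"
  structure(list(network = out, retained = keep,
                 n_retained = sum(keep & real != 0),
                 critical_count = crit, alpha = alpha,
                 tolerance = tolerance, n_surrogates = n_sur),
            class = "pruned_network")
}

#' @export
print.pruned_network <- function(x, ...) {
  cat(sprintf(
    "<pruned_network> %d nodes, %d edges retained (critical count %d of %d surrogates, alpha %g)\n",
    nrow(x$network), x$n_retained, x$critical_count, x$n_surrogates,
    x$alpha))
  invisible(x)
}
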