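#' Parameters for the phase-transfer-entropy estimator
#'
#' @param delay prediction delay in samples, or `NULL` to derive it from the
#'   sampling rate as `max(1, round(fs / (2 * f_hi)))` with `f_hi` the upper
#'   edge of the analysis band — i.e. tied to the fastest phase dynamics in
#'   the band. `delay_mode = "sign_change"` instead uses the heuristic common
#'   in the directed-PTE literature: total samples times channels divided by
#'   the number of sign changes across all phase series.
#' @param n_bins number of histogram bins, or `"scott"` to compute one bin
#'   count per node pair by Scott's rule on the pooled phase distribution of
#'   both series (bin edges anchored on `[-pi, pi)`).
#' @param analysis_band length-2 band (Hz) the phases are assumed to carry.
#' @param delay_mode `"band"` (default) or `"sign_change"`.
#' @return object of class `pte_params`.
#' @export
pte_params <- function(delay = NULL, n_bins = "scott",
                       analysis_band = c(0.53, 35), delay_mode = "band") {
  if (!is.null(delay)) check_scalar(delay, "delay", lower = 1,
                                    integerish = TRUE)
  if (!identical(n_bins, "scott"))
    check_scalar(n_bins, "n_bins", lower = 2, integerish = TRUE)
  if (length(analysis_band) != 2L || analysis_band[1] >= analysis_band[2])
    stop_param("analysis_band must be (low, high) with low < high")
  delay_mode <- match.arg(delay_mode, c("band", "sign_change"))
  structure(list(delay = delay, n_bins = n_bins,
                 analysis_band = analysis_band, delay_mode = delay_mode),
            class = "pte_params")
}

resolve_delay <- function(params, fs, phases = NULL) {
  if (!is.null(params$delay)) return(as.integer(params$delay))
  if (params$delay_mode == "sign_change") {
    if (is.null(phases)) stop_param("sign-change delay needs phase data")
    sc <- sum(apply(phases, 1, function(p) sum(diff(sign(p)) != 0)))
    return(max(1L, as.integer(round(length(phases) / max(sc, 1)))))
  }
  max(1L, as.integer(round(fs / (2 * params$analysis_band[2]))))
}

#' Instantaneous phase via the Hilbert transform
#'
#' Computes the analytic signal of each node's time series by FFT and
#' returns the phase angle, wrapped to `[-pi, pi)`. The input should already
#' be band-passed to the analysis band.
#'
#' @param segment numeric matrix (nodes x samples) or numeric vector.
#' @return matrix (or vector) of phases in radians.
#' @export
instantaneous_phase <- function(segment) {
  vec <- is.null(dim(segment))
  m <- if (vec) matrix(segment, nrow = 1) else segment
  if (!is.numeric(m)) stop_param("`segment` must be numeric")
  zero <- which(rowSums(m != 0) == 0)
  if (length(zero))
    stop_param("phase undefined for all-zero signal (node %d)", zero[1])
  n <- ncol(m)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    if (n > 1) h[2:((n + 1) / 2)] <- 2
  }
  a <- mvfft(mvfft(t(m)) * h, inverse = TRUE)   # analytic, samples x nodes
  out <- t(Arg(a))
  out <- ((out + pi) %% (2 * pi)) - pi
  rownames(out) <- rownames(m)
  if (vec) out[1, ] else out
}

#' Scott's rule bin count for phase histograms
#'
#' Bin width `h = 3.49 * sd(x) * N^(-1/3)`; the count is `ceiling(2*pi / h)`
#' (the phase range is fixed at one full circle), floored at 2.
#'
#' @param phase_values numeric vector of phases.
#' @return integer bin count.
#' @export
scott_bin_count <- function(phase_values) {
  if (length(phase_values) < 2 || length(unique(phase_values)) < 2)
    stop_param("Scott's rule needs at least two distinct values")
  h <- 3.49 * sd(phase_values) * length(phase_values)^(-1 / 3)
  max(2L, as.integer(ceiling(2 * pi / h)))
}

#' Phase transfer entropy between two phase series
#'
#' Estimates `PTE(x -> y) = sum p(y_{t+d}, y_t, x_t) *
#' log[ p(y_{t+d} | y_t, x_t) / p(y_{t+d} | y_t) ]` in nats, with
#' probabilities from histogram counts of the binned phase triplets. Small
#' negative values arising from finite samples are clipped to zero.
#'
#' @param phase_x,phase_y phase vectors in `[-pi, pi)`, equal length, at
#'   least `10 * delay` samples.
#' @param params a [pte_params()]; `delay` must resolve without a sampling
#'   rate here, so either set it explicitly or pass `fs`.
#' @param fs sampling rate used to derive the default delay.
#' @return list with `xy` and `yx`, the two directed PTE values (nats).
#' @export
phase_transfer_entropy <- function(phase_x, phase_y, params = pte_params(),
                                   fs = NULL) {
  if (length(phase_x) != length(phase_y))
    stop_param("phase series must have equal length")
  d <- if (!is.null(params$delay)) as.integer(params$delay)
       else if (!is.null(fs)) resolve_delay(params, fs)
       else stop_param("set `delay` in pte_params() or supply `fs`")
  if (length(phase_x) < 10 * d)
    stop_param("need at least 10 * delay = %d samples, got %d",
               10 * d, length(phase_x))
  nb <- if (identical(params$n_bins, "scott")) -1L else
    as.integer(params$n_bins)
  v <- cpp_pte_pair(as.numeric(phase_x), as.numeric(phase_y), nb, d)
  list(xy = v[1], yx = v[2])
}

#' Per-segment directed connectivity matrices
#'
#' For every segment, extracts instantaneous phases and computes the full
#' n x n phase-transfer-entropy matrix (entry `[i, j]` = PTE(i -> j),
#' diagonal zero). Segments must already be band-passed to the analysis
#' band (see [apply_analysis_band()]).
#'
#' @param segment_set a [epoch_and_select()] result.
#' @param params a [pte_params()].
#' @return list of weight matrices, one per segment, with node labels as
#'   dimnames and `provenance` attribute `"segment-level"`.
#' @export
connectivity_matrix <- function(segment_set, params = pte_params()) {
  stopifnot(inherits(segment_set, "segment_set"))
  lapply(seq_along(segment_set$segments), function(s) {
    seg <- segment_set$segments[[s]]
    ph <- tryCatch(instantaneous_phase(seg), error = function(e)
      stop_param("segment %d: %s", s, conditionMessage(e)))
    d <- resolve_delay(params, segment_set$fs, ph)
    nb <- if (identical(params$n_bins, "scott")) -1L else
      as.integer(params$n_bins)
    if (ncol(ph) < 10 * d)
      stop_param("segment %d: need at least 10 * delay samples", s)
    w <- cpp_pte_matrix(ph, nb, d)
    dimnames(w) <- list(segment_set$labels, segment_set$labels)
    attr(w, "provenance") <- "segment-level"
    w
  })
}

#' Subject-level PTE network from a recording
#'
#' The pipeline's standard estimator path: instantaneous phases are
#' extracted once on the whole (filtered, analysis-band) recording — which
#' avoids per-segment edge artifacts in the analytic signal — then the
#' phase series is cut into the randomly selected segments, one PTE matrix
#' is computed per segment, and the matrices are averaged.
#' [build_surrogate_ensemble()] runs the identical path on
#' phase-randomized copies, so estimator bias cancels edge by edge.
#'
#' @param rec a [recording()], already band-passed to the analysis band.
#' @param params a [pte_params()].
#' @param segment_length_s,n_segments,seed segmentation settings as in
#'   [epoch_and_select()].
#' @return averaged weight matrix (provenance `"averaged"`), with the
#'   selected segment starts as attribute `"starts"`.
#' @export
subject_network <- function(rec, params = pte_params(),
                            segment_length_s = 4, n_segments = 15,
                            seed = 1L) {
  stopifnot(inherits(rec, "recording"))
  segs <- epoch_and_select(rec, segment_length_s, n_segments, seed)
  ph <- t(instantaneous_phase(rec$data))        # samples x nodes
  avg <- pte_over_segments(ph, segs$starts,
                           round(segment_length_s * rec$fs), params,
                           rec$fs)
  dimnames(avg) <- list(rec$labels, rec$labels)
  attr(avg, "provenance") <- "averaged"
  attr(avg, "starts") <- segs$starts
  avg
}

# shared inner loop: cut a recording-level phase matrix (samples x nodes)
# into segments, compute one PTE matrix per segment, average.
pte_over_segments <- function(ph, starts, seg_len, params, fs) {
  d <- if (is.null(params$delay) && params$delay_mode == "sign_change")
    resolve_delay(params, fs, t(ph)) else resolve_delay(params, fs)
  if (seg_len < 10 * d)
    stop_param("segments need at least 10 * delay = %d samples", 10 * d)
  nb <- if (identical(params$n_bins, "scott")) -1L else
    as.integer(params$n_bins)
  acc <- NULL
  for (st in starts) {
    w <- cpp_pte_matrix(ph[(st + 1):(st + seg_len), , drop = FALSE], nb, d,
                        nodes_in_cols = TRUE)
    acc <- if (is.null(acc)) w else acc + w
  }
  acc / length(starts)
}

#' Average segment-level networks into one network
#'
#' @param networks non-empty list of equally shaped weight matrices.
#' @return entrywise mean matrix with `provenance` attribute `"averaged"`.
#' @export
average_connectivity <- function(networks) {
  if (!length(networks)) stop_param("cannot average an empty network list")
  dims <- vapply(networks, function(m) dim(m), integer(2))
  if (any(dims != dims[, 1]))
    stop_param("all networks must share the same shape")
  out <- Reduce(`+`, networks) / length(networks)
  attr(out, "provenance") <- "averaged"
  out
}
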