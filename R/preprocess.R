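#' Denoising filter specification
#'
#' Defaults reproduce a standard resting-state EEG chain: 0.53 Hz high-pass,
#' 48-52 Hz line-noise notch, 97 Hz low-pass, with connectivity subsequently
#' estimated in the 0.53-35 Hz analysis band. All filters are Butterworth
#' IIR designs applied forward-backward (zero phase), which protects the
#' phase estimates the connectivity stage depends on.
#'
#' @param highpass_hz high-pass corner (Hz).
#' @param notch_band_hz length-2 stop band (Hz); `NULL` disables the notch.
#' @param lowpass_hz low-pass corner (Hz).
#' @param analysis_band_hz length-2 band-pass (Hz) applied before phase
#'   extraction in the connectivity stage.
#' @return object of class `filter_spec`.
#' @export
filter_spec <- function(highpass_hz = 0.53, notch_band_hz = c(48, 52),
                        lowpass_hz = 97, analysis_band_hz = c(0.53, 35)) {
  check_scalar(highpass_hz, "highpass_hz", lower = 0)
  check_scalar(lowpass_hz, "lowpass_hz", lower = 0)
  if (highpass_hz >= lowpass_hz)
    stop_param("highpass_hz must be below lowpass_hz")
  if (!is.null(notch_band_hz)) {
    if (length(notch_band_hz) != 2L || notch_band_hz[1] >= notch_band_hz[2])
      stop_param("notch_band_hz must be (low, high) with low < high")
    if (notch_band_hz[1] <= highpass_hz || notch_band_hz[2] >= lowpass_hz)
      stop_param("notch band must lie inside (highpass, lowpass)")
  }
  if (length(analysis_band_hz) != 2L ||
      analysis_band_hz[1] >= analysis_band_hz[2])
    stop_param("analysis_band_hz must be (low, high) with low < high")
  if (analysis_band_hz[1] < highpass_hz - 1e-12 ||
      analysis_band_hz[2] > lowpass_hz + 1e-12)
    stop_param("analysis band must lie inside the filtered band")
  structure(list(highpass_hz = highpass_hz, notch_band_hz = notch_band_hz,
                 lowpass_hz = lowpass_hz,
                 analysis_band_hz = analysis_band_hz),
            class = "filter_spec")
}

# Zero-phase IIR filtering with odd-reflection padding. signal::filtfilt
# alone leaves large edge transients; padding with the signal reflected
# about its endpoints (scipy-style) confines them to the discarded pad.
zerophase_filter <- function(x, flt, pad = NULL) {
  n <- length(x)
  if (is.null(pad)) pad <- min(n - 1L, 3000L)
  left <- 2 * x[1] - x[seq(pad + 1, 2)]
  right <- 2 * x[n] - x[seq(n - 1, n - pad)]
  xp <- c(left, x, right)
  yp <- signal::filtfilt(flt, xp)
  yp[(pad + 1):(pad + n)]
}

#' Apply the denoising filter chain to a recording
#'
#' Applies high-pass, notch and low-pass Butterworth filters in that order,
#' each forward-backward (zero phase). Channels are demeaned first; the
#' output has the input's length.
#'
#' @param rec a [recording()].
#' @param spec a [filter_spec()].
#' @return filtered `recording`.
#' @export
apply_filters <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "recording"), inherits(spec, "filter_spec"))
  fs <- rec$fs
  if (fs <= 2 * spec$lowpass_hz)
    stop_param("sampling rate %g Hz too low for a %g Hz low-pass",
               fs, spec$lowpass_hz)
  nyq <- fs / 2
  hp <- signal::butter(2, spec$highpass_hz / nyq, type = "high")
  lp <- signal::butter(4, spec$lowpass_hz / nyq, type = "low")
  nt <- if (!is.null(spec$notch_band_hz))
    signal::butter(2, spec$notch_band_hz / nyq, type = "stop")
  out <- rec$data
  for (k in seq_len(nrow(out))) {
    x <- out[k, ] - mean(out[k, ])
    x <- zerophase_filter(x, hp)
    if (!is.null(nt)) x <- zerophase_filter(x, nt)
    x <- zerophase_filter(x, lp)
    out[k, ] <- x
  }
  recording(out, fs, rec$labels)
}

#' Band-pass a recording to the analysis band
#'
#' Applied before phase extraction so that connectivity is computed on the
#' stated analysis band only (the denoising low-pass is much higher).
#'
#' @param rec a [recording()].
#' @param band length-2 band (Hz).
#' @return filtered `recording`.
#' @export
apply_analysis_band <- function(rec, band = c(0.53, 35)) {
  stopifnot(inherits(rec, "recording"))
  if (rec$fs <= 2 * band[2])
    stop_param("sampling rate %g Hz too low for band up to %g Hz",
               rec$fs, band[2])
  bp <- signal::butter(2, band / (rec$fs / 2), type = "pass")
  out <- rec$data
  for (k in seq_len(nrow(out)))
    out[k, ] <- zerophase_filter(out[k, ] - mean(out[k, ]), bp)
  recording(out, rec$fs, rec$labels)
}

#' Randomly select non-overlapping fixed-length segments
#'
#' Partitions the recording into consecutive windows of `segment_length_s`
#' seconds and uniformly samples `n_segments` of them without replacement,
#' emulating the random selection of artifact-free epochs (fifteen
#' four-second segments per recording in the reference setup).
#'
#' @param rec a [recording()].
#' @param segment_length_s segment length in seconds.
#' @param n_segments number of segments to draw.
#' @param seed integer seed making the draw reproducible.
#' @return object of class `segment_set`: list with `segments` (list of
#'   node x sample matrices), `fs`, `labels`, `segment_length_s`, and the
#'   0-based starting sample `starts`.
#' @export
epoch_and_select <- function(rec, segment_length_s = 4, n_segments = 15,
                             seed = 1L) {
  stopifnot(inherits(rec, "recording"))
  check_scalar(segment_length_s, "segment_length_s", lower = 1e-12)
  check_scalar(n_segments, "n_segments", lower = 1, integerish = TRUE)
  check_scalar(seed, "seed", integerish = TRUE)
  seg_len <- as.integer(round(segment_length_s * rec$fs))
  n_avail <- floor(ncol(rec$data) / seg_len)
  if (n_avail < n_segments)
    stop_param(paste0("recording too short: %d segments of %g s requested ",
                      "but only %d available (%.1f s recorded)"),
               n_segments, segment_length_s, n_avail,
               ncol(rec$data) / rec$fs)
  set.seed(seed)
  picks <- sort(sample.int(n_avail, n_segments))
  segs <- lapply(picks, function(w) {
    rec$data[, ((w - 1) * seg_len + 1):(w * seg_len), drop = FALSE]
  })
  structure(list(segments = segs, fs = rec$fs, labels = rec$labels,
                 segment_length_s = segment_length_s,
                 starts = (picks - 1L) * seg_len),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> %d segments of %g s, %d nodes @ %g Hz\n",
              length(x$segments), x$segment_length_s,
              nrow(x$segments[[1]]), x$fs))
  invisible(x)
}
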