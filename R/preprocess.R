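#' Split a signal into non-overlapping windows
#'
#' Contiguous windows of exactly \code{fs * window_s} samples; the trailing
#' remainder is dropped so every per-window stream in the pipeline has
#' \code{floor(N / (fs * window_s))} entries. Windows are half-open
#' \code{[t, t + window_s)} with 0-based start times.
#'
#' @param signal numeric sample vector.
#' @param fs sampling rate in Hz.
#' @param window_s window length in seconds (default 1).
#' @return a samples-per-window x n-window numeric matrix (one window per
#'   column), with window start times (s) in the \code{"times"} attribute.
#' @export
segment_windows <- function(signal, fs, window_s = 1) {
  if (length(signal) == 0L) stop("empty signal")
  wlen <- round(fs * window_s)
  if (wlen < 2L) stop("fs * window_s must be at least 2 samples")
  n_win <- floor(length(signal) / wlen)
  if (n_win < 1L) stop("signal shorter than one window (", wlen, " samples)")
  m <- matrix(signal[seq_len(n_win * wlen)], nrow = wlen)
  attr(m, "times") <- (seq_len(n_win) - 1L) * window_s
  m
}

#' Angular oscillation of the goniometer trace
#'
#' The labeling input for arm oscillation: the sample standard deviation of
#' the elbow angle computed in non-overlapping windows (4 s by default), then
#' expanded back to per-sample length by zero-order hold so it can be paired
#' with the raw angle sample-by-sample. SD is a block statistic, so the hold
#' (rather than interpolation) avoids inventing intermediate values; samples
#' beyond the last full window take the last window's SD.
#'
#' @param angle elbow-angle vector in degrees.
#' @param fs sampling rate in Hz.
#' @param window_s oscillation window length in seconds (default 4).
#' @return per-sample oscillation (degrees SD), same length as \code{angle}.
#' @export
gonio_oscillation <- function(angle, fs, window_s = 4) {
  wlen <- round(fs * window_s)
  if (length(angle) < wlen) {
    stop("angle trace shorter than one ", window_s, "-s oscillation window")
  }
  n_win <- floor(length(angle) / wlen)
  blocks <- matrix(angle[seq_len(n_win * wlen)], nrow = wlen)
  sds <- apply(blocks, 2L, stats::sd)   # sample (n-1) SD, package convention
  out <- rep(sds, each = wlen)
  n_tail <- length(angle) - n_win * wlen
  if (n_tail > 0L) out <- c(out, rep(sds[n_win], n_tail))
  out
}
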