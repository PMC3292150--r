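# Polynomial with given roots, leading coefficient 1.
# Roots occur in conjugate pairs so the result is real up to rounding.
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

# Digital Butterworth band-pass in zero-pole-gain form: analog prototype,
# low-pass to band-pass transform, bilinear mapping with pre-warped edges.
butter_bandpass_zpk <- function(order, low, high, fs) {
  stopifnot(order >= 1, fs > 0)
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop("band edges must satisfy 0 < low < high < fs/2 (got [",
         low, ", ", high, "] Hz at fs = ", fs, " Hz)")
  }
  k <- seq_len(order)
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # prototype poles

  fs2 <- 2 * fs
  w1 <- fs2 * tan(pi * low / fs)
  w2 <- fs2 * tan(pi * high / fs)
  bw <- w2 - w1
  wo <- sqrt(w1 * w2)

  ps <- p * bw / 2
  p_bp <- c(ps + sqrt(ps^2 - wo^2), ps - sqrt(ps^2 - wo^2))
  z_bp <- rep(0 + 0i, order)
  gain <- bw^order

  pd <- (1 + p_bp / fs2) / (1 - p_bp / fs2)
  gain_d <- gain * Re(prod(fs2 - z_bp) / prod(fs2 - p_bp))
  # order zeros at z = +1 (from s = 0) and order zeros at z = -1 (from s = inf)
  list(p = pd, k = gain_d, n = order)
}

# Cascade of second-order sections. Each section takes one zero at +1 and one
# at -1 (numerator 1, 0, -1) and a pole pair: conjugate pairs stay together,
# real poles are paired after sorting. Gain is applied to the first section.
# Sections are well conditioned where the full polynomial form is not (the
# 1 Hz edge puts poles extremely close to the unit circle).
butter_bandpass_sos <- function(order, low, high, fs) {
  zpk <- butter_bandpass_zpk(order, low, high, fs)
  p <- zpk$p
  tol <- 1e-10
  cplx <- p[Im(p) > tol]
  reals <- sort(Re(p[abs(Im(p)) <= tol]))
  if (length(cplx) * 2 + length(reals) != length(p)) {
    stop("internal error: unbalanced pole set")  # conjugacy violated
  }
  sections <- list()
  for (pp in cplx) {
    sections[[length(sections) + 1L]] <-
      c(1, 0, -1, 1, -2 * Re(pp), Mod(pp)^2)
  }
  if (length(reals) %% 2L != 0L) stop("internal error: odd real pole count")
  for (i in seq_len(length(reals) / 2)) {
    r1 <- reals[2 * i - 1]; r2 <- reals[2 * i]
    sections[[length(sections) + 1L]] <- c(1, 0, -1, 1, -(r1 + r2), r1 * r2)
  }
  sos <- do.call(rbind, sections)
  sos[1, 1:3] <- sos[1, 1:3] * zpk$k
  sos
}

# One biquad with zero initial conditions via stats::filter (C loops):
# moving-average pass then the order-2 recursion.
biquad_filter <- function(sec, x) {
  b <- sec[1:3] / sec[4]
  a <- sec[4:6] / sec[4]
  xp <- c(0, 0, x)
  ma <- as.numeric(stats::filter(xp, b, method = "convolution", sides = 1))
  ma <- ma[seq(3, length(xp))]
  as.numeric(stats::filter(ma, -a[2:3], method = "recursive"))
}

sos_filter <- function(sos, x) {
  for (i in seq_len(nrow(sos))) x <- biquad_filter(sos[i, ], x)
  x
}

#' Zero-phase (dual-pass) Butterworth band-pass filter
#'
#' Applies a Butterworth band-pass forward and backward, so the net phase
#' response is zero and the magnitude response is the squared one-pass
#' response. Zero phase preserves the time alignment between the sEMG and the
#' goniometer channel, which the per-second labels rely on. The filter runs
#' as a cascade of second-order sections for numerical stability, with odd
#' reflection padding at both ends to suppress start-up transients; since a
#' band-pass has zero DC gain, the leading level is removed before each pass
#' so that the all-zero initial state is the true rest state.
#'
#' @param signal numeric sample vector (mV for sEMG, but any unit works).
#' @param fs sampling rate in Hz.
#' @param low,high pass-band edges in Hz (defaults 1 and 500).
#' @param order Butterworth prototype order (default 5).
#' @return filtered vector of the same length as \code{signal}.
#' @examples
#' x <- sin(2 * pi * 50 * seq(0, 2, by = 1 / 2000))
#' y <- bandpass_filter(x, fs = 2000)
#' @export
bandpass_filter <- function(signal, fs, low = 1, high = 500, order = 5) {
  sos <- butter_bandpass_sos(order, low, high, fs)
  n_edge <- 3 * 2 * nrow(sos)
  if (length(signal) <= 3 * n_edge) {
    stop("signal too short for order-", order, " dual-pass filtering (need > ",
         3 * n_edge, " samples, got ", length(signal), ")")
  }
  if (!all(is.finite(signal))) stop("signal contains non-finite samples")
  head_pad <- 2 * signal[1] - signal[seq(n_edge + 1, 2)]
  tail_pad <- 2 * signal[length(signal)] -
    signal[seq(length(signal) - 1, length(signal) - n_edge)]
  xp <- c(head_pad, signal, tail_pad)
  y <- sos_filter(sos, xp - xp[1])
  yr <- rev(y)
  y <- rev(sos_filter(sos, yr - yr[1]))
  y[seq(n_edge + 1, n_edge + length(signal))]
}
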