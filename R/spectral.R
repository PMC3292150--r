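# One-sided PSD scaling shared by the periodogram and Welch estimators:
# integral of the returned density over its frequency grid approximates the
# signal variance (Parseval), with interior bins doubled.
one_sided <- function(p2, n, fs) {
  n_keep <- floor(n / 2) + 1L
  p <- p2[seq_len(n_keep)]
  if (n %% 2L == 0L) {
    p[seq(2L, n_keep - 1L)] <- 2 * p[seq(2L, n_keep - 1L)]
  } else if (n_keep > 1L) {
    p[seq(2L, n_keep)] <- 2 * p[seq(2L, n_keep)]
  }
  list(freqs = (seq_len(n_keep) - 1L) * fs / n, power = p)
}

#' Raw periodogram power spectral density
#'
#' Rectangular-window periodogram on the full window: for a 1-s window at
#' 2 kHz this gives the finest available 1 Hz grid, which the median
#' frequency needs. One-sided density scaling (mV^2/Hz).
#'
#' @param window numeric sample vector.
#' @param fs sampling rate in Hz.
#' @return list with \code{freqs} (Hz) and \code{power} (density).
#' @export
periodogram_psd <- function(window, fs) {
  n <- length(window)
  if (n < 2L) stop("window too short for a periodogram")
  p2 <- Mod(stats::fft(window))^2 / (fs * n)
  one_sided(p2, n, fs)
}

#' Welch power spectral density
#'
#' Averaged modified periodogram with a Hamming taper: the window is cut into
#' \code{seg_len}-sample segments overlapping by \code{overlap}, each segment
#' is tapered and its periodogram accumulated. Density normalization, so the
#' integral over the grid approximates the signal variance.
#'
#' @param window numeric sample vector (at least \code{seg_len} samples).
#' @param fs sampling rate in Hz.
#' @param seg_len segment length in samples (default 256).
#' @param overlap fractional segment overlap in \code{[0, 1)} (default 0.5).
#' @return list with \code{freqs} (Hz) and \code{power} (density).
#' @export
welch_psd <- function(window, fs, seg_len = 256, overlap = 0.5) {
  n <- length(window)
  if (n < seg_len) {
    stop("window (", n, " samples) shorter than Welch segment (", seg_len, ")")
  }
  if (!(overlap >= 0 && overlap < 1)) stop("overlap must be in [0, 1)")
  step <- max(1L, round(seg_len * (1 - overlap)))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(seg_len) - 1L) / (seg_len - 1L))
  scale <- 1 / (fs * sum(w^2))
  acc <- numeric(seg_len)
  for (s in starts) {
    seg <- window[seq(s, s + seg_len - 1L)] * w
    acc <- acc + Mod(stats::fft(seg))^2 * scale
  }
  one_sided(acc / length(starts), seg_len, fs)
}

#' Instantaneous median frequency of a window
#'
#' The frequency splitting the window's power spectrum into halves of equal
#' power, the classic sEMG fatigue marker (it declines as the spectrum
#' compresses). Computed on the raw periodogram for maximal frequency
#' resolution; the median is the first grid frequency at which the cumulative
#' power reaches half the total (no interpolation), so the result is always a
#' grid point and the estimator is fully deterministic.
#'
#' @param window numeric sample vector with non-zero variance.
#' @param fs sampling rate in Hz.
#' @return median frequency in Hz.
#' @export
imdf <- function(window, fs) {
  psd <- periodogram_psd(window, fs)
  total <- sum(psd$power)
  if (total <= 0) stop("median frequency undefined for an all-zero window")
  # relative tolerance so an exact half split (e.g. two equal lines) hits the
  # lower bin despite floating-point rounding of the cumulative sum
  psd$freqs[which(cumsum(psd$power) >= total / 2 * (1 - 1e-9))[1]]
}

#' Total band power of a window
#'
#' Trapezoidal integral of the Welch PSD over its full frequency grid
#' (approximately the signal variance, in mV^2).
#'
#' @inheritParams welch_psd
#' @return scalar power (mV^2).
#' @export
total_band_power <- function(window, fs, seg_len = 256, overlap = 0.5) {
  psd <- welch_psd(window, fs, seg_len = seg_len, overlap = overlap)
  trapz(psd$freqs, psd$power)
}

# trapezoidal rule on an arbitrary grid
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Dimitrov spectral fatigue index FInsmX
#'
#' Ratio of the order minus-one spectral moment to the order-\code{X} moment
#' of the power spectrum over \code{[f1, f2]} Hz. The index grows as the
#' spectrum compresses toward low frequencies, making it a sensitive fatigue
#' marker; amplitude scaling cancels. Moments are trapezoidal integrals on
#' the raw periodogram grid.
#'
#' @param window numeric sample vector.
#' @param fs sampling rate in Hz.
#' @param X moment order, one of 2..5 (default 2, the variant with the best
#'   reported classification performance).
#' @param f1,f2 integration band in Hz (defaults 8 and 500).
#' @return scalar index value.
#' @export
fi_nsm <- function(window, fs, X = 2, f1 = 8, f2 = 500) {
  if (!(X %in% 2:5)) stop("moment order X must be in 2..5")
  if (!(f1 < f2)) stop("f1 must be below f2")
  psd <- periodogram_psd(window, fs)
  if (max(psd$freqs) < f2 || min(psd$freqs) > f1) {
    stop("periodogram grid does not cover [", f1, ", ", f2, "] Hz")
  }
  keep <- psd$freqs >= f1 & psd$freqs <= f2
  f <- psd$freqs[keep]
  ps <- psd$power[keep]
  denom <- trapz(f, f^X * ps)
  if (denom <= 0) stop("zero denominator moment: spectrum empty in band")
  trapz(f, f^(-1) * ps) / denom
}
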