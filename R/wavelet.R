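# Orthonormal scaling (low-pass) filters, unit energy, sum sqrt(2).
# Computed by spectral factorization of the Daubechies polynomial (minimal
# phase for dbN, near-linear phase root selection for symN); they satisfy
# the QMF orthonormality and vanishing-moment conditions to ~1e-14.
WAVELET_FILTERS <- list(
  haar = c(0.7071067811865475, 0.7071067811865475),
  db2 = c(0.4829629131445342, 0.8365163037378079,
          0.2241438680420134, -0.1294095225512604),
  db3 = c(0.3326705529500827, 0.8068915093110927, 0.4598775021184913,
          -0.1350110200102550, -0.0854412738820268, 0.0352262918857095),
  db4 = c(0.2303778133088964, 0.7148465705529156, 0.6308807679298594,
          -0.0279837694168590, -0.1870348117190927, 0.0308413818355607,
          0.0328830116668852, -0.0105974017850690),
  sym4 = c(-0.0757657147895022, -0.0296355276460025, 0.4976186676327749,
           0.8037387518051321, 0.2978577956053062, -0.0992195435766332,
           -0.0126039672620311, 0.0322231006040515),
  sym5 = c(0.0195388827352496, -0.0211018340246890, -0.1753280899080552,
           0.0166021057645102, 0.6339789634567891, 0.7234076904040422,
           0.1993975339768624, -0.0391342493023094, 0.0295194909257066,
           0.0273330683449984))

wavelet_filter <- function(wavelet) {
  h <- WAVELET_FILTERS[[tolower(wavelet)]]
  if (is.null(h)) {
    stop("unsupported wavelet '", wavelet, "'; supported: ",
         paste(names(WAVELET_FILTERS), collapse = ", "))
  }
  h
}

# quadrature mirror high-pass of a scaling filter
qmf_highpass <- function(h) {
  L <- length(h)
  (-1)^(seq_len(L) - 1) * rev(h)
}

# one periodized analysis step: even-length x -> list(approx, detail)
dwt_step <- function(x, h) {
  N <- length(x)
  stopifnot(N %% 2L == 0L)
  g <- qmf_highpass(h)
  k2 <- 2L * (seq_len(N / 2L) - 1L)
  a <- numeric(N / 2L); d <- numeric(N / 2L)
  for (n in seq_along(h)) {
    idx <- (k2 + (n - 1L)) %% N + 1L
    a <- a + h[n] * x[idx]
    d <- d + g[n] * x[idx]
  }
  list(approx = a, detail = d)
}

# adjoint (= inverse, filters are orthonormal) of dwt_step
idwt_step <- function(a, d, h) {
  N <- 2L * length(a)
  g <- qmf_highpass(h)
  x <- numeric(N)
  k2 <- 2L * (seq_len(N / 2L) - 1L)
  for (n in seq_along(h)) {
    idx <- (k2 + (n - 1L)) %% N + 1L
    x[idx] <- x[idx] + h[n] * a + g[n] * d
  }
  x
}

#' Multilevel discrete wavelet decomposition (periodized, orthonormal)
#'
#' Pyramid decomposition to \code{level} with the named wavelet. The signal
#' is first extended to a multiple of \code{2^level} samples by symmetric
#' (reflected) padding, then transformed with periodized filtering, which
#' keeps the transform exactly orthonormal and invertible.
#'
#' @param x numeric signal.
#' @param wavelet one of \code{haar, db2, db3, db4, sym4, sym5}.
#' @param level decomposition depth (default 12).
#' @return list with \code{approx} (coarsest approximation coefficients),
#'   \code{details} (list, finest level first), \code{n} (original length)
#'   and the transform parameters.
#' @export
wavelet_decompose <- function(x, wavelet = "db3", level = 12) {
  h <- wavelet_filter(wavelet)
  block <- 2^level
  n <- length(x)
  n_pad <- ceiling(n / block) * block
  if (n_pad > n) {
    # reflect the tail; recycle if the signal is shorter than the padding
    pad <- n_pad - n
    refl <- rev(x)
    while (length(refl) < pad) refl <- c(refl, rev(refl))
    x <- c(x, refl[seq_len(pad)])
  }
  details <- vector("list", level)
  a <- x
  for (j in seq_len(level)) {
    st <- dwt_step(a, h)
    a <- st$approx
    details[[j]] <- st$detail
  }
  list(approx = a, details = details, n = n, wavelet = wavelet, level = level)
}

#' Reconstruct the approximation at the decomposition depth
#'
#' Inverse transform with every detail band zeroed: the level-\code{level}
#' approximation signal, truncated back to the original length. At 2 kHz and
#' level 12 this is the sub-0.25 Hz content of the signal.
#'
#' @param dec result of \code{\link{wavelet_decompose}}.
#' @return numeric vector of length \code{dec$n}.
#' @export
wavelet_approx_signal <- function(dec) {
  h <- wavelet_filter(dec$wavelet)
  a <- dec$approx
  for (j in rev(seq_len(dec$level))) {
    a <- idwt_step(a, numeric(length(a)), h)
  }
  a[seq_len(dec$n)]
}

#' Per-second wavelet approximation energy feature
#'
#' The wavelet comparison feature: the whole trial's sEMG channel is
#' band-pass filtered, decomposed to \code{level} with the chosen mother
#' wavelet, the approximation at that depth is reconstructed to signal
#' length, and each one-second window's feature is the mean squared value of
#' the reconstruction inside the window. A one-second window cannot support
#' a depth-12 decomposition on its own, which is why the decomposition runs
#' on the full trial and only the per-window statistic is windowed.
#'
#' @param trial a \code{semg_trial}.
#' @param wavelet mother wavelet name (default \code{"db3"}, the best
#'   performer among the published comparison set).
#' @param level decomposition depth (default 12).
#' @param channel sEMG channel: 1, 2 or \code{"mean"}.
#' @param prefilter apply the 1-500 Hz acquisition band-pass first
#'   (default TRUE).
#' @return a \code{feature_series} named \code{"wavelet_<wavelet>"}.
#' @export
wavelet_feature <- function(trial, wavelet = "db3", level = 12,
                            channel = 1, prefilter = TRUE) {
  validate_trial(trial)
  x <- select_channel(trial, channel)
  if (prefilter) x <- bandpass_filter(x, trial$fs_emg)
  dec <- wavelet_decompose(x, wavelet = wavelet, level = level)
  approx <- wavelet_approx_signal(dec)
  w <- segment_windows(approx, trial$fs_emg, 1)
  new_feature_series(paste0("wavelet_", tolower(wavelet)),
                     times = attr(w, "times"),
                     values = colMeans(w^2))
}
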