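select_channel <- function(trial, channel = 1) {
  if (identical(channel, "mean")) return(rowMeans(trial$emg))
  if (!(channel %in% c(1, 2))) stop("channel must be 1, 2 or \"mean\"")
  trial$emg[, channel]
}

# apply a per-window scalar statistic over 1-s windows of a prepared signal
window_series <- function(x, fs, fun, name, window_s = 1) {
  w <- segment_windows(x, fs, window_s)
  vals <- apply(w, 2L, fun)
  new_feature_series(name, attr(w, "times"), vals, window_duration = window_s)
}

#' Per-second instantaneous median frequency series
#'
#' Band-pass filters the chosen sEMG channel (1-500 Hz acquisition filter),
#' splits it into one-second windows and computes the periodogram median
#' frequency of each.
#'
#' @param trial a \code{semg_trial}.
#' @param channel sEMG channel: 1 (default), 2 or \code{"mean"}.
#' @param prefilter apply the acquisition band-pass first (default TRUE).
#' @return a \code{feature_series} named \code{"imdf"} (Hz).
#' @export
imdf_series <- function(trial, channel = 1, prefilter = TRUE) {
  validate_trial(trial)
  x <- select_channel(trial, channel)
  if (prefilter) x <- bandpass_filter(x, trial$fs_emg)
  window_series(x, trial$fs_emg, function(w) imdf(w, trial$fs_emg), "imdf")
}

#' Per-second total band power series
#'
#' Welch-estimated total power of each one-second window (mV^2).
#'
#' @inheritParams imdf_series
#' @return a \code{feature_series} named \code{"bandpower"}.
#' @export
bandpower_series <- function(trial, channel = 1, prefilter = TRUE) {
  validate_trial(trial)
  x <- select_channel(trial, channel)
  if (prefilter) x <- bandpass_filter(x, trial$fs_emg)
  window_series(x, trial$fs_emg,
                function(w) total_band_power(w, trial$fs_emg), "bandpower")
}

#' Per-second Dimitrov spectral index series
#'
#' @inheritParams imdf_series
#' @param X moment order in 2..5 (default 2).
#' @return a \code{feature_series} named \code{"fi<X>"}.
#' @export
fi_series <- function(trial, X = 2, channel = 1, prefilter = TRUE) {
  validate_trial(trial)
  x <- select_channel(trial, channel)
  if (prefilter) x <- bandpass_filter(x, trial$fs_emg)
  window_series(x, trial$fs_emg,
                function(w) fi_nsm(w, trial$fs_emg, X = X),
                paste0("fi", X))
}

#' Unify band power and median frequency into the 1D spectro stream
#'
#' Power (mV^2) and median frequency (Hz) live on incommensurable scales, so
#' each series is first standardized over the trial (mean removed, divided
#' by the sample SD) and the dimensionless streams are subtracted:
#' \code{z(power) - z(mdf)}. The sign convention makes the unified value rise
#' as fatigue develops, since fatigue pushes power up and median frequency
#' down. This z-score reading of "unification by subtraction" is a package
#' interpretation; raw-unit subtraction would be dimensionally incoherent.
#'
#' @param power,mdf aligned \code{feature_series} (equal times).
#' @return a \code{feature_series} named \code{"unified"} (dimensionless).
#' @export
unify_1d_spectro <- function(power, mdf) {
  if (length(power$values) != length(mdf$values) ||
      any(abs(power$times - mdf$times) > 1e-9)) {
    stop("power and mdf series must share their time grid")
  }
  z <- function(v, what) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      stop("cannot standardize zero-variance ", what, " series")
    }
    (v - mean(v)) / s
  }
  new_feature_series("unified", power$times,
                     z(power$values, "power") - z(mdf$values, "mdf"),
                     window_duration = power$window_duration)
}

#' Rolling standard deviation of a feature series
#'
#' Sliding sample SD over \code{span} consecutive values with step 1. The
#' output value at position i summarizes values i..i+span-1 and is
#' timestamped at the start of the last window in the span, so a value at
#' time t only uses data up to t + 1 s -- the transform is causal and never
#' peeks ahead, as a predictor must not. A span of 1 returns zeros (the SD
#' of a singleton is taken as 0).
#'
#' @param series a \code{feature_series} with at least \code{span} values.
#' @param span window length in values (default 3).
#' @return a \code{feature_series} named \code{"<name>_std<span>"} of length
#'   \code{length(series) - span + 1}.
#' @export
rolling_std <- function(series, span = 3) {
  v <- series$values
  n <- length(v)
  if (span < 1) stop("span must be at least 1")
  if (n < span) stop("series of length ", n, " shorter than span ", span)
  n_out <- n - span + 1L
  if (span == 1L) {
    out <- rep(0, n_out)
  } else {
    # sample SD via running sums
    c1 <- cumsum(c(0, v)); c2 <- cumsum(c(0, v^2))
    s1 <- c1[seq_len(n_out) + span] - c1[seq_len(n_out)]
    s2 <- c2[seq_len(n_out) + span] - c2[seq_len(n_out)]
    var_ <- pmax((s2 - s1^2 / span) / (span - 1), 0)
    out <- sqrt(var_)
  }
  new_feature_series(paste0(series$name, "_std", span),
                     times = series$times[seq_len(n_out) + span - 1L],
                     values = out, window_duration = series$window_duration)
}

#' The 1D spectro_std feature of a trial
#'
#' The package's headline feature: band-pass filter, split into one-second
#' windows, estimate median frequency and total band power per window, unify
#' the two standardized streams by subtraction (\code{\link{unify_1d_spectro}})
#' and take the causal 3-s rolling standard deviation. The onset of
#' Transition-to-Fatigue makes the unified stream swing, producing spikes in
#' the rolling SD; deep in fatigue the stream settles and the values fall.
#'
#' @param trial a \code{semg_trial} at least 3 s long.
#' @param span rolling SD span in windows (default 3).
#' @param channel sEMG channel: 1 (default), 2 or \code{"mean"}.
#' @return a \code{feature_series} named \code{"spectro_std"}.
#' @export
spectro_std <- function(trial, span = 3, channel = 1) {
  validate_trial(trial)
  x <- bandpass_filter(select_channel(trial, channel), trial$fs_emg)
  mdf <- window_series(x, trial$fs_emg,
                       function(w) imdf(w, trial$fs_emg), "imdf")
  pow <- window_series(x, trial$fs_emg,
                       function(w) total_band_power(w, trial$fs_emg),
                       "bandpower")
  uni <- unify_1d_spectro(pow, mdf)
  out <- rolling_std(uni, span = span)
  out$name <- "spectro_std"
  out
}

#' Extract the full comparison feature set of a trial
#'
#' Returns the five per-second feature streams compared throughout the
#' package: \code{spectro_std} plus the four comparison features (median
#' frequency, band power, Dimitrov FI2, db3 wavelet energy), each passed
#' through the same 3-s rolling SD so all five are commensurable; they share
#' identical timestamps. Higher-order Dimitrov moments can be added via
#' \code{fi_moments}.
#'
#' @param trial a \code{semg_trial}.
#' @param span rolling SD span in windows (default 3).
#' @param channel sEMG channel: 1 (default), 2 or \code{"mean"}.
#' @param fi_moments integer vector of Dimitrov moment orders (default 2).
#' @param wavelet,level mother wavelet and decomposition depth for the
#'   wavelet feature.
#' @return named list of \code{feature_series}.
#' @export
extract_all <- function(trial, span = 3, channel = 1, fi_moments = 2,
                        wavelet = "db3", level = 12) {
  validate_trial(trial)
  x <- bandpass_filter(select_channel(trial, channel), trial$fs_emg)
  fs <- trial$fs_emg
  mdf <- window_series(x, fs, function(w) imdf(w, fs), "imdf")
  pow <- window_series(x, fs, function(w) total_band_power(w, fs), "bandpower")
  uni <- unify_1d_spectro(pow, mdf)
  sstd <- rolling_std(uni, span = span)
  sstd$name <- "spectro_std"
  out <- list(spectro_std = sstd)
  out[[paste0("imdf_std", span)]] <- rolling_std(mdf, span = span)
  out[[paste0("bandpower_std", span)]] <- rolling_std(pow, span = span)
  for (X in fi_moments) {
    fi <- window_series(x, fs, function(w) fi_nsm(w, fs, X = X),
                        paste0("fi", X))
    out[[paste0("fi", X, "_std", span)]] <- rolling_std(fi, span = span)
  }
  wv <- wavelet_feature(trial, wavelet = wavelet, level = level,
                        channel = channel, prefilter = TRUE)
  out[[paste0("wavelet_", tolower(wavelet), "_std", span)]] <-
    rolling_std(wv, span = span)
  out
}
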