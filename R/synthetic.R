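# Run expr under a private RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic 31-bit seed derivation for (subject, trial, stream) counters.
derive_seed <- function(seed, ...) {
  m <- 2147483647  # 2^31 - 1
  h <- as.numeric(seed) %% m
  for (k in c(...)) {
    # 48271 is a classic Lehmer multiplier; double precision holds the
    # intermediate exactly (< 2^53)
    h <- (h * 48271 + as.numeric(k) + 1) %% m
  }
  as.integer(h)
}

#' Configuration of the synthetic fatiguing-contraction generator
#'
#' The generator emulates an isometric biceps trial held near 90 degrees
#' elbow flexion: stationary band-limited sEMG whose median frequency
#' compresses and whose amplitude grows as fatigue develops, and a
#' goniometer trace that oscillates increasingly and finally drops below the
#' 86.5 degree fatigue boundary. Phases are Non-Fatigue \code{[0, t_tf)},
#' Transition-to-Fatigue \code{[t_tf, t_f)} and Fatigue \code{[t_f, end)}.
#'
#' @param duration_s total trial length in seconds (default 180).
#' @param t_tf Transition-to-Fatigue onset in seconds (default 100).
#' @param t_f Fatigue onset in seconds (default 150).
#' @param mdf_start,mdf_end median frequency in Hz before \code{t_tf} and at
#'   \code{t_f} (defaults 95 and 55); the target declines linearly in
#'   between and stays at \code{mdf_end} afterwards.
#' @param amp_gain relative sEMG amplitude at the end of the trial relative
#'   to the start (default 1.6); amplitude ramps linearly over the whole
#'   trial.
#' @param angle_hold elbow angle held before fatigue, degrees (default 90).
#' @param angle_end elbow angle after task failure, degrees (default 84).
#' @param decline_s seconds the angle takes to fall from \code{angle_hold}
#'   to \code{angle_end} once fatigue sets in at \code{t_f} (default 5 --
#'   task failure is rapid once it starts).
#' @param osc_sd_nf,osc_sd_tf goniometer oscillation SD in degrees before and
#'   after \code{t_tf} (defaults 0.2 and 1.0, straddling the 0.6 degree
#'   labeling boundary).
#' @param noise_sd additive goniometer sensor noise SD in degrees
#'   (default 0.05).
#' @param band_width_hz width of the band-pass shaping the sEMG noise
#'   (default 60).
#' @param fs sampling rate in Hz for both channels (default 2000).
#' @param seed integer RNG seed.
#' @return validated \code{synthetic_config} list.
#' @export
synthetic_config <- function(duration_s = 180, t_tf = 100, t_f = 150,
                             mdf_start = 95, mdf_end = 55, amp_gain = 1.6,
                             angle_hold = 90, angle_end = 84, decline_s = 5,
                             osc_sd_nf = 0.2, osc_sd_tf = 1.0,
                             noise_sd = 0.05, band_width_hz = 60,
                             fs = 2000, seed = 1) {
  cfg <- list(duration_s = duration_s, t_tf = t_tf, t_f = t_f,
              mdf_start = mdf_start, mdf_end = mdf_end, amp_gain = amp_gain,
              angle_hold = angle_hold, angle_end = angle_end,
              decline_s = decline_s, osc_sd_nf = osc_sd_nf,
              osc_sd_tf = osc_sd_tf, noise_sd = noise_sd,
              band_width_hz = band_width_hz, fs = fs, seed = seed)
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
}

#' @rdname synthetic_config
#' @param cfg a \code{synthetic_config} to validate.
#' @export
validate_synthetic_config <- function(cfg) {
  bad <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) bad <<- c(bad, msg)
  chk(cfg$t_tf > 0 && cfg$t_f > cfg$t_tf && cfg$duration_s > cfg$t_f,
      "phase times must satisfy 0 < t_tf < t_f < duration_s")
  chk(cfg$mdf_end < cfg$mdf_start, "mdf_end must be below mdf_start")
  chk(cfg$mdf_end > cfg$band_width_hz / 2,
      "mdf_end must leave the shaping band above 0 Hz")
  chk(cfg$mdf_start + cfg$band_width_hz / 2 < cfg$fs / 2,
      "mdf_start band must stay below Nyquist")
  chk(cfg$angle_end < 86.5 && 86.5 < cfg$angle_hold,
      "angles must satisfy angle_end < 86.5 < angle_hold")
  chk(cfg$osc_sd_nf < 0.6 && 0.6 < cfg$osc_sd_tf,
      "oscillation SDs must straddle the 0.6 degree boundary")
  chk(cfg$decline_s > 0 && cfg$t_f + cfg$decline_s <= cfg$duration_s,
      "decline_s must fit between t_f and the end of the trial")
  chk(cfg$noise_sd >= 0, "noise_sd must be non-negative")
  chk(cfg$amp_gain > 0, "amp_gain must be positive")
  if (length(bad)) {
    stop("invalid synthetic_config:\n  - ", paste(bad, collapse = "\n  - "))
  }
  cfg
}

# target median frequency at time t (s): flat, linear decline, flat
mdf_profile <- function(cfg, t) {
  m <- rep(cfg$mdf_start, length(t))
  ramp <- t >= cfg$t_tf & t < cfg$t_f
  m[ramp] <- cfg$mdf_start +
    (cfg$mdf_end - cfg$mdf_start) * (t[ramp] - cfg$t_tf) / (cfg$t_f - cfg$t_tf)
  m[t >= cfg$t_f] <- cfg$mdf_end
  m
}

# expected variance gain of a filter cascade for unit white noise,
# from the magnitude response on a dense two-sided grid
sos_noise_gain <- function(sos, fs, n_grid = 1024) {
  f <- (seq_len(n_grid) - 1L) / n_grid * fs
  z <- exp(-1i * 2 * pi * f / fs)
  h <- rep(1 + 0i, n_grid)
  for (i in seq_len(nrow(sos))) {
    b <- sos[i, 1:3]; a <- sos[i, 4:6]
    h <- h * (b[1] + b[2] * z + b[3] * z^2) / (a[1] + a[2] * z + a[3] * z^2)
  }
  mean(Mod(h)^2)
}

#' Generate one synthetic fatiguing-contraction trial
#'
#' sEMG: per-second blocks of Gaussian white noise shaped by a 4th-order
#' Butterworth band-pass of width \code{band_width_hz} re-designed every
#' second around the target median frequency (piecewise-stationary spectral
#' compression), normalized by the filter's expected noise gain and scaled by
#' a linear amplitude ramp reaching \code{amp_gain} at the end of the trial.
#' Goniometer: \code{angle_hold} plus low-pass (5 Hz) oscillation noise with
#' phase-dependent SD, sensor noise, and a linear drop to \code{angle_end}
#' over \code{decline_s} seconds starting at \code{t_f}. Deterministic given
#' the seed.
#'
#' @param cfg a \code{synthetic_config}.
#' @param subject_id,trial_id identifiers stamped on the trial.
#' @return list with elements \code{trial} (a \code{semg_trial}) and
#'   \code{labels} (the ground-truth \code{label_series}).
#' @export
generate_trial <- function(cfg, subject_id = "s1", trial_id = "t1") {
  validate_synthetic_config(cfg)
  fs <- cfg$fs
  n_sec <- floor(cfg$duration_s)
  n <- n_sec * fs

  out <- with_local_seed(cfg$seed, {
    # --- sEMG channels -----------------------------------------------------
    emg <- matrix(0, nrow = n, ncol = 2)
    sec_mid <- (seq_len(n_sec) - 1L) + 0.5
    targets <- mdf_profile(cfg, sec_mid)
    amp <- 1 + (cfg$amp_gain - 1) * (seq_len(n) - 1L) / (n - 1L)
    for (ch in 1:2) {
      white <- stats::rnorm(n)
      x <- numeric(n)
      for (i in seq_len(n_sec)) {
        idx <- seq((i - 1L) * fs + 1L, i * fs)
        sos <- butter_bandpass_sos(4, targets[i] - cfg$band_width_hz / 2,
                                   targets[i] + cfg$band_width_hz / 2, fs)
        blk <- sos_filter(sos, white[idx])
        x[idx] <- blk / sqrt(sos_noise_gain(sos, fs))
      }
      emg[, ch] <- x * amp
    }

    # --- goniometer --------------------------------------------------------
    t <- (seq_len(n) - 1L) / fs
    osc_raw <- sos_filter(butter_bandpass_sos(2, 0.1, 5, fs), stats::rnorm(n))
    osc_unit <- osc_raw / stats::sd(osc_raw)
    osc_scale <- ifelse(t < cfg$t_tf, cfg$osc_sd_nf, cfg$osc_sd_tf)
    drop_frac <- pmin(pmax((t - cfg$t_f) / cfg$decline_s, 0), 1)
    angle <- cfg$angle_hold + (cfg$angle_end - cfg$angle_hold) * drop_frac +
      osc_unit * osc_scale
    if (cfg$noise_sd > 0) angle <- angle + stats::rnorm(n, sd = cfg$noise_sd)
    angle <- pmin(pmax(angle, 0), 180)
    list(emg = emg, angle = angle)
  })

  trial <- new_trial(out$emg, out$angle, fs_emg = fs, fs_gonio = fs,
                     subject_id = subject_id, trial_id = trial_id)
  # ground truth by the majority class of each whole second
  sec_mid <- (seq_len(n_sec) - 1L) + 0.5
  gt <- ifelse(sec_mid < cfg$t_tf, "NF", ifelse(sec_mid < cfg$t_f, "TF", "F"))
  list(trial = trial, labels = new_label_series(gt))
}

#' Generate a cohort of synthetic subjects
#'
#' Mirrors the original acquisition design (ten participants, three trials
#' each). Subject-level parameters are drawn once per subject by perturbing
#' the base configuration within \code{+/- jitter} relative (phase onsets,
#' spectral end points, amplitude gain and fatigue-phase oscillation;
#' angle boundaries and the pre-fatigue oscillation stay fixed so the
#' labeling geometry is preserved). Phase onsets are rounded to whole
#' seconds so ground-truth boundaries stay aligned with the per-second
#' windows. Every trial's seed derives deterministically from \code{seed}.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param trials_per_subject trials per subject (>= 1).
#' @param base base \code{synthetic_config}.
#' @param jitter relative spread in \code{[0, 0.5)} (default 0.1).
#' @param seed cohort seed.
#' @return list of \code{list(trial =, labels =, config =)} entries.
#' @export
generate_cohort <- function(n_subjects, trials_per_subject,
                            base = synthetic_config(), jitter = 0.1,
                            seed = 1) {
  stopifnot(n_subjects >= 1, trials_per_subject >= 1)
  if (!(jitter >= 0 && jitter < 0.5)) stop("jitter must be in [0, 0.5)")
  out <- vector("list", n_subjects * trials_per_subject)
  k <- 0L
  for (s in seq_len(n_subjects)) {
    u <- with_local_seed(derive_seed(seed, s, 0), stats::runif(6, -1, 1))
    cfg_s <- base
    cfg_s$t_tf <- round(base$t_tf * (1 + jitter * u[1]))
    cfg_s$t_f <- round(base$t_f * (1 + jitter * u[2]))
    cfg_s$mdf_start <- base$mdf_start * (1 + jitter * u[3])
    cfg_s$mdf_end <- base$mdf_end * (1 + jitter * u[4])
    cfg_s$amp_gain <- base$amp_gain * (1 + jitter * u[5])
    cfg_s$osc_sd_tf <- base$osc_sd_tf * (1 + jitter * u[6])
    validate_synthetic_config(cfg_s)
    for (tr in seq_len(trials_per_subject)) {
      cfg_t <- cfg_s
      cfg_t$seed <- derive_seed(seed, s, tr)
      k <- k + 1L
      gen <- generate_trial(cfg_t, subject_id = sprintf("s%02d", s),
                            trial_id = sprintf("t%d", tr))
      gen$config <- cfg_t
      out[[k]] <- gen
    }
  }
  out
}
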