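#' semgfatigue: sEMG muscle-fatigue prediction and detection
#'
#' Tools for detecting and predicting localized muscle fatigue from surface
#' electromyography (sEMG) recorded during isometric contraction, together
#' with a synthetic trial generator for end-to-end testing. The pipeline
#' labels each second of a trial as Non-Fatigue (NF), Transition-to-Fatigue
#' (TF) or Fatigue (F) using a six-rule type-1 fuzzy classifier driven by
#' elbow-angle kinematics, extracts a family of per-second spectral fatigue
#' features -- including the composite "1D spectro_std" feature (rolling
#' standard deviation of the unified band-power / median-frequency stream) --
#' and evaluates pairwise class separability with Fisher linear discriminant
#' analysis and a Davies-Bouldin-style index.
#'
#' @docType package
#' @name semgfatigue
#' @keywords internal
"_PACKAGE"

#' Fatigue class levels, least to most severe
#'
#' The three per-second states of a fatiguing contraction: \code{"NF"}
#' (Non-Fatigue), \code{"TF"} (Transition-to-Fatigue) and \code{"F"}
#' (Fatigue). Severity is total: NF < TF < F. Ties anywhere in the package
#' resolve toward the more severe class (conservative toward detecting
#' fatigue).
#'
#' @export
FATIGUE_LEVELS <- c("NF", "TF", "F")

#' Convert labels to an ordered fatigue factor
#'
#' @param x character vector with values in \code{"NF"}, \code{"TF"},
#'   \code{"F"}.
#' @return ordered factor with severity order NF < TF < F.
#' @export
fatigue_class <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), FATIGUE_LEVELS)
  if (length(bad)) {
    stop("unknown fatigue label(s): ", paste(bad, collapse = ", "),
         " (expected NF, TF or F)")
  }
  factor(x, levels = FATIGUE_LEVELS, ordered = TRUE)
}

#' Construct a trial (two-channel sEMG plus goniometer)
#'
#' A trial bundles synchronized recordings from one fatiguing contraction:
#' two double-differential sEMG channels in mV and the elbow-angle
#' goniometer trace in degrees, all sharing one clock.
#'
#' @param emg numeric matrix, samples x 2 channels, in mV.
#' @param gonio_angle numeric vector of elbow angles in degrees, in
#'   \code{[0, 180]}.
#' @param fs_emg,fs_gonio sampling rates in Hz (both default 2000; the
#'   acquisition records both streams simultaneously on one clock).
#' @param subject_id,trial_id identifiers carried through the pipeline.
#' @return object of class \code{semg_trial}.
#' @export
new_trial <- function(emg, gonio_angle, fs_emg = 2000, fs_gonio = 2000,
                      subject_id = "s1", trial_id = "t1") {
  emg <- as.matrix(emg)
  trial <- structure(
    list(subject_id = as.character(subject_id),
         trial_id = as.character(trial_id),
         fs_emg = fs_emg, fs_gonio = fs_gonio,
         emg = emg, gonio_angle = as.numeric(gonio_angle)),
    class = "semg_trial")
  validate_trial(trial)
}

#' Validate a trial object
#'
#' Checks the invariants every downstream stage relies on: positive sampling
#' rates, two equal-length finite sEMG channels, goniometer angles inside
#' \code{[0, 180]} degrees, and sEMG / goniometer durations agreeing to
#' within one sample period.
#'
#' @param trial a \code{semg_trial}.
#' @return the trial, invisibly unchanged, or an error.
#' @export
validate_trial <- function(trial) {
  stopifnot(inherits(trial, "semg_trial"))
  if (!(is.numeric(trial$fs_emg) && trial$fs_emg > 0) ||
      !(is.numeric(trial$fs_gonio) && trial$fs_gonio > 0)) {
    stop("sampling rates must be positive")
  }
  if (!is.matrix(trial$emg) || ncol(trial$emg) != 2L) {
    stop("emg must be a samples x 2 matrix (two DD channels)")
  }
  if (nrow(trial$emg) == 0L) stop("trial has no sEMG samples")
  if (!all(is.finite(trial$emg))) stop("emg contains non-finite samples")
  if (!all(is.finite(trial$gonio_angle))) {
    stop("gonio_angle contains non-finite samples")
  }
  if (any(trial$gonio_angle < 0 | trial$gonio_angle > 180)) {
    stop("gonio_angle outside [0, 180] degrees")
  }
  dur_emg <- nrow(trial$emg) / trial$fs_emg
  dur_gon <- length(trial$gonio_angle) / trial$fs_gonio
  if (abs(dur_emg - dur_gon) > 1 / min(trial$fs_emg, trial$fs_gonio) + 1e-12) {
    stop("sEMG duration (", dur_emg, " s) and goniometer duration (",
         dur_gon, " s) disagree by more than one sample period")
  }
  invisible(trial)
}

#' @export
print.semg_trial <- function(x, ...) {
  cat("<semg_trial> subject", x$subject_id, "trial", x$trial_id, "--",
      nrow(x$emg), "samples @", x$fs_emg, "Hz (",
      round(nrow(x$emg) / x$fs_emg, 2), "s )\n")
  invisible(x)
}

#' Construct a per-window label series
#'
#' @param labels character or factor vector of \code{"NF"}, \code{"TF"},
#'   \code{"F"} values, one per window.
#' @param window_duration window length in seconds (default 1).
#' @param start_time start time of the first window in seconds.
#' @return object of class \code{label_series} (an ordered factor with
#'   attributes).
#' @export
new_label_series <- function(labels, window_duration = 1, start_time = 0) {
  if (length(labels) == 0L) stop("labels must be non-empty")
  if (!(window_duration > 0)) stop("window_duration must be positive")
  structure(list(labels = fatigue_class(labels),
                 window_duration = window_duration,
                 start_time = start_time),
            class = "label_series")
}

#' Window start times of a label series
#' @param ls a \code{label_series}.
#' @return numeric vector of window start times in seconds.
#' @export
label_times <- function(ls) {
  ls$start_time + (seq_along(ls$labels) - 1L) * ls$window_duration
}

#' @export
print.label_series <- function(x, ...) {
  cat("<label_series>", length(x$labels), "windows of", x$window_duration,
      "s:", paste(table(x$labels), collapse = "/"),
      paste0("(", paste(levels(x$labels), collapse = "/"), ")\n"))
  invisible(x)
}

#' Construct a per-window scalar feature series
#'
#' @param name feature name (e.g. \code{"spectro_std"}).
#' @param times window start times in seconds, strictly increasing.
#' @param values finite scalar feature values, one per time.
#' @param window_duration window length in seconds (default 1).
#' @return object of class \code{feature_series}.
#' @export
new_feature_series <- function(name, times, values, window_duration = 1) {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop("times and values must have equal length")
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("times must be strictly increasing")
  }
  if (!all(is.finite(values))) stop("feature values must be finite")
  structure(list(name = as.character(name), window_duration = window_duration,
                 times = times, values = values),
            class = "feature_series")
}

#' @export
print.feature_series <- function(x, ...) {
  cat("<feature_series>", x$name, "--", length(x$values), "windows, range [",
      signif(min(x$values), 4), ",", signif(max(x$values), 4), "]\n")
  invisible(x)
}

# ---- CSV interchange ------------------------------------------------------
# Trial CSV:   time_s,emg_ch1_mV,emg_ch2_mV,gonio_deg
# Label CSV:   window_start_s,label           (label in NF/TF/F)
# Feature CSV: "# name=<feature>" comment, then window_start_s,value

#' Read a trial from CSV
#'
#' Expects the header \code{time_s,emg_ch1_mV,emg_ch2_mV,gonio_deg}, one row
#' per sample, '.' decimal separator. The sampling rate is recovered from the
#' median time step.
#'
#' @param path CSV file path.
#' @param subject_id,trial_id identifiers; defaults are parsed from the file
#'   name when it looks like \code{<subject>_<trial>.csv}.
#' @return a validated \code{semg_trial}.
#' @export
read_trial <- function(path, subject_id = NULL, trial_id = NULL) {
  if (!file.exists(path)) stop("no such trial file: ", path)
  dt <- data.table::fread(path, sep = ",", header = TRUE)
  need <- c("time_s", "emg_ch1_mV", "emg_ch2_mV", "gonio_deg")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols)) {
    stop("trial CSV ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in need) {
    v <- dt[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))[1]
      stop("non-numeric value in column '", col, "' at data row ",
           if (is.na(bad)) "?" else bad, " of ", path)
    }
  }
  if (nrow(dt) < 2L) stop("trial CSV ", path, " has fewer than 2 samples")
  fs <- 1 / stats::median(diff(dt$time_s))
  ids <- strsplit(sub("\\.csv$", "", basename(path)), "_")[[1]]
  if (is.null(subject_id)) subject_id <- if (length(ids) >= 2) ids[1] else "s1"
  if (is.null(trial_id)) {
    trial_id <- if (length(ids) >= 2) paste(ids[-1], collapse = "_") else "t1"
  }
  new_trial(emg = cbind(dt$emg_ch1_mV, dt$emg_ch2_mV),
            gonio_angle = dt$gonio_deg, fs_emg = round(fs, 6),
            fs_gonio = round(fs, 6),
            subject_id = subject_id, trial_id = trial_id)
}

#' Write a trial to CSV
#'
#' Inverse of \code{\link{read_trial}}; the written file round-trips to
#' better than 1e-9 mV / degrees.
#'
#' @param trial a validated \code{semg_trial}.
#' @param path destination path.
#' @return \code{path}, invisibly.
#' @export
write_trial <- function(trial, path) {
  validate_trial(trial)
  if (nrow(trial$emg) == 0L) stop("refusing to write an empty trial")
  # one row per sample carries both streams; durations may legally differ by
  # one sample period, so truncate to the common length
  n <- min(nrow(trial$emg), length(trial$gonio_angle))
  dt <- data.table::data.table(
    time_s = (seq_len(n) - 1L) / trial$fs_emg,
    emg_ch1_mV = trial$emg[seq_len(n), 1], emg_ch2_mV = trial$emg[seq_len(n), 2],
    gonio_deg = trial$gonio_angle[seq_len(n)])
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read / write a label series CSV
#'
#' @param path CSV with header \code{window_start_s,label}.
#' @return a \code{label_series}.
#' @export
read_label_series <- function(path) {
  dt <- data.table::fread(path, sep = ",", header = TRUE)
  if (!all(c("window_start_s", "label") %in% names(dt))) {
    stop("label CSV ", path, " must have columns window_start_s,label")
  }
  wd <- if (nrow(dt) > 1) stats::median(diff(dt$window_start_s)) else 1
  new_label_series(dt$label, window_duration = wd,
                   start_time = dt$window_start_s[1])
}

#' @rdname read_label_series
#' @param ls a \code{label_series} to write.
#' @export
write_label_series <- function(ls, path) {
  dt <- data.table::data.table(window_start_s = label_times(ls),
                               label = as.character(ls$labels))
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read / write a feature series CSV
#'
#' Feature CSVs carry a \code{# name=<feature>} comment line before the
#' \code{window_start_s,value} header.
#'
#' @param path CSV file path.
#' @return a \code{feature_series}.
#' @export
read_feature_series <- function(path) {
  first <- readLines(path, n = 1L)
  name <- if (grepl("^# name=", first)) sub("^# name=", "", first) else "feature"
  dt <- data.table::fread(path, sep = ",", header = TRUE, skip = "window_start_s")
  wd <- if (nrow(dt) > 1) stats::median(diff(dt$window_start_s)) else 1
  new_feature_series(name, dt$window_start_s, dt$value, window_duration = wd)
}

#' @rdname read_feature_series
#' @param fs_obj a \code{feature_series} to write.
#' @export
write_feature_series <- function(fs_obj, path) {
  con <- file(path, "w")
  writeLines(paste0("# name=", fs_obj$name), con)
  close(con)
  dt <- data.table::data.table(window_start_s = fs_obj$times,
                               value = fs_obj$values)
  data.table::fwrite(dt, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Reduce per-sample labels to per-second labels by majority vote
#'
#' Splits the per-sample label stream into whole one-second blocks (the
#' trailing partial second is dropped) and assigns each second the majority
#' label of its samples; ties resolve to the more severe class.
#'
#' @param labels_per_sample character/factor vector of per-sample labels.
#' @param fs sampling rate in Hz.
#' @param window_s window length in seconds (default 1).
#' @return a \code{label_series}.
#' @export
align_labels_to_seconds <- function(labels_per_sample, fs, window_s = 1) {
  if (fs <= 0) stop("fs must be positive")
  lab <- fatigue_class(labels_per_sample)
  n_win <- floor(length(lab) / (fs * window_s))
  if (n_win < 1L) stop("label sequence shorter than one window")
  wlen <- round(fs * window_s)
  out <- character(n_win)
  for (i in seq_len(n_win)) {
    block <- lab[seq((i - 1L) * wlen + 1L, i * wlen)]
    counts <- tabulate(block, nbins = 3L)
    # which.max on the reversed counts prefers the more severe class on ties
    out[i] <- FATIGUE_LEVELS[4L - which.max(rev(counts))]
  }
  new_label_series(out, window_duration = window_s, start_time = 0)
}
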