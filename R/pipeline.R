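default_pipeline_config <- function() {
  list(
    simulate = list(n_subjects = 3, trials_per_subject = 2, jitter = 0.1,
                    seed = 1,
                    duration_s = 120, t_tf = 60, t_f = 96,
                    mdf_start = 95, mdf_end = 55, amp_gain = 1.6,
                    angle_hold = 90, angle_end = 84, decline_s = 5,
                    osc_sd_nf = 0.2, osc_sd_tf = 1.0, noise_sd = 0.05,
                    band_width_hz = 60, fs = 2000),
    filter = list(low_hz = 1, high_hz = 500, order = 5),
    fuzzy = list(angle_nf = c(86.5, 89, 180, 180),
                 angle_tf = c(86.5, 87.75, 89),
                 angle_f = c(0, 0, 86.5, 89),
                 osc_low = c(0, 0, 0.4, 0.8),
                 osc_high = c(0.4, 0.8, 1e6, 1e6),
                 osc_window_s = 4),
    features = list(span_s = 3, channel = 1, fi_moments = 2,
                    wavelet = "db3", level = 12),
    classify = list(train_frac = 0.5,
                    pairs = list(c("NF", "TF"), c("TF", "F"))),
    report = list(reference_feature = "spectro_std", dbi_spans = 1:5))
}

modify_list <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(base[[nm]]) && is.list(new[[nm]]) &&
        !is.null(names(new[[nm]]))) {
      base[[nm]] <- modify_list(base[[nm]], new[[nm]])
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}

#' Read and validate a pipeline configuration
#'
#' YAML with sections \code{simulate}, \code{filter}, \code{fuzzy},
#' \code{features}, \code{classify}, \code{report}; unspecified keys take
#' package defaults (see \code{inst/extdata/quickstart.yaml} for a commented
#' template carrying every labeling and filtering constant). Validation runs
#' before any computation.
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @param overrides named list merged over the file (e.g. a seed).
#' @return validated config list.
#' @export
read_pipeline_config <- function(path = NULL, overrides = list()) {
  cfg <- default_pipeline_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config file: ", path)
    cfg <- modify_list(cfg, yaml::read_yaml(path))
  }
  cfg <- modify_list(cfg, overrides)
  sim <- cfg$simulate
  do.call(synthetic_config,
          sim[setdiff(names(sim), c("n_subjects", "trials_per_subject",
                                    "jitter"))])
  if (!(cfg$filter$low_hz < cfg$filter$high_hz)) {
    stop("filter.low_hz must be below filter.high_hz")
  }
  cfg
}

fuzzy_params_from_config <- function(fz) {
  list(angle = list(NF = do.call(trap_mf, as.list(fz$angle_nf)),
                    TF = do.call(tri_mf, as.list(fz$angle_tf)),
                    F = do.call(trap_mf, as.list(fz$angle_f))),
       osc = list(Low = do.call(trap_mf, as.list(fz$osc_low)),
                  High = do.call(trap_mf, as.list(fz$osc_high))))
}

#' Run the full pipeline: simulate, label, extract, classify, report
#'
#' Executes every stage on a synthetic cohort (or on user trial CSVs placed
#' in \code{<out_dir>/trials} beforehand with \code{simulate: FALSE} -- any
#' file readable by \code{\link{read_trial}} works), persisting all
#' intermediates so every number in the final report can be recomputed from
#' files on disk: trial CSVs, ground-truth and fuzzy label CSVs, one feature
#' CSV per trial and feature, the per-subject classification table, the
#' summary report (CSV + Markdown) and a JSON run manifest with the config
#' echo, package version, seeds and per-stage wall times.
#'
#' @param config config list from \code{\link{read_pipeline_config}}, or a
#'   YAML path.
#' @param out_dir output directory (created if needed).
#' @param seed optional override of \code{simulate.seed}.
#' @return \code{out_dir}, invisibly.
#' @export
run_pipeline <- function(config = NULL, out_dir = "semg_run", seed = NULL) {
  if (is.null(config) || is.character(config)) {
    config <- read_pipeline_config(config)
  }
  if (!is.null(seed)) config$simulate$seed <- seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (d in c("trials", "labels", "features")) {
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  }
  stage_time <- list()
  tick <- function(stage, expr) {
    t0 <- Sys.time()
    r <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    stage_time[[stage]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 2)
    r
  }

  sim <- config$simulate
  cohort <- tick("simulate", {
    base <- do.call(synthetic_config,
                    sim[setdiff(names(sim),
                                c("n_subjects", "trials_per_subject",
                                  "jitter"))])
    ch <- generate_cohort(sim$n_subjects, sim$trials_per_subject, base,
                          jitter = sim$jitter, seed = sim$seed)
    for (g in ch) {
      id <- paste0(g$trial$subject_id, "_", g$trial$trial_id)
      write_trial(g$trial, file.path(out_dir, "trials", paste0(id, ".csv")))
      write_label_series(g$labels,
                         file.path(out_dir, "labels",
                                   paste0(id, "_truth.csv")))
    }
    ch
  })

  fuzzy_params <- fuzzy_params_from_config(config$fuzzy)
  cohort <- tick("label", {
    for (i in seq_along(cohort)) {
      g <- cohort[[i]]
      lab <- label_trial(g$trial, params = fuzzy_params,
                         osc_window_s = config$fuzzy$osc_window_s)
      id <- paste0(g$trial$subject_id, "_", g$trial$trial_id)
      write_label_series(lab, file.path(out_dir, "labels",
                                        paste0(id, "_fuzzy.csv")))
      cohort[[i]]$labels <- lab   # classification uses the automated labels
    }
    cohort
  })

  fc <- config$features
  cohort <- tick("extract", {
    for (i in seq_along(cohort)) {
      g <- cohort[[i]]
      feats <- extract_all(g$trial, span = fc$span_s, channel = fc$channel,
                           fi_moments = fc$fi_moments, wavelet = fc$wavelet,
                           level = fc$level)
      id <- paste0(g$trial$subject_id, "_", g$trial$trial_id)
      for (nm in names(feats)) {
        write_feature_series(feats[[nm]],
                             file.path(out_dir, "features",
                                       paste0(id, "_", nm, ".csv")))
      }
      cohort[[i]]$features <- feats
    }
    cohort
  })

  results <- tick("classify", {
    pairs <- lapply(config$classify$pairs, unlist)
    res <- run_cohort(cohort, pairs = pairs,
                      train_frac = config$classify$train_frac)
    data.table::fwrite(res, file.path(out_dir, "classification.csv"))
    res
  })

  tick("report", {
    lines <- c("# Fatigue classification report", "")
    for (pr in unique(results$pair)) {
      sub <- results[results$pair == pr, ]
      tbl <- stats::reshape(sub[, c("subject", "feature", "percent_correct")],
                            idvar = "subject", timevar = "feature",
                            direction = "wide")
      rn <- tbl$subject
      tbl <- as.matrix(tbl[, -1, drop = FALSE])
      colnames(tbl) <- sub("^percent_correct\\.", "", colnames(tbl))
      rownames(tbl) <- rn
      summ <- summarize_percent_correct(tbl)
      imp <- improvements(summ, config$report$reference_feature)
      out <- rbind(round_half_up(tbl, 2), AVG = summ$mean_2dp,
                   STDEV = summ$sd_2dp)
      fn <- paste0("report_", gsub("/", "_", pr))
      utils::write.csv(out, file.path(out_dir, paste0(fn, ".csv")))
      cm <- confusion_matrix(
        a = round(mean(tapply(sub$a[sub$feature == imp$reference],
                              sub$subject[sub$feature == imp$reference],
                              sum))),
        b = round(mean(tapply(sub$b[sub$feature == imp$reference],
                              sub$subject[sub$feature == imp$reference],
                              sum))),
        c = round(mean(tapply(sub$c[sub$feature == imp$reference],
                              sub$subject[sub$feature == imp$reference],
                              sum))),
        d = round(mean(tapply(sub$d[sub$feature == imp$reference],
                              sub$subject[sub$feature == imp$reference],
                              sum))))
      rt <- rates(cm)
      lines <- c(lines, paste0("## Pair ", pr), "",
                 paste0("| feature | mean %% | sd |"),
                 "|---|---|---|",
                 sprintf("| %s | %.2f | %.2f |", colnames(tbl),
                         summ$mean_2dp, summ$sd_2dp), "",
                 sprintf("Confusion (seconds, averaged per subject, %s): a=%d b=%d c=%d d=%d",
                         imp$reference, cm$a, cm$b, cm$c, cm$d),
                 sprintf("Rates: TP=%.2f FP=%.2f TN=%.2f FN=%.2f P=%.2f acc=%.2f",
                         rt$tp, rt$fp, rt$tn, rt$fn, rt$precision,
                         rt$accuracy), "",
                 sprintf("Improvement of %s vs others' average: %.2f (p=%.3g, %s)",
                         imp$reference, imp$vs_others_avg$delta_2dp,
                         imp$vs_others_avg$p_value, imp$test), "")
    }
    writeLines(lines, file.path(out_dir, "report.md"))
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("semgfatigue")),
    generated = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
    seed = sim$seed, config = config, stage_seconds = stage_time)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

# ---- command-line entry ----------------------------------------------------

cli_usage <- function() {
  cat("usage: semgfatigue <verb> [--config FILE] [--out DIR] [--seed N] [--in FILE]\n",
      "verbs: simulate | label | extract | classify | report | run\n", sep = "")
}

parse_cli_args <- function(args) {
  opts <- list(config = NULL, out = "semg_run", seed = NULL, input = NULL)
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (a %in% c("--config", "--out", "--seed", "--in")) {
      if (i == length(args)) stop("missing value for ", a)
      val <- args[i + 1L]; i <- i + 2L
      switch(a,
             "--config" = opts$config <- val,
             "--out" = opts$out <- val,
             "--seed" = opts$seed <- as.integer(val),
             "--in" = opts$input <- val)
    } else stop("unknown argument: ", a)
  }
  opts
}

# Entry point used by exec/semgfatigue. Returns an exit code:
# 0 success, 2 validation/usage error, 1 runtime error.
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) { cli_usage(); return(2L) }
  verb <- args[1]
  code <- tryCatch({
    opts <- parse_cli_args(args[-1])
    cfg <- read_pipeline_config(opts$config,
                                if (is.null(opts$seed)) list()
                                else list(simulate = list(seed = opts$seed)))
    switch(verb,
      run = run_pipeline(cfg, opts$out),
      simulate = {
        sim <- cfg$simulate
        base <- do.call(synthetic_config,
                        sim[setdiff(names(sim),
                                    c("n_subjects", "trials_per_subject",
                                      "jitter"))])
        ch <- generate_cohort(sim$n_subjects, sim$trials_per_subject, base,
                              jitter = sim$jitter, seed = sim$seed)
        dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
        for (g in ch) {
          id <- paste0(g$trial$subject_id, "_", g$trial$trial_id)
          write_trial(g$trial, file.path(opts$out, paste0(id, ".csv")))
          write_label_series(g$labels,
                             file.path(opts$out, paste0(id, "_truth.csv")))
        }
      },
      label = {
        if (is.null(opts$input)) stop("label needs --in <trial.csv>")
        tr <- read_trial(opts$input)
        lab <- label_trial(tr, params = fuzzy_params_from_config(cfg$fuzzy),
                           osc_window_s = cfg$fuzzy$osc_window_s)
        dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
        write_label_series(lab, file.path(opts$out,
          paste0(sub("\\.csv$", "", basename(opts$input)), "_labels.csv")))
      },
      extract = {
        if (is.null(opts$input)) stop("extract needs --in <trial.csv>")
        tr <- read_trial(opts$input)
        fc <- cfg$features
        feats <- extract_all(tr, span = fc$span_s, channel = fc$channel,
                             fi_moments = fc$fi_moments,
                             wavelet = fc$wavelet, level = fc$level)
        dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
        base_id <- sub("\\.csv$", "", basename(opts$input))
        for (nm in names(feats)) {
          write_feature_series(feats[[nm]],
            file.path(opts$out, paste0(base_id, "_", nm, ".csv")))
        }
      },
      classify = ,
      report = run_pipeline(cfg, opts$out),
      { cli_usage(); return(2L) })
    0L
  },
  error = function(e) {
    msg <- conditionMessage(e)
    message("error: ", msg)
    if (grepl("invalid|must|unknown|missing|needs", msg)) 2L else 1L
  })
  code
}
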