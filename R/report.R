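#' Confusion matrix in seconds
#'
#' The four cells of the two-class confusion table: \code{a} correct
#' negatives, \code{b} incorrect positives, \code{c} incorrect negatives,
#' \code{d} correct positives, counted in seconds. The more severe fatigue
#' class of a pair is the positive.
#'
#' @param a,b,c,d non-negative cell counts.
#' @param positive label of the positive class (optional bookkeeping).
#' @return object of class \code{confusion_matrix}.
#' @export
confusion_matrix <- function(a, b, c, d, positive = NULL) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) stop("confusion cells must be non-negative")
  structure(list(a = a, b = b, c = c, d = d, positive = positive),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("actual -", "actual +"),
                              c("pred -", "pred +")))
  print(m)
  invisible(x)
}

#' Classification rates from a confusion matrix
#'
#' True/false positive and negative rates, precision and accuracy:
#' \code{TP = d/(c+d)}, \code{FP = b/(a+b)}, \code{TN = a/(a+b)},
#' \code{FN = c/(c+d)}, \code{P = d/(b+d)},
#' \code{accuracy = (a+d)/(a+b+c+d)}. A rate whose denominator is zero is
#' returned as \code{NA} (flagged undefined) while the others are still
#' computed.
#'
#' @param cm a \code{\link{confusion_matrix}}.
#' @return list with \code{tp, fp, tn, fn, precision, accuracy}.
#' @export
rates <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$a + cm$b + cm$c + cm$d
  if (total <= 0) stop("empty confusion matrix")
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  list(tp = safe(cm$d, cm$c + cm$d),
       fp = safe(cm$b, cm$a + cm$b),
       tn = safe(cm$a, cm$a + cm$b),
       fn = safe(cm$c, cm$c + cm$d),
       precision = safe(cm$d, cm$b + cm$d),
       accuracy = (cm$a + cm$d) / total)
}

#' Cluster separability index (spread-over-distance variant)
#'
#' The separability measure used throughout the package, implemented exactly
#' as the evaluation defines it: the numerator sums, over clusters, the
#' sample SD of the Euclidean distances from each member to its own
#' centroid; the denominator is the Euclidean distance between the two
#' cluster centroids. Lower values mean better-separated classes. Note this
#' differs from the textbook Davies-Bouldin index, which is provided
#' separately as \code{\link{dbi_canonical}} for comparison.
#'
#' @param clusters list of numeric vectors or matrices (rows = members).
#' @return non-negative scalar.
#' @export
dbi <- function(clusters) {
  if (length(clusters) != 2L) {
    stop("this separability index is defined for exactly two clusters")
  }
  mats <- lapply(clusters, function(cl) {
    m <- as.matrix(cl)
    if (nrow(m) < 1L) stop("empty cluster")
    m
  })
  centroids <- lapply(mats, colMeans)
  spread <- vapply(seq_along(mats), function(i) {
    d <- sqrt(rowSums(sweep(mats[[i]], 2, centroids[[i]])^2))
    if (length(d) > 1L) stats::sd(d) else 0
  }, numeric(1))
  between <- sqrt(sum((centroids[[1]] - centroids[[2]])^2))
  if (between == 0) stop("coincident centroids: separation undefined")
  sum(spread) / between
}

#' Canonical Davies-Bouldin index
#'
#' The standard clustering index: mean over clusters of the worst-case
#' \code{(s_i + s_j) / d_ij} ratio, with \code{s_i} the mean member-centroid
#' distance. Included so the package's \code{\link{dbi}} variant can be
#' compared against the textbook definition.
#'
#' @param clusters list of numeric vectors or matrices (rows = members).
#' @return non-negative scalar.
#' @export
dbi_canonical <- function(clusters) {
  k <- length(clusters)
  if (k < 2L) stop("need at least two clusters")
  mats <- lapply(clusters, as.matrix)
  centroids <- lapply(mats, colMeans)
  s <- vapply(seq_len(k), function(i) {
    mean(sqrt(rowSums(sweep(mats[[i]], 2, centroids[[i]])^2)))
  }, numeric(1))
  r <- numeric(k)
  for (i in seq_len(k)) {
    worst <- 0
    for (j in seq_len(k)) {
      if (j == i) next
      dij <- sqrt(sum((centroids[[i]] - centroids[[j]])^2))
      if (dij == 0) stop("coincident centroids")
      worst <- max(worst, (s[i] + s[j]) / dij)
    }
    r[i] <- worst
  }
  mean(r)
}

#' Separability of a class pair across rolling-SD spans
#'
#' For each span s in \code{spans}, transforms the unified 1D spectro stream
#' with a rolling SD of that span (span 1 keeps the raw unified values --
#' the SD of a single point is identically zero, so the raw stream is the
#' meaningful one-second entry), groups the values by their second's label
#' and evaluates \code{\link{dbi}} on the two groups.
#'
#' @param unified the unified \code{feature_series} of a trial.
#' @param labels the trial's \code{label_series}.
#' @param pair two fatigue classes (default \code{c("NF", "TF")}).
#' @param spans integer spans to sweep (default 1:5).
#' @return named numeric vector, one index value per span.
#' @export
dbi_window_sweep <- function(unified, labels, pair = c("NF", "TF"),
                             spans = 1:5) {
  stopifnot(length(pair) == 2L)
  lt <- label_times(labels)
  out <- stats::setNames(numeric(length(spans)), spans)
  for (i in seq_along(spans)) {
    s <- spans[i]
    f <- if (s == 1L) unified else rolling_std(unified, span = s)
    m <- match(round(f$times), round(lt))
    lab <- as.character(labels$labels)[m]
    g1 <- f$values[!is.na(m) & lab == pair[1]]
    g2 <- f$values[!is.na(m) & lab == pair[2]]
    if (!length(g1) || !length(g2)) {
      stop("span ", s, ": a class of the pair has no seconds")
    }
    out[i] <- dbi(list(g1, g2))
  }
  out
}

# half-up rounding for display (R's round() is round-half-even)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# truncation to 2 dp: reproduces the original report's printed improvement
# deltas, which floor rather than round (e.g. 20.588 -> 20.58, 8.149 -> 8.14)
trunc2 <- function(x) trunc(x * 100 + 1e-9 * sign(x)) / 100

#' Summarize a per-subject percent-correct table
#'
#' Column means and sample SDs of a subjects x features percent-correct
#' table, with 2-dp half-up rounded display values alongside the unrounded
#' statistics.
#'
#' @param tbl numeric matrix or data.frame, rows = subjects, columns =
#'   features.
#' @return object of class \code{comparison_summary}: list with the table,
#'   \code{mean}, \code{sd} (unrounded) and \code{mean_2dp}, \code{sd_2dp}.
#' @export
summarize_percent_correct <- function(tbl) {
  m <- as.matrix(tbl)
  if (nrow(m) < 2L) stop("need at least 2 subjects")
  if (any(!is.finite(m))) stop("percent-correct table has missing cells")
  mu <- colMeans(m)
  sdv <- apply(m, 2L, stats::sd)
  structure(list(table = m, mean = mu, sd = sdv,
                 mean_2dp = round_half_up(mu, 2),
                 sd_2dp = round_half_up(sdv, 2)),
            class = "comparison_summary")
}

#' @export
print.comparison_summary <- function(x, ...) {
  out <- rbind(x$table, AVG = x$mean_2dp, STDEV = x$sd_2dp)
  print(round(out, 2))
  invisible(x)
}

#' Improvement of a reference feature over the others
#'
#' For each non-reference column, the delta of unrounded column means
#' (reference minus other), plus the delta against the average of the other
#' columns' means, each with a two-sided paired t-test across subjects.
#' Display deltas are truncated to 2 dp (\code{*_2dp}), matching how the
#' original report's printed improvements were evidently derived. Deltas
#' between identical columns are 0 with an undefined (NA) p-value.
#'
#' @param summary a \code{\link{summarize_percent_correct}} result.
#' @param reference_feature reference column name (default
#'   \code{"spectro_std"}).
#' @return list with per-feature \code{delta}, \code{delta_2dp},
#'   \code{p_value}, and \code{vs_others_avg} (delta, delta_2dp, p_value),
#'   plus \code{test = "paired t-test"}.
#' @export
improvements <- function(summary, reference_feature = "spectro_std") {
  stopifnot(inherits(summary, "comparison_summary"))
  m <- summary$table
  if (!(reference_feature %in% colnames(m))) {
    stop("reference feature '", reference_feature, "' not in table")
  }
  ref <- m[, reference_feature]
  others <- setdiff(colnames(m), reference_feature)
  per <- lapply(others, function(f) {
    delta <- mean(ref) - mean(m[, f])
    p <- if (isTRUE(all.equal(ref, m[, f]))) NA_real_ else {
      stats::t.test(ref, m[, f], paired = TRUE)$p.value
    }
    list(delta = delta, delta_2dp = trunc2(delta), p_value = p)
  })
  names(per) <- others
  other_avg <- rowMeans(m[, others, drop = FALSE])
  d_avg <- mean(ref) - mean(other_avg)
  p_avg <- if (isTRUE(all.equal(ref, other_avg))) NA_real_ else {
    stats::t.test(ref, other_avg, paired = TRUE)$p.value
  }
  list(per_feature = per,
       vs_others_avg = list(delta = d_avg, delta_2dp = trunc2(d_avg),
                            p_value = p_avg),
       reference = reference_feature, test = "two-sided paired t-test")
}
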