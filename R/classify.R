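#' Fit a two-class Fisher linear discriminant
#'
#' Computes the Fisher direction \code{W = Sw^-1 (mu_pos - mu_neg)} (pooled
#' within-class covariance, equal priors) and the midpoint bias
#' \code{w0 = -W' (mu_pos + mu_neg) / 2}, so the decision score
#' \code{y = W'x + w0} is positive on the positive class side of the
#' midpoint between the class means. A singular pooled covariance is ridged
#' with \code{1e-6 * trace / d} on the diagonal.
#'
#' @param X numeric matrix of feature vectors (rows = examples); a vector is
#'   treated as one-dimensional features.
#' @param y labels with exactly two distinct values.
#' @param positive which label plays the positive (\code{y > 0}) role;
#'   default the first of \code{sort(unique(y))}'s more severe value when
#'   labels are fatigue classes, otherwise the second sorted level.
#' @return object of class \code{semg_lda} with \code{W}, \code{w0},
#'   \code{positive_class}, \code{negative_class}.
#' @export
fit_lda <- function(X, y, positive = NULL) {
  X <- as.matrix(X)
  y <- as.character(y)
  classes <- unique(y)
  if (length(classes) != 2L) {
    stop("fit_lda needs exactly two classes, got: ",
         paste(classes, collapse = ", "))
  }
  if (is.null(positive)) {
    positive <- if (all(classes %in% FATIGUE_LEVELS)) {
      classes[which.max(match(classes, FATIGUE_LEVELS))]  # more severe
    } else sort(classes)[2]
  }
  negative <- setdiff(classes, positive)
  if (sum(y == positive) < 2L || sum(y == negative) < 2L) {
    stop("each class needs at least 2 examples")
  }
  Xp <- X[y == positive, , drop = FALSE]
  Xn <- X[y == negative, , drop = FALSE]
  mu_p <- colMeans(Xp); mu_n <- colMeans(Xn)
  ctr <- rbind(sweep(Xp, 2, mu_p), sweep(Xn, 2, mu_n))
  Sw <- crossprod(ctr) / (nrow(X) - 2L)
  d <- ncol(X)
  ridge_applied <- FALSE
  W <- tryCatch(solve(Sw, mu_p - mu_n), error = function(e) NULL)
  if (is.null(W) || !all(is.finite(W))) {
    Sw <- Sw + diag(1e-6 * sum(diag(Sw)) / d + 1e-12, d)
    W <- solve(Sw, mu_p - mu_n)
    ridge_applied <- TRUE
  }
  if (all(W == 0)) warning("identical class means: zero-margin discriminant")
  structure(list(W = as.numeric(W),
                 w0 = -sum(W * (mu_p + mu_n)) / 2,
                 positive_class = positive, negative_class = negative,
                 ridge = ridge_applied),
            class = "semg_lda")
}

#' Predict fatigue classes from a fitted discriminant
#'
#' \code{y = W'x + w0}; positive class when \code{y >= 0} (the midpoint tie
#' goes to the positive -- i.e. more severe -- class), negative otherwise.
#'
#' @param object a \code{semg_lda}.
#' @param newdata feature matrix or vector (rows = examples).
#' @param ... unused.
#' @return character vector of predicted class labels.
#' @export
predict.semg_lda <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$W)) {
    stop("feature dimension ", ncol(X), " does not match model (",
         length(object$W), ")")
  }
  score <- as.numeric(X %*% object$W + object$w0)
  ifelse(score >= 0, object$positive_class, object$negative_class)
}

#' Build the two-class per-second dataset for a feature and class pair
#'
#' Collects, across the given trials, every second whose label belongs to
#' the pair, with the feature value of that second.
#'
#' @param trials list of \code{list(trial =, labels =, features =)} where
#'   \code{features} is the \code{\link{extract_all}} output (computed here
#'   when absent).
#' @param feature_name which feature stream to use.
#' @param pair character vector of two fatigue classes, e.g.
#'   \code{c("NF", "TF")}.
#' @return data.frame with columns \code{subject, trial, t, x, y}.
#' @export
build_pair_dataset <- function(trials, feature_name, pair) {
  stopifnot(length(pair) == 2L, all(pair %in% FATIGUE_LEVELS))
  rows <- lapply(trials, function(tr) {
    feats <- tr$features
    if (is.null(feats)) feats <- extract_all(tr$trial)
    f <- feats[[feature_name]]
    if (is.null(f)) stop("no feature named '", feature_name, "'")
    lt <- label_times(tr$labels)
    m <- match(round(f$times), round(lt))
    ok <- !is.na(m)
    lab <- as.character(tr$labels$labels)[m[ok]]
    keep <- lab %in% pair
    data.frame(subject = tr$trial$subject_id, trial = tr$trial$trial_id,
               t = f$times[ok][keep], x = f$values[ok][keep],
               y = lab[keep], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Chronological (longitudinal) train/test split
#'
#' Within each trial and each class, the chronologically first
#' \code{ceil(train_frac * n)} seconds go to training and the remainder to
#' testing, so every training timestamp precedes every test timestamp of the
#' same trial and class: the model must generalize forward in time.
#'
#' @param ds dataset from \code{\link{build_pair_dataset}}.
#' @param train_frac fraction of each class's seconds used for training
#'   (default 0.5).
#' @return list with \code{train} and \code{test} data.frames.
#' @export
longitudinal_split <- function(ds, train_frac = 0.5) {
  stopifnot(train_frac > 0, train_frac < 1)
  ds <- ds[order(ds$subject, ds$trial, ds$t), ]
  key <- interaction(ds$subject, ds$trial, ds$y, drop = TRUE)
  take <- logical(nrow(ds))
  for (k in levels(key)) {
    idx <- which(key == k)
    n <- length(idx)
    if (n < 4L) {
      stop("class ", ds$y[idx[1]], " has only ", n,
           " seconds in trial ", ds$trial[idx[1]], " (need >= 4)")
    }
    take[idx[seq_len(ceiling(train_frac * n))]] <- TRUE
  }
  list(train = ds[take, ], test = ds[!take, ])
}

#' Pairwise longitudinal classification for one subject
#'
#' Builds the per-second dataset for the subject's trials, splits it
#' chronologically, fits the Fisher discriminant on the training seconds and
#' scores the held-out later seconds. The more severe class of the pair acts
#' as the confusion-matrix positive.
#'
#' @param trials list of the subject's labeled trials (as in
#'   \code{\link{build_pair_dataset}}).
#' @param feature_name feature stream to classify on (one-dimensional).
#' @param pair two fatigue classes, default \code{c("NF", "TF")}.
#' @param train_frac chronological training fraction (default 0.5).
#' @return list with \code{percent_correct}, \code{confusion} (a
#'   \code{\link{confusion_matrix}}), \code{model} and test-set size
#'   \code{n_test}.
#' @export
run_pairwise <- function(trials, feature_name, pair = c("NF", "TF"),
                         train_frac = 0.5) {
  ds <- build_pair_dataset(trials, feature_name, pair)
  if (length(unique(ds$y)) < 2L) {
    stop("subject lacks one of the classes ", paste(pair, collapse = "/"))
  }
  sp <- longitudinal_split(ds, train_frac)
  model <- fit_lda(matrix(sp$train$x, ncol = 1), sp$train$y)
  pred <- predict(model, matrix(sp$test$x, ncol = 1))
  pos <- model$positive_class
  actual_pos <- sp$test$y == pos
  cm <- confusion_matrix(
    a = sum(!actual_pos & pred != pos), b = sum(!actual_pos & pred == pos),
    c = sum(actual_pos & pred != pos), d = sum(actual_pos & pred == pos),
    positive = pos)
  list(percent_correct = 100 * mean(pred == sp$test$y), confusion = cm,
       model = model, n_test = nrow(sp$test))
}

#' Pairwise classification across a cohort
#'
#' Runs \code{\link{run_pairwise}} for every subject and feature, for both
#' class pairs, and returns the tidy result table the report stage consumes.
#'
#' @param cohort list of labeled trials (with or without precomputed
#'   \code{features}).
#' @param feature_names features to compare (default: all in the first
#'   trial's feature set).
#' @param pairs list of class pairs (default NF/TF and TF/F).
#' @param train_frac chronological training fraction.
#' @return data.frame with one row per subject x feature x pair:
#'   \code{subject, feature, pair, percent_correct, a, b, c, d}.
#' @export
run_cohort <- function(cohort, feature_names = NULL,
                       pairs = list(c("NF", "TF"), c("TF", "F")),
                       train_frac = 0.5) {
  for (i in seq_along(cohort)) {
    if (is.null(cohort[[i]]$features)) {
      cohort[[i]]$features <- extract_all(cohort[[i]]$trial)
    }
  }
  if (is.null(feature_names)) feature_names <- names(cohort[[1]]$features)
  subjects <- unique(vapply(cohort, function(x) x$trial$subject_id, ""))
  out <- list()
  for (pair in pairs) {
    for (feat in feature_names) {
      for (s in subjects) {
        mine <- Filter(function(x) x$trial$subject_id == s, cohort)
        res <- run_pairwise(mine, feat, pair, train_frac)
        out[[length(out) + 1L]] <- data.frame(
          subject = s, feature = feat, pair = paste(pair, collapse = "/"),
          percent_correct = res$percent_correct,
          a = res$confusion$a, b = res$confusion$b,
          c = res$confusion$c, d = res$confusion$d,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
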