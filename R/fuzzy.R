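#' Piecewise-linear fuzzy membership functions
#'
#' \code{trap_mf(a, b, c, d)} builds a trapezoidal membership function rising
#' linearly on \code{[a, b]}, flat at 1 on \code{[b, c]} and falling on
#' \code{[c, d]}; \code{tri_mf(a, b, c)} is the triangular special case with
#' apex \code{b}. Degenerate (zero-width) ramps are treated as crisp steps.
#'
#' @param a,b,c,d sorted breakpoints in the input's units.
#' @return object of class \code{fuzzy_mf}.
#' @export
trap_mf <- function(a, b, c, d) {
  if (is.unsorted(c(a, b, c, d))) stop("breakpoints must satisfy a <= b <= c <= d")
  structure(list(shape = "trapezoidal", pts = c(a, b, c, d)),
            class = "fuzzy_mf")
}

#' @rdname trap_mf
#' @export
tri_mf <- function(a, b, c) {
  if (is.unsorted(c(a, b, c))) stop("breakpoints must satisfy a <= b <= c")
  structure(list(shape = "triangular", pts = c(a, b, b, c)),
            class = "fuzzy_mf")
}

#' Evaluate a membership function
#'
#' Piecewise-linear evaluation, vectorised over \code{x}: 0 outside the
#' support, 1 on the plateau or apex, linear on the ramps.
#'
#' @param mf a \code{fuzzy_mf}.
#' @param x numeric vector of input values.
#' @return membership degrees in \code{[0, 1]}.
#' @export
membership <- function(mf, x) {
  stopifnot(inherits(mf, "fuzzy_mf"))
  p <- mf$pts
  up <- if (p[2] > p[1]) (x - p[1]) / (p[2] - p[1]) else as.numeric(x >= p[2])
  dn <- if (p[4] > p[3]) (p[4] - x) / (p[4] - p[3]) else as.numeric(x <= p[3])
  pmin(pmax(pmin(up, dn), 0), 1)
}

#' Default fuzzy labeling parameterization
#'
#' Elbow-angle terms reproduce the published crisp regions -- angles above
#' 89 degrees are Non-Fatigue, below 86.5 degrees Fatigue, linear overlap
#' between: F trapezoid (0, 0, 86.5, 89), TF triangle (86.5, 87.75, 89),
#' NF trapezoid (86.5, 89, 180, 180). Oscillation terms cross at 0.6 degrees
#' SD, the boundary between steady holding and fatigue-related arm
#' oscillation: Low (0, 0, 0.4, 0.8), High (0.4, 0.8, Inf-plateau). Only the
#' two boundary values are fixed by the underlying study; the ramp widths are
#' this package's parameterization and can be overridden.
#'
#' @return list with \code{angle} (NF/TF/F membership functions) and
#'   \code{osc} (Low/High membership functions).
#' @export
default_fuzzy_params <- function() {
  list(angle = list(NF = trap_mf(86.5, 89, 180, 180),
                    TF = tri_mf(86.5, 87.75, 89),
                    F = trap_mf(0, 0, 86.5, 89)),
       osc = list(Low = trap_mf(0, 0, 0.4, 0.8),
                  High = trap_mf(0.4, 0.8, 1e6, 1e6)))
}

# The six-rule base: antecedents (angle term, oscillation term) and the
# consequent class. Angle TF maps to TF regardless of oscillation; angle F
# maps to F regardless; angle NF splits on oscillation.
fuzzy_rulebase <- function() {
  data.frame(
    angle = c("NF", "NF", "TF", "TF", "F", "F"),
    osc = c("Low", "High", "Low", "High", "Low", "High"),
    consequent = c("NF", "TF", "TF", "TF", "F", "F"),
    stringsAsFactors = FALSE)
}

# strength matrix: n x 6, product inference per rule
rule_strengths <- function(angle, osc, params) {
  rules <- fuzzy_rulebase()
  mu_a <- sapply(c(NF = "NF", TF = "TF", F = "F"),
                 function(k) membership(params$angle[[k]], angle))
  mu_o <- sapply(c(Low = "Low", High = "High"),
                 function(k) membership(params$osc[[k]], osc))
  mu_a <- matrix(mu_a, ncol = 3, dimnames = list(NULL, c("NF", "TF", "F")))
  mu_o <- matrix(mu_o, ncol = 2, dimnames = list(NULL, c("Low", "High")))
  s <- sapply(seq_len(nrow(rules)),
              function(r) mu_a[, rules$angle[r]] * mu_o[, rules$osc[r]])
  matrix(s, ncol = nrow(rules))
}

#' Classify one (angle, oscillation) sample
#'
#' Evaluates all six rules with product inference and returns the consequent
#' of the rule with the greatest firing strength (single winning label, no
#' blending). Ties resolve toward the more severe class. If every rule fires
#' with strength zero -- impossible under the default parameterization, whose
#' supports cover the whole input plane -- the sample is labeled NF with a
#' warning flag.
#'
#' @param angle elbow angle in degrees, in \code{[0, 180]}.
#' @param osc angular oscillation (degrees SD), non-negative.
#' @param params membership parameterization (default
#'   \code{\link{default_fuzzy_params}}).
#' @return list with \code{label}, the winning rule's index \code{rule},
#'   its \code{strength}, and \code{degenerate} (TRUE when nothing fired).
#' @export
classify_sample <- function(angle, osc, params = default_fuzzy_params()) {
  stopifnot(length(angle) == 1L, length(osc) == 1L)
  if (angle < 0 || angle > 180) stop("angle outside [0, 180]")
  if (osc < 0) stop("oscillation must be non-negative")
  s <- rule_strengths(angle, osc, params)[1, ]
  if (all(s == 0)) {
    warning("no rule fired; defaulting to NF")
    return(list(label = "NF", rule = NA_integer_, strength = 0,
                degenerate = TRUE))
  }
  rules <- fuzzy_rulebase()
  sev <- match(rules$consequent, FATIGUE_LEVELS)
  best <- which(s == max(s))
  win <- best[which.max(sev[best])]
  list(label = rules$consequent[win], rule = win, strength = s[win],
       degenerate = FALSE)
}

# vectorised winning-label path used by label_trial
classify_samples <- function(angle, osc, params = default_fuzzy_params()) {
  s <- rule_strengths(angle, osc, params)
  rules <- fuzzy_rulebase()
  sev <- match(rules$consequent, FATIGUE_LEVELS)
  # stable severity-aware argmax: add a tiny severity bonus only on exact ties
  ord <- order(sev, seq_len(nrow(rules)), decreasing = TRUE)
  s_ord <- s[, ord, drop = FALSE]
  win_ord <- max.col(s_ord, ties.method = "first")  # first = most severe
  lab <- rules$consequent[ord][win_ord]
  lab[rowSums(s) == 0] <- "NF"
  lab
}

#' Label every second of a trial from its goniometer kinematics
#'
#' The automated labeler: computes the 4-s-block angular oscillation signal,
#' classifies every sample with the six-rule fuzzy classifier, and reduces
#' the per-sample labels to per-second labels by majority vote (ties toward
#' the more severe class).
#'
#' @param trial a \code{semg_trial} at least 4 s long.
#' @param params membership parameterization.
#' @param osc_window_s oscillation window in seconds (default 4).
#' @return a \code{label_series} with one label per whole second.
#' @export
label_trial <- function(trial, params = default_fuzzy_params(),
                        osc_window_s = 4) {
  validate_trial(trial)
  osc <- gonio_oscillation(trial$gonio_angle, trial$fs_gonio,
                           window_s = osc_window_s)
  lab <- classify_samples(trial$gonio_angle, osc, params)
  align_labels_to_seconds(lab, trial$fs_gonio)
}
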