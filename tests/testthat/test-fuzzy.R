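test_that("membership evaluates piecewise-linearly with crisp plateaus", {
  nf <- trap_mf(86.5, 89, 180, 180)
  expect_equal(membership(nf, 90), 1)
  expect_equal(membership(nf, 86.5), 0)
  expect_equal(membership(nf, 87.75), 0.5)

  # random inputs against a direct piecewise formula
  oracle <- function(p, x) {
    if (x < p[1] || x > p[4]) return(0)
    if (x >= p[2] && x <= p[3]) return(1)
    if (x < p[2]) return((x - p[1]) / (p[2] - p[1]))
    (p[4] - x) / (p[4] - p[3])
  }
  set.seed(10)
  mf <- trap_mf(2, 5, 7, 11)
  for (x in runif(50, -1, 13)) {
    expect_equal(membership(mf, x), oracle(c(2, 5, 7, 11), x),
                 tolerance = 1e-12)
  }
  tri <- tri_mf(0, 1, 3)
  expect_equal(membership(tri, 1), 1)
  expect_equal(membership(tri, 2), 0.5)
  expect_error(trap_mf(3, 2, 5, 6), "sorted|satisfy")
})

test_that("classify_sample reproduces the six-rule base", {
  expect_identical(classify_sample(91, 0.1)$label, "NF")
  expect_identical(classify_sample(91, 1.2)$label, "TF")
  expect_identical(classify_sample(85, 1.2)$label, "F")
  expect_identical(classify_sample(85, 0.1)$label, "F")
  expect_identical(classify_sample(88, 0.1)$label, "TF")
  res <- classify_sample(88, 0.1)
  expect_true(res$strength > 0 && res$strength <= 1)
  expect_error(classify_sample(190, 0.1), "\\[0, 180\\]")
  expect_error(classify_sample(90, -1), "non-negative")
})

test_that("default supports cover the input plane; gaps warn and default NF", {
  set.seed(11)
  for (i in 1:50) {
    s <- classify_sample(runif(1, 0, 180), runif(1, 0, 8))
    expect_gt(s$strength, 0)
  }
  gappy <- default_fuzzy_params()
  gappy$angle$NF <- trap_mf(120, 130, 180, 180)  # hole between 89 and 120
  gappy$angle$TF <- tri_mf(86.5, 87.75, 89)
  expect_warning(res <- classify_sample(100, 0.1, gappy), "no rule fired")
  expect_identical(res$label, "NF")
  expect_true(res$degenerate)
})

test_that("lowering the angle never makes the label less severe", {
  sev <- function(l) match(l, FATIGUE_LEVELS)
  for (osc in c(0, 0.3, 0.6, 0.9, 2)) {
    labs <- vapply(seq(180, 0, by = -0.5),
                   function(a) classify_sample(a, osc)$label, "")
    expect_true(all(diff(sev(labs)) >= 0))
  }
})

test_that("label_trial handles crisp kinematics", {
  n <- 8 * FS
  flat <- new_trial(cbind(rnorm(n), rnorm(n)), rep(90, n))
  expect_true(all(label_trial(flat)$labels == "NF"))
  low <- new_trial(cbind(rnorm(n), rnorm(n)), rep(84, n))
  expect_true(all(label_trial(low)$labels == "F"))
})

test_that("label_trial recovers synthetic ground truth", {
  gen <- generate_trial(short_config(seed = 5, noise_sd = 0))
  lab <- label_trial(gen$trial)
  truth <- as.character(gen$labels$labels)
  pred <- as.character(lab$labels)
  expect_gte(mean(pred == truth), 0.95)
  # change-points within one oscillation block (4 s) of the phase onsets
  expect_lte(abs((which(pred == "TF")[1] - 1) - 16), 4)
  expect_lte(abs((which(pred == "F")[1] - 1) - 30), 4)
})
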