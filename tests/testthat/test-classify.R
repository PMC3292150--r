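test_that("fit_lda separates, matches the closed-form Fisher direction", {
  set.seed(30)
  x <- c(rnorm(20, 10, 0.1), rnorm(20, -10, 0.1))
  y <- rep(c("TF", "NF"), each = 20)
  m <- fit_lda(matrix(x, ncol = 1), y)
  expect_identical(m$positive_class, "TF")
  expect_true(all(predict(m, matrix(x, ncol = 1)) == y))

  # 2-D correlated Gaussians against the closed-form oracle
  S <- matrix(c(2, 0.8, 0.8, 1), 2)
  L <- chol(S)
  X <- rbind(matrix(rnorm(400), ncol = 2) %*% L,
             sweep(matrix(rnorm(400), ncol = 2) %*% L, 2, c(-1.5, 1), "+"))
  yy <- rep(c("a", "b"), each = 200)
  mm <- fit_lda(X, yy, positive = "b")
  expect_lt(angle_between(mm$W, oracle_fisher_direction(X, yy)), 1e-6)

  expect_error(fit_lda(matrix(x, ncol = 1), rep("NF", 40)), "two classes")
  expect_warning(fit_lda(matrix(rep(c(1, 1), 20), ncol = 1),
                         rep(c("NF", "TF"), 20)), "identical class means")
})

test_that("predict applies the sign rule with midpoint tie to positive", {
  set.seed(31)
  X <- matrix(c(rnorm(10, 2, 0.3), rnorm(10, -2, 0.3)), ncol = 1)
  y <- rep(c("TF", "NF"), each = 10)
  m <- fit_lda(X, y)
  mid <- (mean(X[1:10, ]) + mean(X[11:20, ])) / 2
  expect_identical(predict(m, matrix(mid)), "TF")       # tie -> positive
  expect_identical(predict(m, matrix(mean(X[1:10, ]))), "TF")
  for (x0 in rnorm(20)) {
    want <- if (m$W * x0 + m$w0 >= 0) "TF" else "NF"
    expect_identical(predict(m, matrix(x0)), want)
  }
  expect_error(predict(m, matrix(1:4, ncol = 2)), "dimension")
})

test_that("longitudinal_split is chronological per trial and class", {
  ds <- data.frame(subject = "s1", trial = "t1",
                   t = 0:19, x = rnorm(20),
                   y = rep(c("NF", "TF"), each = 10))
  sp <- longitudinal_split(ds, 0.5)
  expect_identical(nrow(sp$train), 10L)
  expect_identical(nrow(sp$test), 10L)
  for (cl in c("NF", "TF")) {
    expect_lt(max(sp$train$t[sp$train$y == cl]),
              min(sp$test$t[sp$test$y == cl]))
  }
  sp9 <- longitudinal_split(ds, 0.9)
  expect_identical(sum(sp9$train$y == "NF"), 9L)
  expect_identical(sum(sp9$test$y == "NF"), 1L)
  tiny <- ds[c(1:3, 11:20), ]
  expect_error(longitudinal_split(tiny), "NF")
})

test_that("run_pairwise scores chance-level and separable features", {
  mk <- function(values, labels, subject = "s1", trial = "t1") {
    n <- length(values)
    list(trial = structure(list(subject_id = subject, trial_id = trial),
                           class = "semg_trial"),
         labels = new_label_series(labels),
         features = list(
           f = new_feature_series("f", seq_len(n) - 1, values)))
  }
  labs <- rep(c("NF", "TF"), each = 30)
  set.seed(32)
  sep <- mk(c(rnorm(30, 0, 0.05), rnorm(30, 5, 0.05)), labs)
  res <- run_pairwise(list(sep), "f", c("NF", "TF"))
  expect_equal(res$percent_correct, 100)
  with(res$confusion, expect_identical(a + b + c + d, res$n_test))

  # identical distributions: about chance on the balanced test half
  ident <- mk(rnorm(60), labs)
  res2 <- run_pairwise(list(ident), "f", c("NF", "TF"))
  expect_gte(res2$percent_correct, 20)
  expect_lte(res2$percent_correct, 80)
})

test_that("no test leakage and affine invariance of the decision", {
  gen <- generate_trial(short_config(seed = 33))
  feats <- list(spectro_std = spectro_std(gen$trial))
  tr <- list(trial = gen$trial, labels = gen$labels, features = feats)
  res <- run_pairwise(list(tr), "spectro_std", c("NF", "TF"))

  # shuffle only the test seconds: model must be bit-identical
  ds <- build_pair_dataset(list(tr), "spectro_std", c("NF", "TF"))
  sp <- longitudinal_split(ds, 0.5)
  set.seed(34)
  sp_shuf <- sp$test[sample(nrow(sp$test)), ]
  m1 <- fit_lda(matrix(sp$train$x, ncol = 1), sp$train$y)
  m2 <- fit_lda(matrix(sp$train$x, ncol = 1), sp$train$y)
  expect_identical(m1, m2)
  expect_setequal(predict(m1, matrix(sp_shuf$x, ncol = 1)),
                  predict(m1, matrix(sp$test$x, ncol = 1)))

  # rescaling the feature leaves training-set predictions unchanged
  m_sc <- fit_lda(matrix(10 * sp$train$x + 3, ncol = 1), sp$train$y)
  expect_identical(predict(m_sc, matrix(10 * sp$train$x + 3, ncol = 1)),
                   predict(m1, matrix(sp$train$x, ncol = 1)))
})
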