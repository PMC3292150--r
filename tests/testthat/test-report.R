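test_that("rates computes the exact ratios and flags undefined ones", {
  r <- rates(confusion_matrix(16, 1, 8, 11))
  expect_equal(r$tp, 11 / 19)
  expect_equal(r$fn, 8 / 19)
  expect_equal(r$tn, 16 / 17)
  expect_equal(r$fp, 1 / 17)
  expect_equal(r$accuracy, 27 / 36)

  perfect <- rates(confusion_matrix(10, 0, 0, 10))
  expect_equal(unlist(perfect[c("tp", "tn", "precision", "accuracy")]),
               c(tp = 1, tn = 1, precision = 1, accuracy = 1))
  expect_equal(unlist(perfect[c("fp", "fn")]), c(fp = 0, fn = 0))

  nopos <- rates(confusion_matrix(5, 2, 0, 0))
  expect_true(is.na(nopos$tp) && is.na(nopos$fn))
  expect_false(is.na(nopos$fp))
  expect_error(confusion_matrix(-1, 0, 0, 1), "non-negative")

  # recompose: rates times their denominators give back the cells
  cm <- confusion_matrix(7, 3, 2, 9)
  rr <- rates(cm)
  expect_equal(rr$tp * (cm$c + cm$d), cm$d)
  expect_equal(rr$tn * (cm$a + cm$b), cm$a)
})

test_that("dbi matches hand values and the brute-force oracle", {
  expect_equal(dbi(list(c(0, 1, 2), c(10, 12))), sd(c(1, 0, 1)) / 10)
  expect_equal(dbi(list(c(5, 5, 5), c(9, 9))), 0)
  g1 <- c(0, 1, 2); g2 <- c(10, 12)
  expect_equal(dbi(list(g1 + 100, g2 + 100)), dbi(list(g1, g2)))
  expect_error(dbi(list(c(1, 2), c(1, 2))), "coincident")

  set.seed(40)
  for (i in 1:100) {
    d <- sample(1:3, 1)
    a <- matrix(rnorm(d * sample(2:40, 1)), ncol = d)
    b <- matrix(rnorm(d * sample(2:40, 1), mean = 2), ncol = d)
    expect_equal(dbi(list(a, b)), oracle_dbi(a, b), tolerance = 1e-12)
  }
})

test_that("dbi_canonical follows the textbook definition", {
  a <- c(0, 2); b <- c(10, 14)
  # s1 = 1, s2 = 2, d = 11, R = (1+2)/11 for both clusters
  expect_equal(dbi_canonical(list(a, b)), 3 / 11)
  expect_error(dbi_canonical(list(a)), "two clusters")
})

test_that("dbi_window_sweep spans 1..5 with raw values at span 1", {
  gen <- generate_trial(short_config(seed = 41))
  x <- bandpass_filter(gen$trial$emg[, 1], FS)
  w <- segment_windows(x, FS)
  uni <- unify_1d_spectro(
    new_feature_series("bandpower", attr(w, "times"),
                       apply(w, 2, total_band_power, fs = FS)),
    new_feature_series("imdf", attr(w, "times"), apply(w, 2, imdf, fs = FS)))
  sw <- dbi_window_sweep(uni, gen$labels, c("NF", "TF"))
  expect_identical(names(sw), as.character(1:5))
  expect_true(all(is.finite(sw) & sw >= 0))
  # span-1 entry equals dbi on the raw unified values
  ph <- phase_at(gen$labels, uni$times)
  expect_equal(sw[["1"]], dbi(list(uni$values[ph == "NF"],
                                   uni$values[ph == "TF"])))
})

test_that("summarize agrees with a second-pass oracle and validates", {
  set.seed(42)
  tbl <- matrix(runif(40, 40, 95), nrow = 10,
                dimnames = list(NULL, paste0("f", 1:4)))
  s <- summarize_percent_correct(tbl)
  for (j in 1:4) {
    mu <- sum(tbl[, j]) / 10
    expect_equal(s$mean[[j]], mu, tolerance = 1e-12)
    expect_equal(s$sd[[j]], sqrt(sum((tbl[, j] - mu)^2) / 9),
                 tolerance = 1e-12)
  }
  const <- cbind(tbl, cc = rep(50, 10))
  expect_equal(summarize_percent_correct(const)$sd[["cc"]], 0)
  expect_error(summarize_percent_correct(tbl[1, , drop = FALSE]), "2 subjects")
})

test_that("improvements handles identical columns and reports its test", {
  tbl <- matrix(c(rep(60, 5), rep(60, 5)), ncol = 2,
                dimnames = list(NULL, c("spectro_std", "other")))
  s <- summarize_percent_correct(tbl)
  imp <- improvements(s)
  expect_equal(imp$per_feature$other$delta, 0)
  expect_true(is.na(imp$per_feature$other$p_value))
  expect_match(imp$test, "t-test")
  expect_error(improvements(s, "nope"), "not in table")
})
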