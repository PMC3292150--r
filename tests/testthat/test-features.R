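test_that("unify_1d_spectro standardizes and subtracts", {
  p <- new_feature_series("bandpower", 0:2, c(1, 2, 3))
  m <- new_feature_series("imdf", 0:2, c(3, 2, 1))
  u <- unify_1d_spectro(p, m)
  # sample-SD z-scores: z(1,2,3) = (-1,0,1), z(3,2,1) = (1,0,-1)
  expect_equal(u$values, c(-2, 0, 2))

  same <- new_feature_series("imdf", 0:2, c(1, 2, 3))
  expect_equal(unify_1d_spectro(p, same)$values, rep(0, 3))

  flatm <- new_feature_series("imdf", 0:2, rep(5, 3))
  expect_error(unify_1d_spectro(p, flatm), "zero-variance")
  off <- new_feature_series("imdf", 1:3, c(3, 2, 1))
  expect_error(unify_1d_spectro(p, off), "time grid")
})

test_that("rolling_std matches the sample-SD oracle and is causal", {
  s <- new_feature_series("u", 0:3, c(1, 2, 3, 4))
  r <- rolling_std(s, 3)
  expect_equal(r$values, c(sd(1:3), sd(2:4)))  # both exactly 1
  expect_equal(r$values, c(1, 1))
  expect_equal(r$times, c(2, 3))               # stamped at span end: causal

  const <- new_feature_series("u", 0:9, rep(7, 10))
  expect_true(all(rolling_std(const, 3)$values == 0))
  expect_true(all(rolling_std(s, 1)$values == 0))
  expect_error(rolling_std(s, 9), "shorter")

  # shift invariance and absolute-scale equivariance
  set.seed(17)
  v <- rnorm(30)
  base <- rolling_std(new_feature_series("u", 0:29, v), 4)$values
  shifted <- rolling_std(new_feature_series("u", 0:29, v + 5), 4)$values
  scaled <- rolling_std(new_feature_series("u", 0:29, -3 * v), 4)$values
  expect_equal(shifted, base, tolerance = 1e-12)
  expect_equal(scaled, 3 * base, tolerance = 1e-12)
})

test_that("spectro_std composes the chain and handles the minimal trial", {
  tiny <- signal_trial(rnorm(3 * FS))
  expect_length(spectro_std(tiny)$values, 1L)

  gen <- generate_trial(short_config(seed = 19))
  ss <- spectro_std(gen$trial)
  # manual composition oracle
  x <- bandpass_filter(gen$trial$emg[, 1], FS)
  w <- segment_windows(x, FS)
  mdf <- new_feature_series("imdf", attr(w, "times"),
                           apply(w, 2, imdf, fs = FS))
  pow <- new_feature_series("bandpower", attr(w, "times"),
                            apply(w, 2, total_band_power, fs = FS))
  manual <- rolling_std(unify_1d_spectro(pow, mdf), 3)
  expect_equal(ss$values, manual$values, tolerance = 1e-12)
  expect_identical(ss$name, "spectro_std")
})

test_that("wavelet machinery: filters, energy conservation, band ordering", {
  expect_error(wavelet_feature(signal_trial(rnorm(FS * 8)), wavelet = "db9"),
               "db2")

  set.seed(20)
  x <- rnorm(4096)
  for (wv in c("haar", "db3", "sym5")) {
    dec <- wavelet_decompose(x, wv, 5)
    e <- sum(dec$approx^2) + sum(unlist(lapply(dec$details,
                                               function(d) sum(d^2))))
    expect_equal(e, sum(x^2), tolerance = 1e-10)  # orthonormal transform
    # full inverse restores the signal
    a <- dec$approx
    h <- semgfatigue:::wavelet_filter(wv)
    for (j in rev(seq_len(5))) {
      a <- semgfatigue:::idwt_step(a, dec$details[[j]], h)
    }
    expect_equal(a, x, tolerance = 1e-10)
  }

  # depth-12 approximation keeps low-frequency energy, rejects high
  zero <- wavelet_feature(signal_trial(numeric(8 * FS)), prefilter = FALSE)
  expect_true(all(zero$values == 0))
  f_lo <- wavelet_feature(signal_trial(sine(1, 8)), prefilter = FALSE)
  f_hi <- wavelet_feature(signal_trial(sine(400, 8)), prefilter = FALSE)
  expect_true(all(f_lo$values > f_hi$values))
  expect_true(all(f_lo$values >= 0))
})

test_that("extract_all aligns all five streams and is deterministic", {
  gen <- generate_trial(short_config(seed = 23))
  feats <- extract_all(gen$trial)
  expect_setequal(names(feats),
                  c("spectro_std", "imdf_std3", "bandpower_std3",
                    "fi2_std3", "wavelet_db3_std3"))
  n_sec <- 40
  for (f in feats) {
    expect_length(f$values, n_sec - 2)
    expect_equal(f$times, feats$spectro_std$times)
  }
  feats2 <- extract_all(gen$trial)
  expect_identical(feats, feats2)

  # higher moments available on request, absent by default
  fm <- extract_all(gen$trial, fi_moments = c(2, 3))
  expect_true("fi3_std3" %in% names(fm))
  expect_false("fi3_std3" %in% names(feats))
})
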