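test_that("generate_trial obeys its configuration contract", {
  gen <- generate_trial(short_config(seed = 1))
  expect_equal(nrow(gen$trial$emg), 40 * FS)
  counts <- table(gen$labels$labels)
  expect_identical(as.integer(counts[c("NF", "TF", "F")]), c(16L, 14L, 10L))

  # same config + seed: bit-identical
  gen2 <- generate_trial(short_config(seed = 1))
  expect_identical(gen$trial$emg, gen2$trial$emg)
  expect_identical(gen$trial$gonio_angle, gen2$trial$gonio_angle)
  gen3 <- generate_trial(short_config(seed = 2))
  expect_false(identical(gen$trial$emg, gen3$trial$emg))
})

test_that("invalid configurations are rejected with the violated invariant", {
  expect_error(synthetic_config(t_tf = 150, t_f = 100), "t_tf < t_f")
  expect_error(synthetic_config(mdf_start = 50, mdf_end = 60), "mdf_end")
  expect_error(synthetic_config(angle_end = 88), "86.5")
  expect_error(synthetic_config(osc_sd_nf = 0.7), "0.6")
  expect_error(synthetic_config(decline_s = 200), "decline_s")
})

test_that("generated kinematics land on the stated phase geometry", {
  gen <- generate_trial(short_config(seed = 31))
  cfg <- short_config()
  ang <- gen$trial$gonio_angle
  nf <- ang[1:(cfg$t_tf * FS)]
  expect_lt(abs(mean(nf) - cfg$angle_hold),
            3 * cfg$osc_sd_nf / sqrt(length(nf)) + 0.02)
  last5 <- ang[((cfg$duration_s - 5) * FS):(cfg$duration_s * FS)]
  expect_lt(mean(last5), 86.5)
  expect_identical(as.character(gen$labels$labels[cfg$t_tf]), "NF")
  expect_identical(as.character(gen$labels$labels[cfg$t_tf + 1]), "TF")
  expect_identical(as.character(gen$labels$labels[cfg$t_f + 1]), "F")
})

test_that("spectral compression holds for every seed", {
  for (seed in 1:5) {
    gen <- generate_trial(short_config(seed = seed))
    w <- segment_windows(gen$trial$emg[, 1], FS)
    early <- mean(apply(w[, 1:10], 2, imdf, fs = FS))
    late <- mean(apply(w[, 31:40], 2, imdf, fs = FS))
    expect_lt(late, early)
  }
  # absolute recovery of the configured start frequency
  gen <- generate_trial(short_config(seed = 2))
  w <- segment_windows(gen$trial$emg[, 1], FS)
  expect_lt(abs(mean(apply(w[, 1:10], 2, imdf, fs = FS)) - 95), 5)
})

test_that("cohorts are reproducible with deterministic structure", {
  base <- short_config()
  ch <- generate_cohort(4, 3, base, jitter = 0.1, seed = 7)
  expect_length(ch, 12L)
  ids <- vapply(ch, function(g) g$trial$subject_id, "")
  expect_length(unique(ids), 4L)

  ch2 <- generate_cohort(4, 3, base, jitter = 0.1, seed = 7)
  expect_identical(lapply(ch, function(g) g$trial$emg),
                   lapply(ch2, function(g) g$trial$emg))

  # zero jitter: every subject shares the base parameters
  ch0 <- generate_cohort(3, 1, base, jitter = 0, seed = 1)
  for (g in ch0) {
    expect_identical(g$config$t_tf, base$t_tf)
    expect_identical(g$config$mdf_start, base$mdf_start)
  }
  expect_error(generate_cohort(2, 1, base, jitter = 0.7), "jitter")
})
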