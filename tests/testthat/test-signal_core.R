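test_that("trial validation enforces the recording invariants", {
  x <- rnorm(FS)
  expect_s3_class(signal_trial(x), "semg_trial")
  expect_error(new_trial(cbind(x, x, x), rep(90, FS)), "2")
  expect_error(new_trial(cbind(x, x), rep(200, FS)), "\\[0, 180\\]")
  bad <- x; bad[5] <- NA
  expect_error(new_trial(cbind(bad, x), rep(90, FS)), "non-finite")
  expect_error(new_trial(cbind(x, x), rep(90, FS / 2)), "duration")
  # one-sample-period duration mismatch is legal
  expect_s3_class(new_trial(cbind(x, x), rep(90, FS - 1)), "semg_trial")
})

test_that("trial CSVs round-trip losslessly", {
  gen <- generate_trial(short_config(seed = 11))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial(gen$trial, path)
  back <- read_trial(path, subject_id = "s1", trial_id = "t1")
  expect_equal(back$fs_emg, gen$trial$fs_emg)
  expect_lt(max(abs(back$emg - gen$trial$emg)), 1e-9)
  expect_lt(max(abs(back$gonio_angle - gen$trial$gonio_angle)), 1e-9)
})

test_that("trial CSV format errors name the offending part", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,emg_ch1_mV,gonio_deg", "0,0.1,90", "0.0005,0.2,90"),
             path)
  expect_error(read_trial(path), "emg_ch2_mV")
  writeLines(c("time_s,emg_ch1_mV,emg_ch2_mV,gonio_deg",
               "0,0.1,0.2,90", "0.0005,oops,0.2,90"), path)
  expect_error(read_trial(path), "emg_ch1_mV|non-numeric")
  expect_error(read_trial(file.path(tempdir(), "nope.csv")), "no such")
})

test_that("writing degenerate trials is refused / minimal cases work", {
  gen <- generate_trial(short_config())
  tr <- gen$trial
  tr$emg <- tr$emg[0, , drop = FALSE]
  tr$gonio_angle <- numeric(0)
  expect_error(write_trial(tr, tempfile()), "")
  one <- gen$trial
  one$emg <- one$emg[1, , drop = FALSE]
  one$gonio_angle <- one$gonio_angle[1]
  p <- withr::local_tempfile(fileext = ".csv")
  write_trial(one, p)
  expect_length(readLines(p), 2L)  # header + 1 data row
})

test_that("label and feature series validate and round-trip", {
  expect_error(new_label_series(character(0)), "non-empty")
  expect_error(new_label_series(c("NF", "XX")), "unknown fatigue label")
  expect_error(new_feature_series("f", c(0, 0), c(1, 2)), "increasing")
  expect_error(new_feature_series("f", c(0, 1), c(1, Inf)), "finite")

  ls <- new_label_series(c("NF", "NF", "TF", "F"))
  p <- withr::local_tempfile(fileext = ".csv")
  write_label_series(ls, p)
  back <- read_label_series(p)
  expect_identical(as.character(back$labels), as.character(ls$labels))
  expect_equal(label_times(back), 0:3)

  fs_obj <- new_feature_series("imdf", 0:4, c(95, 94, 93, 80, 60))
  pf <- withr::local_tempfile(fileext = ".csv")
  write_feature_series(fs_obj, pf)
  fb <- read_feature_series(pf)
  expect_identical(fb$name, "imdf")
  expect_equal(fb$values, fs_obj$values)
})

test_that("align_labels_to_seconds takes majorities with severe tie-break", {
  expect_identical(
    as.character(align_labels_to_seconds(rep("NF", FS), FS)$labels), "NF")
  # exact tie goes to the more severe class
  expect_identical(
    as.character(align_labels_to_seconds(
      c(rep("NF", FS / 2), rep("TF", FS / 2)), FS)$labels), "TF")
  expect_error(align_labels_to_seconds(rep("NF", FS - 1), FS), "shorter")
})

test_that("align_labels_to_seconds matches the brute-force oracle", {
  set.seed(42)
  for (rep_i in 1:5) {
    n_sec <- sample(2:6, 1)
    extra <- sample(0:(FS - 1), 1)   # trailing partial second must drop
    labs <- sample(FATIGUE_LEVELS, n_sec * FS + extra, replace = TRUE,
                   prob = c(0.4, 0.35, 0.25))
    got <- align_labels_to_seconds(labs, FS)
    expect_length(got$labels, n_sec)
    expect_identical(as.character(got$labels), oracle_majority(labs, FS))
  }
})
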