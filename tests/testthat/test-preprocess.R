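mkrec <- function(x, fs = 4) fhr_record(x, fs = fs)

test_that("missing segments are maximal ordered zero-runs", {
  expect_equal(nrow(find_missing_segments(mkrec(rep(130, 20)))), 0)

  x <- c(rep(130, 5), rep(0, 80), rep(140, 5))
  gaps <- find_missing_segments(mkrec(x))
  expect_equal(gaps$start, 6)
  expect_equal(gaps$length, 80)

  x2 <- c(0, 0, rep(130, 10), 0, 0, 0, rep(140, 10), 0)
  gaps2 <- find_missing_segments(mkrec(x2))
  expect_equal(gaps2$start, c(1, 13, 26))
  expect_equal(gaps2$length, c(2, 3, 1))
})

test_that("zero-runs longer than 15 s are spliced, shorter ones interpolated", {
  # 80 zeros at 4 Hz = 20 s > 15 s: removed
  x <- c(rep(130, 40), rep(0, 80), rep(140, 40))
  out <- remove_long_gaps(mkrec(x))
  expect_length(out$samples, 80)
  expect_true(all(out$samples > 0))

  # 40 zeros = 10 s: linear ramp between the flanking 120 and 160
  x2 <- c(rep(120, 10), rep(0, 40), rep(160, 10))
  out2 <- remove_long_gaps(mkrec(x2))
  expect_length(out2$samples, 60)
  expect_equal(out2$samples[11:50],
               approx(c(10, 51), c(120, 160), xout = 11:50)$y)

  # 60 zeros = exactly 15 s: "longer than" is strict, so interpolated
  x3 <- c(rep(120, 10), rep(0, 60), rep(160, 10))
  out3 <- remove_long_gaps(mkrec(x3))
  expect_length(out3$samples, 80)
  expect_true(all(out3$samples > 0))

  expect_error(remove_long_gaps(mkrec(rep(0, 10))), "no valid signal")
})

test_that("boundary zero-runs are trimmed, not extrapolated", {
  x <- c(rep(0, 8), rep(130, 40), rep(0, 4))
  out <- remove_long_gaps(mkrec(x))
  expect_equal(out$samples, rep(130, 40))
})

test_that("stabilisation repairs spikes and leaves calm signal alone", {
  expect_equal(stabilize(mkrec(rep(130, 50)))$samples, rep(130, 50))

  # slow ramp, adjacent diffs of 1 bpm
  ramp <- seq(110, 159, by = 1)
  expect_equal(stabilize(mkrec(ramp))$samples, ramp)

  # single spike 120 -> 180 -> 120
  x <- c(rep(120, 20), 180, rep(120, 20))
  out <- stabilize(mkrec(x))
  expect_true(all(abs(diff(out$samples)) <= 25))
  expect_equal(out$samples, rep(120, 41))

  expect_error(stabilize(mkrec(c(100, 200, 100, 200, 100, 200))),
               "unstable")
})

test_that("level steps between two stable runs are bridged", {
  x <- c(rep(120, 30), rep(160, 30))  # one 40-bpm step, both sides stable
  out <- stabilize(mkrec(x))
  expect_true(all(abs(diff(out$samples)) <= 25))
  expect_equal(out$samples[1], 120)
  expect_equal(tail(out$samples, 1), 160)
})

test_that("extreme samples are replaced by in-range Hermite interpolation", {
  x <- c(rep(140, 10), 210, rep(140, 10))
  out <- remove_extremes(mkrec(x))
  expect_length(out$samples, 21)
  expect_true(all(out$samples >= 50 & out$samples <= 200))

  x2 <- c(rep(140, 10), 45, rep(140, 10))
  out2 <- remove_extremes(mkrec(x2))
  expect_true(all(out2$samples >= 50 & out2$samples <= 200))

  x3 <- 120 + sin(1:50)
  expect_equal(remove_extremes(mkrec(x3))$samples, x3)

  expect_error(remove_extremes(mkrec(c(210, 220, 45, 140, 230))), "4 in-range")
})

test_that("full preprocessing is identity on artifact-free records", {
  rec <- clean_record(duration_s = 120, seed = 7)
  out <- preprocess_fhr(rec)
  expect_equal(out$samples, rec$samples)
})

test_that("full preprocessing postconditions hold on a dirty record", {
  x <- c(rep(130, 100), rep(0, 80),          # long gap (spliced)
         rep(135, 60), 220,                   # extreme
         rep(135, 60), 180,                   # spike
         rep(132, 100))
  out <- preprocess_fhr(mkrec(x))
  expect_true(all(out$samples > 0))
  expect_true(all(out$samples >= 50 & out$samples <= 200))
  expect_true(all(abs(diff(out$samples)) <= 25))
  expect_lte(length(out$samples), length(x))
  expect_error(preprocess_fhr(mkrec(rep(0, 20))), "no valid signal")
})

test_that("preprocessing is idempotent and output-range safe on synthetic records", {
  for (seed in 1:20) {
    cls <- if (seed %% 2 == 0) "pathological" else "normal"
    rec <- generate_fhr(synth_config(cls, duration_s = 300, seed = seed))
    out <- preprocess_fhr(rec)
    expect_true(all(out$samples > 0))
    expect_true(all(out$samples >= 50 & out$samples <= 200))
    again <- preprocess_fhr(out)
    expect_equal(again$samples, out$samples)
  }
})

test_that("segment selection returns the trailing window", {
  rec <- mkrec(seq_len(20 * 60 * 4))  # 20 min of increasing values
  seg <- select_segment(rec, 13)
  expect_length(seg$samples, 3120)
  expect_equal(seg$samples, seq(20 * 240 - 3120 + 1, 20 * 240))

  rec13 <- mkrec(rep(130, 13 * 240))
  expect_equal(select_segment(rec13, 13)$samples, rec13$samples)

  expect_error(select_segment(mkrec(rep(130, 5 * 240)), 8), "1200")
})
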