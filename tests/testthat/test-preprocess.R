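test_that("wide CSV round-trips into raw channels and segments", {
  dir <- withr::local_tempdir()
  fx <- write_wide_fixture(dir)
  loaded <- load_participant(c(wide = fx$wide), fx$segments)
  expect_named(loaded$channels, c("HR", "VE", "BF", "Hacc", "CAD", "VO2"),
               ignore.order = TRUE)
  expect_equal(loaded$channels$HR$values, 60 + sin(seq(0, 119) / 10))
  expect_equal(loaded$segments$label, c("REST", "ADL"))
})

test_that("missing channels and bad timestamps are rejected by name", {
  dir <- withr::local_tempdir()
  fx <- write_wide_fixture(dir, drop = "CAD")
  expect_error(load_participant(c(wide = fx$wide)), "CAD")
  expect_error(raw_channel("HR", c(0, 5, 3), c(1, 2, 3)),
               "strictly increasing.*HR")
  expect_error(raw_channel("XX", c(0, 1), c(1, 2)), "unknown channel")
})

test_that("resampling interpolates linearly and never extrapolates", {
  # hand-computed linear interpolation of breath-by-breath VO2
  vo2 <- raw_channel("VO2", c(0, 2.5, 5), c(10, 12, 14))
  fr <- synchronize_resample(list(vo2))
  expect_equal(fr$time, 0:5)
  expect_equal(fr$channels$VO2, c(10, 10.8, 11.6, 12.4, 13.2, 14))

  # already-1-Hz input is returned unchanged
  hr <- raw_channel("HR", 0:50, 60 + sin(0:50))
  fr2 <- synchronize_resample(list(hr))
  expect_identical(fr2$channels$HR, 60 + sin(0:50))

  # frame is trimmed to the intersection of channel supports
  a <- raw_channel("HR", c(0, 100), c(60, 70))
  b <- raw_channel("VE", c(50, 150), c(10, 20))
  fr3 <- synchronize_resample(list(a, b))
  expect_equal(range(fr3$time), c(50, 100))

  short <- raw_channel("HR", c(0, 0.5), c(60, 61))
  expect_error(synchronize_resample(list(short)), "shorter than 2 s")
})

test_that("delta_hr applies the 1-s lag difference with zero first element", {
  expect_equal(delta_hr(c(60, 63, 61)), c(0, 3, -2))
  expect_equal(delta_hr(rep(70, 10)), rep(0, 10))
  expect_equal(delta_hr(70), 0)
  expect_error(delta_hr(numeric(0)), "empty")
  # telescoping: differences sum to last - first
  set.seed(3)
  hr <- cumsum(rnorm(200))
  expect_equal(sum(delta_hr(hr)[-1]), hr[200] - hr[1])
})

test_that("zero-phase low-pass filter meets its frequency-response contract", {
  # DC gain is exactly 1
  expect_equal(lowpass_001(rep(7, 500)), rep(7, 500), tolerance = 1e-9)

  # stopband: 0.05 Hz (5x cutoff) attenuated below 0.01
  t <- 0:1999
  x_stop <- sin(2 * pi * 0.05 * t)
  expect_lt(max(abs(lowpass_001(x_stop)[300:1700])), 0.01)

  # passband: 0.001 Hz passes within 1%
  t2 <- 0:3999
  x_pass <- sin(2 * pi * 0.001 * t2)
  y_pass <- lowpass_001(x_pass)
  expect_lt(abs(max(abs(y_pass[500:3500])) - 1), 0.01)

  # idempotence in the deep passband: filtering twice changes < 1%
  x_slow <- sin(2 * pi * 0.002 * t2)
  y1 <- lowpass_001(x_slow)
  y2 <- lowpass_001(y1)
  expect_lt(max(abs(y2[500:3500] - y1[500:3500])) / max(abs(y1[500:3500])), 0.01)

  # zero phase: cross-correlation peak of a 0.002 Hz sinusoid is at lag 0
  cc <- stats::ccf(y1[500:3500], x_slow[500:3500], lag.max = 30, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  expect_error(lowpass_001(1:10), "too short")
})

test_that("feature matrix has the fixed column order and segment restriction", {
  dir <- withr::local_tempdir()
  fx <- write_wide_fixture(dir)
  loaded <- load_participant(c(wide = fx$wide), fx$segments)
  fr <- synchronize_resample(loaded$channels, loaded$segments)
  fm <- build_feature_matrix(fr)
  expect_identical(colnames(fm$X), c("HR", "dHR", "VE", "BF", "Hacc", "CAD"))
  expect_equal(nrow(fm$X), length(fr$time))
  expect_equal(length(fm$y), nrow(fm$X))

  fm_seg <- build_feature_matrix(fr, segments = "ADL")
  expect_equal(nrow(fm_seg$X), 60)  # half-open [40, 100)

  fr_missing <- fr
  fr_missing$channels$VE <- NULL
  expect_error(build_feature_matrix(fr_missing), "VE")
})

test_that("resampling is the identity for integer-second input (property)", {
  set.seed(11)
  for (rep in 1:5) {
    v <- rnorm(100)
    ch <- raw_channel("Hacc", 0:99, v)
    fr <- synchronize_resample(list(ch))
    expect_identical(fr$channels$Hacc, v)
  }
})
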