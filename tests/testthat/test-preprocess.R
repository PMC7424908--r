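test_that("blink endpoint extension finds the artifact end, caps, and degrades gracefully", {
  # quiet flat signal after the blink: criterion met at the first sample
  ser <- blinky_series(tail = 0)
  expect_equal(extend_blink_end(ser, one_blink()), 8200)

  # a 140-ms constant-magnitude derivative artifact: extension lands at its end
  ser <- blinky_series(tail = 140)
  ext <- extend_blink_end(ser, one_blink())
  expect_lt(abs(ext - 8340), 20)

  # artifact persisting past the cap: extension is exactly +1000 ms
  ser <- blinky_series(n = 20000, tail = 2000)
  expect_equal(extend_blink_end(ser, one_blink()), 9200)

  # blink at the very end of the recording: original offset plus warning flag
  ser <- blinky_series(n = 8201, on = 8000, off = 8199)
  out <- extend_blink_end(ser, list(onset_ms = 8000, offset_ms = 8300))
  expect_equal(as.numeric(out), 8300)
  expect_true(attr(out, "warning"))
})

test_that("extension accuracy holds across generator blinks with 140-ms tails", {
  set.seed(71)
  cfg <- sim_config()
  n <- 120000
  pupil <- 2000 +
    fixpupil:::bl_noise(n, 1000, cfg$noise$hippus_hz, cfg$noise$hippus_sd) +
    rnorm(n, 0, cfg$noise$measurement_sd)
  wb <- fixpupil:::insert_blinks(pupil, cfg)
  ser <- sample_series(seq_len(n) - 1, rep(500, n), rep(400, n), wb$pupil, 1000)
  rep <- repair_blinks(ser, wb$blinks)
  err <- attr(rep, "blink_log")$extended_offset_ms - wb$blinks$artifact_end_ms
  expect_gte(nrow(wb$blinks), 5)
  expect_true(all(abs(err) <= 20))
})

test_that("extension is monotone in the z-fraction", {
  ser <- blinky_series(tail = 140)
  fr <- c(0.05, 0.1, 0.2, 0.4)
  ext <- vapply(fr, function(z)
    as.numeric(extend_blink_end(ser, one_blink(), blink_params(z_fraction = z))),
    numeric(1))
  expect_true(all(diff(ext) <= 0))
})

test_that("blink repair interpolates linearly and merges touching spans", {
  # bounding values 100 and 110 -> interpolated midpoint 105
  n <- 2000
  p <- rep(100, n); p[1102:n] <- 110
  p[901:1101] <- 0
  ser <- sample_series(seq_len(n) - 1, rep(0, n), rep(0, n), p, 1000)
  out <- repair_blinks(ser, data.frame(onset_ms = 900, offset_ms = 1100),
                       blink_params(max_extend_ms = 1))
  expect_equal(out$pupil[1001], 105, tolerance = 0.2)  # t = 1000 ms
  expect_true(all(out$interp[901:1101]))
  expect_false(any(out$interp[1:899]))
  expect_equal(out$pupil[1:899], p[1:899])

  # a linear ground-truth segment reconstructs with zero error
  p <- seq(0, 199.9, by = 0.1)
  ser <- sample_series(0:1999, rep(0, 2000), rep(0, 2000), p, 1000)
  out <- repair_blinks(ser, data.frame(onset_ms = 500, offset_ms = 700),
                       blink_params(max_extend_ms = 1))
  expect_equal(out$pupil, p, tolerance = 1e-12)

  # two blinks whose extended spans touch become one merged span
  spans <- fixpupil:::merge_intervals(c(100, 350, 900), c(400, 600, 950))
  expect_equal(spans$start, c(100, 900))
  expect_equal(spans$end, c(600, 950))
})

test_that("interpolated fraction counts masked samples", {
  n <- 3000
  ser <- sample_series(seq_len(n) - 1, rep(0, n), rep(0, n), rep(1, n), 1000,
                       interp = seq_len(n) <= 300)
  expect_equal(interpolated_fraction(ser, 0, n - 1), 0.1)
  expect_equal(interpolated_fraction(ser, 1000, n - 1), 0)
  expect_error(interpolated_fraction(ser, 5000, 6000), "no samples")
})

test_that("downsampling bin-averages and propagates the mask", {
  ser <- flat_series(n = 1000, pupil = 500)
  out <- downsample(ser, 50)
  expect_equal(length(out$t_ms), 50)
  expect_equal(out$pupil, rep(500, 50))
  expect_equal(out$rate_hz, 50)

  ramp <- sample_series(0:999, rep(0, 1000), rep(0, 1000), 0:999, 1000)
  out <- downsample(ramp, 50)
  expect_equal(out$pupil, seq(9.5, 989.5, by = 20))

  m <- flat_series(n = 1000)
  m$interp[15] <- TRUE
  out <- downsample(m, 50)
  expect_equal(which(out$interp), 1L)
  expect_error(downsample(flat_series(n = 1000), 30), "divisible")
})

test_that("zero-phase Butterworth filter matches its analytic magnitude contract", {
  fp <- filter_params()
  n <- 2000
  t <- seq_len(n) / 50
  # DC gain
  const <- sample_series(seq(0, by = 20, length.out = n), rep(0, n), rep(0, n),
                         rep(800, n), 50)
  out <- smooth_pupil(const, fp)
  expect_lt(max(abs(out$pupil - 800)) / 800, 1e-6)

  gain_at <- function(f) {
    s <- sample_series(seq(0, by = 20, length.out = n), rep(0, n), rep(0, n),
                       1000 + 100 * sin(2 * pi * f * t), 50)
    out <- smooth_pupil(s, fp)
    core <- 200:(n - 200)
    diff(range(out$pupil[core])) / diff(range(1000 + 100 * sin(2 * pi * f * t)))
  }
  analytic <- function(f) 1 / (1 + (f / 4)^6)  # squared single-pass magnitude
  # stopband: 20 Hz attenuated below 0.1%, and no more than the analog
  # prototype transmits
  g20 <- gain_at(20)
  expect_lt(g20, 0.001)
  expect_lt(g20, analytic(20) * 1.1)
  # passband/transition: digital response tracks the analytic curve
  expect_lt(abs(gain_at(0.5) - analytic(0.5)), 0.02)
  expect_lt(abs(gain_at(2) / analytic(2) - 1), 0.1)
  expect_error(smooth_pupil(flat_series(n = 50, rate = 50), fp), "warm-up")
})

test_that("preprocessing chain on blink-free data equals downsample + smooth", {
  set.seed(4)
  n <- 10000
  p <- 2000 + fixpupil:::bl_noise(n, 1000, 2, 30)
  ser <- sample_series(seq_len(n) - 1, rnorm(n, 500, 5), rnorm(n, 400, 5),
                       p, 1000)
  a <- preprocess(ser, event_table())
  b <- smooth_pupil(downsample(ser, 50))
  expect_equal(a$pupil, b$pupil)
  expect_equal(a$t_ms, b$t_ms)
})
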