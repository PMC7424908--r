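series_50hz <- function(values, gx = 0, gy = 0) {
  n <- length(values)
  sample_series(seq(0, by = 20, length.out = n), rep_len(gx, n),
                rep_len(gy, n), values, 50)
}

test_that("epoch extraction baseline-normalises and aligns exactly", {
  # constant pupil: all values 0
  ser <- series_50hz(rep(500, 500))
  ep <- extract_epoch(ser, 3000)
  expect_equal(ep$values, rep(0, 126))
  expect_equal(ep$rel_time_ms, seq(-500, 2000, by = 20))
  expect_equal(ep$baseline_mean, 500)

  # baseline 500, value 510 at +600 ms: +2% at that sample
  v <- rep(500, 500)
  t0 <- 3000
  v[(t0 + 600) / 20 + 1] <- 510
  ep <- extract_epoch(series_50hz(v), t0)
  expect_equal(ep$values[ep$rel_time_ms == 600], 2.0)
  expect_equal(ep$values[ep$rel_time_ms == 580], 0.0)

  # baseline-mean-zero property over random epochs
  set.seed(6)
  for (r in 1:20) {
    v <- 500 + rnorm(500, 0, 20)
    ep <- extract_epoch(series_50hz(abs(v) + 1), 3000 + 20 * sample(0:50, 1))
    bl <- ep$rel_time_ms >= -500 & ep$rel_time_ms < 0
    expect_lt(abs(mean(ep$values[bl])), 1e-10)
  }

  # rejection contracts
  r1 <- extract_epoch(series_50hz(rep(1, 50)), 400)
  expect_null(r1$values)
  expect_match(r1$reason, "window")
  r2 <- extract_epoch(series_50hz(rep(0, 500)), 3000)
  expect_null(r2$values)
  expect_match(r2$reason, "baseline")
})

test_that("grand averaging pools epochs or subjects as requested", {
  m <- matrix(rep(c(1, 3), each = 5), nrow = 2, byrow = TRUE)
  av <- grand_average(m, unit = "epoch")
  expect_equal(av$mean, rep(2, 5))
  expect_equal(av$n_units, 2)

  # identical epochs: mean equals any one, bootstrap SEM 0
  m <- matrix(rep(1.5, 20), 4, 5)
  av <- grand_average(m, unit = "epoch")
  expect_equal(av$mean, rep(1.5, 5))
  expect_equal(bootstrap_sem(m, n_boot = 200, seed = 1), rep(0, 5))

  # subject-first averaging: unequal epoch counts do not bias the grand mean
  vals <- rbind(matrix(1, 3, 4), matrix(3, 1, 4))
  subj <- c("a", "a", "a", "b")
  av <- grand_average(vals, unit = "subject", subject = subj)
  expect_equal(av$mean, rep(2, 4))
  av2 <- grand_average(vals, unit = "epoch")
  expect_equal(av2$mean, rep(1.5, 4))

  # linearity: scaling epochs scales the average
  set.seed(3)
  m <- matrix(rnorm(40), 8, 5)
  expect_equal(grand_average(3 * m, unit = "epoch")$mean,
               3 * grand_average(m, unit = "epoch")$mean)

  # equal contributions: subject- and epoch-level averaging agree exactly
  m2 <- m[rep(1:4, each = 2), ]
  subj <- rep(letters[1:4], each = 2)
  expect_equal(grand_average(m2, unit = "subject", subject = subj)$mean,
               grand_average(m2, unit = "epoch")$mean)
})

test_that("bootstrap SEM approximates the analytic standard error and is seeded", {
  set.seed(12)
  x <- matrix(scale(rnorm(100)), 100, 1)  # unit sample SD isolates the MC error
  sem <- bootstrap_sem(x, n_boot = 2000, seed = 9)
  expect_lt(abs(sem - 1 / sqrt(100)) / (1 / sqrt(100)), 0.15)
  expect_identical(sem, bootstrap_sem(x, n_boot = 2000, seed = 9))
  expect_error(bootstrap_sem(x[1, , drop = FALSE], 100, 1), "2 units")
})

test_that("whole-trial traces share a single pre-onset baseline", {
  tr <- mk_trials(1, onset = 6000, dur = 8000)
  # constant pupil: all three segments identically 0%
  ser <- series_50hz(rep(400, 1000))
  wt <- whole_trial_traces(ser, tr[1, ])
  expect_equal(wt$onset_locked$values, rep(0, 301))
  expect_equal(wt$search_phase$values, rep(0, 401))
  expect_equal(wt$offset_locked$values, rep(0, 301))

  # plateau 440 during search on baseline 400: +10%
  v <- rep(400, 1000)
  v[(6000 / 20 + 1):(14000 / 20 + 1)] <- 440
  wt <- whole_trial_traces(series_50hz(v), tr[1, ])
  expect_equal(wt$baseline_mean, 400)
  expect_equal(mean(wt$search_phase$values), 10, tolerance = 0.01)

  # half-interpolated baseline flags the trial
  ser <- series_50hz(rep(400, 1000))
  ser$interp[(5000 / 20):(6000 / 20)] <- TRUE
  expect_true(whole_trial_traces(ser, tr[1, ])$flagged)
})

test_that("time normalisation maps variable-length searches onto a common grid", {
  # constant traces stay constant at any length
  expect_equal(time_normalize(rep(2, 77))$values, rep(2, 101))
  # affine invariance: ramps of different lengths normalise identically
  r1 <- time_normalize(seq(0, 1, length.out = 300))$values
  r2 <- time_normalize(seq(0, 1, length.out = 500))$values
  expect_equal(r1, r2, tolerance = 1e-10)
  expect_equal(r1[c(1, 101)], c(0, 1))
  # sampled sinusoid reproduces the analytic phase curve within 1%
  x <- sin(2 * pi * seq(0, 1, length.out = 401))
  out <- time_normalize(x)
  expect_lt(max(abs(out$values - sin(2 * pi * out$phase))), 0.01)
  # min/max/endpoints of monotone traces preserved
  mono <- cumsum(runif(200))
  nm <- time_normalize(mono)$values
  expect_equal(range(nm), range(mono))
  expect_error(time_normalize(5), "single-sample")
})

test_that("condition averages group by targets and termination", {
  cfg <- sim_config(search = list(trials_per_condition = 3))
  ses <- simulate_search_session(cfg, seed = 41)
  pp <- preprocess(ses$series, ses$events)
  ca <- condition_averages(pp, ses$trials, group_by = "n_targets",
                           n_boot = 50)
  expect_true(all(names(ca$groups) %in% as.character(0:3)))
  g0 <- ca$groups[[1]]
  expect_equal(length(g0$search_phase$mean), 101)
  expect_equal(length(g0$onset_locked$mean), 301)
  expect_true(all(g0$onset_locked$sem >= 0))
  # the injected load ramp rises with targets: 3-target modulation > 0-target
  mod <- tapply(ca$modulation$mean_modulation, ca$modulation$group, mean)
  expect_gt(mod[["3"]], mod[["0"]])
})
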