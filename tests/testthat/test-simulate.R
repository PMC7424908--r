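test_that("search arrays satisfy the grid, centre and quadrant constraints", {
  cfg <- sim_config()
  g <- cfg$geometry
  span <- 20 * g$px_per_deg
  x0 <- g$screen_width_px / 2 - span / 2
  y0 <- g$screen_height_px / 2 - span / 2
  cell <- span / 10
  for (seed in 1:40) {
    nt <- seed %% 4
    ly <- make_search_array(nt, cfg, seed = seed)
    expect_equal(nrow(ly), 30)
    expect_equal(sum(ly$is_target), nt)
    col <- round((ly$x_px - x0) / cell + 0.5)
    row <- round((ly$y_px - y0) / cell + 0.5)
    expect_true(all(col %in% 1:10 & row %in% 1:10))
    expect_false(any(duplicated(cbind(row, col))))          # distinct cells
    expect_false(any(row %in% 5:6 & col %in% 5:6))          # centre excluded
    quad <- 1 + (col > 5) + 2 * (row > 5)
    expect_false(any(duplicated(quad[ly$is_target])))       # <=1 per quadrant
    # distractor orientation variants balanced within one of each other
    tab <- table(ly$variant[!ly$is_target])
    expect_lte(diff(range(tab)), 1)
  }
})

test_that("simulation is bitwise deterministic under a fixed seed", {
  cfg <- sim_config(search = list(trials_per_condition = 1))
  a <- simulate_search_session(cfg, seed = 77)
  b <- simulate_search_session(cfg, seed = 77)
  expect_identical(a$series$pupil, b$series$pupil)
  expect_identical(a$events, b$events)
  expect_identical(a$trials, b$trials)
  expect_identical(a$truth$injected, b$truth$injected)
  e1 <- simulate_ellipse_session(cfg, seed = 12)
  e2 <- simulate_ellipse_session(cfg, seed = 12)
  expect_identical(e1$series$pupil, e2$series$pupil)
})

test_that("the recorded minus true pupil equals the planar gaze term exactly", {
  cfg <- sim_config(pfe = list(b1 = -0.4, b2 = 0.15))
  ell <- simulate_ellipse_session(cfg, seed = 3, keep_true = TRUE)
  diffp <- ell$truth$recorded_pre_blink - ell$truth$true_pupil
  expect_equal(diffp, -0.4 * ell$series$gx_px + 0.15 * ell$series$gy_px,
               tolerance = 1e-12)
  # correlation with horizontal gaze carries the sign of b1
  keep <- ell$series$pupil > 0
  r <- cor(ell$series$pupil[keep], ell$series$gx_px[keep])
  expect_equal(sign(r), sign(cfg$pfe$b1))
})

test_that("a silent configuration produces identically flat epochs", {
  cfg <- sim_config(search = list(trials_per_condition = 1),
                    noise = list(hippus_sd = 0, measurement_sd = 0, drift_sd = 0),
                    blinks = list(rate_hz = 0),
                    behavior = list(error_rate = 0, gaze_noise_deg = 0),
                    response = list(target_amp = 0, revisit_amp = 0,
                                    distractor_revisit_amp = 0, press_amp = 0,
                                    onset_amp = 0, load_base_pct = 0,
                                    load_per_target_pct = 0))
  ses <- simulate_search_session(cfg, seed = 19)
  pp <- downsample(ses$series, 50)   # no smoothing needed on noiseless data
  fix <- fixation_pipeline(ses$events, ses$trials, ses$layouts,
                           selection_params(), cfg$geometry)
  ev <- select_epoch_events(fix, ses$trials, "target_all")
  # remove the gaze plane first: with zero PFE the epochs are exactly zero
  cfg0 <- cfg; model <- structure(list(b0 = 0, b1 = cfg$pfe$b1,
                                       b2 = cfg$pfe$b2), class = "fp_pfe")
  eps <- extract_epochs(apply_pfe_correction(pp, model), ev)
  expect_gt(nrow(eps$values), 0)
  expect_lt(max(abs(eps$values)), 1e-9)
})

test_that("the ground-truth report conserves injected events", {
  cfg <- sim_config(search = list(trials_per_condition = 2))
  ses <- simulate_search_session(cfg, seed = 23)
  rep <- ground_truth_report(ses$truth)
  expect_equal(sum(rep$n_events), nrow(ses$truth$injected))
  expect_equal(sum(rep$n_events[rep$kind == "discovery"]),
               sum(ses$truth$injected$kind == "discovery"))
  # every trial with targets and an onset kernel appears
  expect_true(all(rep$n_events >= 1))

  empty <- ground_truth_report(list(injected = NULL, fixations = NULL))
  expect_equal(nrow(empty), 0)
})

test_that("press kernels separate self-terminated trials at search offset", {
  cfg <- sim_config(search = list(trials_per_condition = 3),
                    response = list(target_amp = 0, revisit_amp = 0,
                                    distractor_revisit_amp = 0, onset_amp = 0,
                                    load_base_pct = 0, load_per_target_pct = 0),
                    behavior = list(error_rate = 0))
  ses <- simulate_search_session(cfg, seed = 29)
  pp <- preprocess(ses$series, ses$events)
  st <- as.logical(ses$trials$self_terminated)
  expect_gt(sum(st), 0); expect_gt(sum(!st), 0)
  mean_around_offset <- function(rows) {
    vals <- sapply(rows, function(i) {
      wt <- whole_trial_traces(pp, ses$trials[i, ])
      mean(wt$offset_locked$values[wt$offset_locked$rel_time_ms > -500 &
                                   wt$offset_locked$rel_time_ms < 1000])
    })
    mean(vals)
  }
  expect_gt(mean_around_offset(which(st)), mean_around_offset(which(!st)) + 1)
})
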