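g35 <- geometry(px_per_deg = 35)

test_that("threshold-based detection separates fixations and saccades", {
  # stationary 2 s, instantaneous 5-degree jump, stationary 2 s
  n <- 4000
  gx <- c(rep(300, 2000), rep(300 + 5 * 35, 2000))
  ser <- sample_series(seq_len(n) - 1, gx, rep(300, n), rep(1000, n), 1000)
  ev <- detect_fixations(ser, geometry = g35)
  expect_equal(sum(ev$kind == "fixation"), 2)
  expect_equal(sum(ev$kind == "saccade"), 1)
  fx <- ev[ev$kind == "fixation", ]
  expect_equal(fx$x_px, c(300, 475), tolerance = 0.01)

  # slow drift at 10 deg/s stays under every threshold: a single fixation
  drift <- sample_series(seq_len(n) - 1, 300 + (seq_len(n) / 1000) * 10 * 35,
                         rep(300, n), rep(1000, n), 1000)
  ev <- detect_fixations(drift, geometry = g35)
  expect_equal(sum(ev$kind == "fixation"), 1)

  # per-sample threshold oracle: velocity from the same smoothed differentials
  vx <- signal::sgolayfilt(drift$gx_px, p = 2, n = 9, m = 1) * 1000 / 35
  expect_true(all(abs(vx[10:3990]) < 30))
})

test_that("detected fixation count matches the generated scanpath", {
  cfg <- sim_config(search = list(trials_per_condition = 1),
                    blinks = list(rate_hz = 0))
  ses <- simulate_search_session(cfg, seed = 17)
  tr <- ses$trials[1, ]
  ev <- detect_fixations(ses$series, geometry = cfg$geometry)
  det <- ev[ev$kind == "fixation" &
            ev$onset_ms >= tr$search_onset_ms + 100 &
            ev$offset_ms <= tr$search_offset_ms, ]
  true_fx <- ses$truth$fixations[
    ses$truth$fixations$trial_id == tr$trial_id &
    ses$truth$fixations$onset_ms >= tr$search_onset_ms + 100 &
    ses$truth$fixations$offset_ms <= tr$search_offset_ms, ]
  expect_equal(nrow(det), nrow(true_fx))
})

test_that("brief fixations merge into near neighbours or are discarded", {
  p <- selection_params()
  # 80-ms fixation 0.5 deg from its 300-ms predecessor: merged
  fx <- rbind(mk_fix("t01", 1000, 300, 100, 100),
              mk_fix("t01", 1330, 80, 100 + 0.5 * 35, 100))
  out <- merge_or_discard_brief(fx, p, g35)
  expect_equal(nrow(out), 1)
  expect_gte(out$duration_ms, 380)
  # centre becomes the duration-weighted mean of the originals
  expect_equal(out$x_px, (300 * 100 + 80 * 117.5) / 380)

  # 80-ms fixation >= 1 deg from both neighbours: discarded
  fx <- rbind(mk_fix("t01", 1000, 300, 100, 100),
              mk_fix("t01", 1330, 80, 100 + 1.5 * 35, 100),
              mk_fix("t01", 1450, 300, 100, 100))
  out <- merge_or_discard_brief(fx, p, g35)
  expect_equal(nrow(out), 2)
  expect_true(all(out$duration_ms == 300))

  # cascade: two 60-ms fixations beside one 200-ms fixation, all within 1 deg
  fx <- rbind(mk_fix("t01", 1000, 200, 100, 100),
              mk_fix("t01", 1230, 60, 110, 100),
              mk_fix("t01", 1320, 60, 120, 100))
  out <- merge_or_discard_brief(fx, p, g35)
  expect_equal(nrow(out), 1)
  expect_equal(out$onset_ms, 1000)
  expect_equal(out$offset_ms, 1380)
})

test_that("interest areas assign by nearest centre within radius, ties to lowest id", {
  p <- selection_params()
  ly <- data.frame(trial_id = "t01", item_id = c(5, 2),
                   x_px = c(100, 100 + 2 * 35), y_px = c(100, 100),
                   is_target = c(TRUE, FALSE))
  # 1.0 deg from the target, far from the rest
  fx <- mk_fix("t01", 0, 200, 100, 100 + 1.0 * 35)
  out <- assign_interest_areas(fx, ly, p, g35)
  expect_equal(out$item_class, "target")
  expect_equal(out$item_id, 5)

  # 1.3 deg from everything: none
  fx <- mk_fix("t01", 0, 200, 100, 100 + 1.3 * 35)
  out <- assign_interest_areas(fx, ly, p, g35)
  expect_equal(out$item_class, "none")
  expect_true(is.na(out$item_id))

  # equidistant midpoint: nearest then lowest item id wins
  fx <- mk_fix("t01", 0, 200, 100 + 35, 100)
  out <- assign_interest_areas(fx, ly, p, g35)
  expect_equal(out$item_id, 2)
})

test_that("duration filters enforce the minimum and the pooled 3-SD cap", {
  p <- selection_params()
  fx <- rbind(mk_fix("t01", 0, 119, 0, 0), mk_fix("t01", 200, 120, 0, 0))
  fx$item_class <- "distractor"
  tg <- mk_fix("t01", 500, 200, 0, 0); tg$item_class <- "target"
  out <- filter_durations(rbind(fx, tg), p)
  expect_equal(sort(out$duration_ms), c(120, 200))

  # target durations {200,220,240,260,280}: cap = 240 + 3*31.62 = 334.9
  tg <- do.call(rbind, lapply(seq(200, 280, 20), function(d)
    mk_fix("t01", d * 10, d, 0, 0)))
  tg$item_class <- "target"
  long <- mk_fix("t01", 5000, 400, 0, 0)
  long$item_class <- "distractor"
  out <- filter_durations(rbind(tg, long), p)
  expect_equal(nrow(out), 5)
  expect_false(400 %in% out$duration_ms)

  # equal durations: zero SD, nothing capped
  eq <- do.call(rbind, lapply(1:4, function(i) mk_fix("t01", i * 1000, 240, 0, 0)))
  eq$item_class <- "target"
  expect_equal(nrow(filter_durations(eq, p)), 4)

  # no targets at all: cap skipped with a warning
  fx <- mk_fix("t01", 0, 500, 0, 0); fx$item_class <- "distractor"
  expect_warning(out <- filter_durations(fx, p), "skipped")
  expect_equal(nrow(out), 1)
})

test_that("boundary exclusions around search onset and button press", {
  p <- selection_params()
  tr <- mk_trials(1, onset = 0, dur = 10000)
  fx <- rbind(mk_fix("t01", 999, 200, 0, 0), mk_fix("t01", 1000, 200, 0, 0))
  out <- exclude_boundary_fixations(fx, tr, p)
  expect_equal(out$onset_ms, 1000)

  # non-terminated trial: no press-window exclusion
  fx <- mk_fix("t01", 9000, 200, 0, 0)
  expect_equal(nrow(exclude_boundary_fixations(fx, tr, p)), 1)

  # press at 8000: onset 5001 dropped, 5000 kept
  tr <- mk_trials(1, onset = 0, dur = 8000, self_term = TRUE, press = 8000)
  fx <- rbind(mk_fix("t01", 5000, 200, 0, 0), mk_fix("t01", 5001, 200, 0, 0))
  out <- exclude_boundary_fixations(fx, tr, p)
  expect_equal(out$onset_ms, 5000)
})

test_that("visit classification distinguishes discoveries, revisits and short returns", {
  p <- selection_params()
  mk_item <- function(onset, item, cls = "target") {
    f <- mk_fix("t01", onset, 200, 0, 0)
    f$item_id <- item; f$item_class <- cls
    f
  }
  # A B A(2000): discovery then true revisit
  fx <- rbind(mk_item(0, 1), mk_item(400, 2, "distractor"), mk_item(2000, 1))
  out <- classify_visits(fx, p)
  expect_equal(out$visit_type[out$item_id == 1], c("discovery", "revisit"))

  # A B A(800): the return is too early
  fx <- rbind(mk_item(0, 1), mk_item(400, 2, "distractor"), mk_item(800, 1))
  out <- classify_visits(fx, p)
  expect_equal(out$visit_type[3], "revisit_short")

  # consecutive same-item fixations never count as revisits
  fx <- rbind(mk_item(0, 1), mk_item(1500, 1))
  out <- classify_visits(fx, p)
  expect_equal(out$visit_type[2], "revisit_short")

  # discovery order numbers target discoveries by onset
  fx <- rbind(mk_item(1500, 3), mk_item(4000, 7), mk_item(7000, 9))
  out <- classify_visits(fx, p)
  expect_equal(out$discovery_order, 1:3)
})

test_that("named selections honour correctness and exclusion rules", {
  p <- selection_params()
  tr <- rbind(mk_trials(1, n_targets = 1, correct = TRUE),
              mk_trials(1, n_targets = 1, correct = FALSE))
  tr$trial_id <- c("t01", "t02")
  mk_item <- function(trial, onset, item, cls, visit) {
    f <- mk_fix(trial, onset, 200, 0, 0)
    f$item_id <- item; f$item_class <- cls; f$visit_type <- visit
    f
  }
  fx <- rbind(mk_item("t01", 7000, 1, "target", "discovery"),
              mk_item("t01", 8000, 2, "target", "revisit_short"),
              mk_item("t02", 7000, 1, "target", "discovery"))
  out <- select_epoch_events(fx, tr, "target_all")
  expect_equal(nrow(out), 1)          # incorrect trial fully excluded
  expect_equal(out$trial_id, "t01")   # and revisit_short never selected
  expect_error(select_epoch_events(fx, tr, "nonsense"), "target_all")
})

test_that("pipeline selections reconcile with the generator ledger", {
  cfg <- sim_config(search = list(trials_per_condition = 4))
  for (seed in c(5, 9)) {
    ses <- simulate_search_session(cfg, seed = seed)
    fix <- fixation_pipeline(ses$events, ses$trials, ses$layouts,
                             selection_params(), cfg$geometry)
    led <- ses$truth$fixations
    expect_equal(nrow(select_epoch_events(fix, ses$trials, "target_all")),
                 sum(led$eligible_target_all))
    expect_equal(nrow(select_epoch_events(fix, ses$trials, "distractor_all")),
                 sum(led$eligible_distractor_all))
    # determinism: rerunning the selection yields the identical table
    fix2 <- fixation_pipeline(ses$events, ses$trials, ses$layouts,
                              selection_params(), cfg$geometry)
    expect_identical(fix, fix2)
  }
})
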