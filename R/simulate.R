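#' Simulation configuration
#'
#' Defaults reproduce the reference study conditions: a 30-s ellipse-tracking
#' calibration (6 counterclockwise rotations mapping a 20 x 20 deg field), and
#' multi-target search trials (0-3 forward-facing targets among 30 items on a
#' 10 x 10 grid with the 4 centre cells excluded and at most one target per
#' quadrant; 2000 ms fixation, 4000 ms mask, up to 10 s search, 2000 ms mask),
#' with 18 trials per targets level per session and two sessions per subject.
#' Pupil responses are Erlang-shaped kernels whose default amplitudes and peak
#' latencies sit at the reported fixation-aligned responses (target discovery
#' ~2% peaking ~680 ms after fixation onset). Pupil noise is dominated by
#' slow physiological fluctuation (hippus, band-limited at ~2 Hz) plus a small
#' white measurement component, which is what makes the derivative-based
#' blink-endpoint rule well-defined; blink recovery artifacts are decaying
#' high-frequency oscillations lasting `artifact_tail_ms` past the parsed
#' blink end.
#'
#' @param geometry [geometry()].
#' @param ... Named overrides of any nested default, e.g.
#'   `sim_config(search = list(trials_per_condition = 2))` replaces only the
#'   named fields.
#' @return A nested list of class `fp_sim_config`.
#' @export
sim_config <- function(geometry = fixpupil::geometry(), ...) {
  cfg <- list(
    geometry = geometry,
    pfe = list(b0 = 2000, b1 = -0.483, b2 = 0.009),
    noise = list(hippus_sd = 20, hippus_hz = 0.5, measurement_sd = 0.05,
                 drift_sd = 15, drift_hz = 0.05),
    blinks = list(rate_hz = 0.15, duration_mean_ms = 150, duration_sd_ms = 30,
                  artifact_tail_ms = 140, artifact_amp = 1000,
                  artifact_freq_hz = 125),
    ellipse = list(duration_s = 30, rotations = 6, radius_deg = 10,
                   tracking_lag_ms = 100, tracking_jitter_deg = 0.3,
                   start_press_amp = 2),
    search = list(trials_per_condition = 18, conditions = 0:3, grid_n = 10,
                  set_size = 30, span_deg = 20, center_exclusion = 4,
                  quadrant_rule = TRUE, fixation_ms = 2000, mask_ms = 4000,
                  max_search_ms = 10000, post_mask_ms = 2000, gap_ms = 1500),
    behavior = list(fixdur_meanlog = log(250), fixdur_sdlog = 0.3,
                    fixdur_min_ms = 120, saccade_ms = 25,
                    reading_bias = 0.8, revisit_rate = 0.12,
                    error_rate = 0.1, p_terminate_on_third = 0.95,
                    p_terminate_exhausted = 0.9, decision_delay_ms = 400,
                    fix_jitter_deg = 0.2, gaze_noise_deg = 0.03),
    response = list(target_amp = 2.02, target_peak_ms = 680,
                    revisit_amp = 3.41, revisit_peak_ms = 520,
                    distractor_revisit_amp = 1.47,
                    distractor_revisit_peak_ms = 500,
                    press_amp = 5, press_peak_ms = 1200, press_lead_ms = 1000,
                    onset_amp = 5, onset_peak_ms = 2000,
                    load_base_pct = 5, load_per_target_pct = 1.8,
                    kernel_shape = 4),
    rate_hz = 1000)
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]]) &&
        !inherits(over[[nm]], "fp_geometry")) {
      for (k in names(over[[nm]])) cfg[[nm]][[k]] <- over[[nm]][[k]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  class(cfg) <- "fp_sim_config"
  cfg
}

# band-limited Gaussian noise: white noise low-passed at cutoff_hz and
# rescaled to the target marginal SD
bl_noise <- function(n, rate_hz, cutoff_hz, sd_target) {
  if (sd_target <= 0 || n == 0L) return(numeric(n))
  burn <- min(2000L, 4L * n)
  w <- rnorm(n + burn)
  bf <- signal::butter(2, min(0.99, cutoff_hz / (rate_hz / 2)), type = "low")
  x <- as.numeric(signal::filter(bf, w))[-seq_len(burn)]
  s <- sd(x)
  if (!is.finite(s) || s == 0) s <- 1
  x * sd_target / s
}

# Erlang-family response kernel: unit peak at `peak_ms`, evaluated at 1 kHz
# over 4x the peak latency.
resp_kernel <- function(peak_ms, shape = 4) {
  t <- seq_len(round(4 * peak_ms))
  (t / peak_ms)^shape * exp(shape * (1 - t / peak_ms))
}

add_kernel <- function(x, at_idx, kernel, amp) {
  n <- length(x)
  idx <- at_idx + seq_along(kernel) - 1L
  ok <- idx >= 1L & idx <= n
  x[idx[ok]] <- x[idx[ok]] + amp * kernel[ok]
  x
}

# Draw non-overlapping blink spans, zero the recorded pupil inside them and
# add a decaying oscillatory recovery artifact after each parsed offset.
# Returns list(pupil, blinks = data.frame(onset_ms, offset_ms, artifact_end_ms)).
insert_blinks <- function(pupil, cfg, margin_ms = 1500) {
  n <- length(pupil)
  bl <- cfg$blinks
  lam <- bl$rate_hz * n / 1000
  k <- rpois(1, lam)
  onsets <- sort(round(runif(k, margin_ms, n - margin_ms - 2500)))
  durs <- pmax(50, round(rnorm(k, bl$duration_mean_ms, bl$duration_sd_ms)))
  keep <- rep(TRUE, k)
  if (k > 1L) for (i in 2:k)
    if (onsets[i] < onsets[i - 1] + durs[i - 1] + bl$artifact_tail_ms + 500)
      keep[i] <- FALSE
  onsets <- onsets[keep]; durs <- durs[keep]
  out <- data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                    artifact_end_ms = numeric(0))
  for (i in seq_along(onsets)) {
    on <- onsets[i]; off <- on + durs[i]
    i_on <- on + 1L; i_off <- min(off + 1L, n)
    pupil[i_on:i_off] <- 0
    tail_t <- seq_len(bl$artifact_tail_ms)
    osc_amp <- bl$artifact_amp * 1000 / (2 * pi * bl$artifact_freq_hz)
    art <- osc_amp * exp(-tail_t / bl$artifact_tail_ms) *
      sin(2 * pi * bl$artifact_freq_hz * tail_t / 1000)
    idx <- i_off + tail_t
    ok <- idx <= n
    pupil[idx[ok]] <- pmax(0, pupil[idx[ok]] + art[ok])
    out <- rbind(out, data.frame(onset_ms = on, offset_ms = off,
                                 artifact_end_ms = off + bl$artifact_tail_ms))
  }
  list(pupil = pupil, blinks = out)
}

#' Simulate an ellipse-tracking calibration session
#'
#' Gaze follows a circular path (6 counterclockwise rotations in 30 s,
#' starting at the top) with a tracking lag and band-limited jitter; the true
#' pupil is baseline + slow drift + hippus (+ a small transient from the
#' trial-initiating button press); the recorded pupil adds the planar
#' foreshortening component `b1*X + b2*Y`, then blinks with recovery
#' artifacts.
#'
#' @param config [sim_config()].
#' @param seed RNG seed.
#' @param session_id Label stored in the outputs.
#' @param keep_true Keep the noiseless bookkeeping traces in the ground truth
#'   (memory-heavy; default FALSE).
#' @return A list with `series`, `events` and `truth` (PFE coefficients, blink
#'   spans with artifact ends, and optionally the true/pre-blink pupil).
#' @export
simulate_ellipse_session <- function(config = sim_config(), seed = 1,
                                     session_id = "ellipse", keep_true = FALSE) {
  set.seed(seed)
  g <- config$geometry
  el <- config$ellipse
  n <- el$duration_s * 1000
  t <- seq_len(n) - 1
  cx <- g$screen_width_px / 2; cy <- g$screen_height_px / 2
  r <- el$radius_deg * g$px_per_deg
  theta <- pi / 2 + 2 * pi * el$rotations * (t - el$tracking_lag_ms) /
    (el$duration_s * 1000)
  gx <- cx + r * cos(theta) +
    bl_noise(n, 1000, 5, el$tracking_jitter_deg * g$px_per_deg)
  gy <- cy - r * sin(theta) +
    bl_noise(n, 1000, 5, el$tracking_jitter_deg * g$px_per_deg)

  p0 <- config$pfe$b0
  true_p <- p0 +
    bl_noise(n, 1000, config$noise$drift_hz, config$noise$drift_sd) +
    bl_noise(n, 1000, config$noise$hippus_hz, config$noise$hippus_sd) +
    rnorm(n, 0, config$noise$measurement_sd)
  true_p <- add_kernel(true_p, 1L, resp_kernel(1000, config$response$kernel_shape),
                       el$start_press_amp / 100 * p0)
  rec <- true_p + config$pfe$b1 * gx + config$pfe$b2 * gy
  withblinks <- insert_blinks(rec, config)

  series <- sample_series(t, gx, gy, withblinks$pupil, 1000)
  bl <- withblinks$blinks
  events <- event_table(
    kind = c("button_press", rep("blink", nrow(bl))),
    onset_ms = c(0, bl$onset_ms), offset_ms = c(0, bl$offset_ms))
  truth <- list(pfe = config$pfe, blinks = bl, session_id = session_id)
  if (keep_true) {
    truth$true_pupil <- true_p
    truth$recorded_pre_blink <- rec
  }
  list(series = series, events = events, truth = truth)
}

#' Generate one search-array layout
#'
#' Thirty items on distinct cells of the 10 x 10 grid spanning the stimulus
#' field, excluding the four centre cells; at most one target per screen
#' quadrant; distractor orientation variants balanced where divisible, else
#' topped up at random. Item ids follow reading order (row-major).
#'
#' @param n_targets 0-3.
#' @param config [sim_config()].
#' @param trial_id Label.
#' @param seed Optional seed (omit when called inside a seeded simulation).
#' @return An [item_layouts()] data.frame for one trial.
#' @export
make_search_array <- function(n_targets, config = sim_config(),
                              trial_id = "t01", seed = NULL) {
  if (!n_targets %in% 0:3) stop_fixpupil("n_targets must be 0..3")
  if (!is.null(seed)) set.seed(seed)
  g <- config$geometry
  sc <- config$search
  gn <- sc$grid_n
  span <- sc$span_deg * g$px_per_deg
  cell <- span / gn
  x0 <- g$screen_width_px / 2 - span / 2
  y0 <- g$screen_height_px / 2 - span / 2
  cells <- expand.grid(col = seq_len(gn), row = seq_len(gn))
  cells$x_px <- x0 + (cells$col - 0.5) * cell
  cells$y_px <- y0 + (cells$row - 0.5) * cell
  mid <- c(gn / 2, gn / 2 + 1)
  centre <- cells$row %in% mid & cells$col %in% mid
  cells <- cells[!centre, , drop = FALSE]
  cells$quadrant <- 1 + (cells$col > gn / 2) + 2 * (cells$row > gn / 2)

  tgt_rows <- integer(0)
  if (n_targets > 0) {
    qs <- sample(1:4, n_targets)
    tgt_rows <- vapply(qs, function(q)
      sample(which(cells$quadrant == q), 1), integer(1))
  }
  rest <- setdiff(seq_len(nrow(cells)), tgt_rows)
  dis_rows <- sample(rest, sc$set_size - n_targets)
  sel <- cells[c(tgt_rows, dis_rows), , drop = FALSE]
  sel$is_target <- c(rep(TRUE, n_targets), rep(FALSE, sc$set_size - n_targets))
  nd <- sc$set_size - n_targets
  variants <- rep(c(90, 180, 270), length.out = 3 * ceiling(nd / 3))
  sel$variant <- NA_real_
  sel$variant[!sel$is_target] <- sample(variants, nd)
  ord <- order((sel$row - 1) * gn + sel$col)
  sel <- sel[ord, , drop = FALSE]
  out <- data.frame(trial_id = trial_id, item_id = seq_len(nrow(sel)),
                    x_px = sel$x_px, y_px = sel$y_px,
                    is_target = sel$is_target, variant = sel$variant)
  rownames(out) <- NULL
  out
}

#' Simulate a complete visual-search session
#'
#' Per trial: a reading-order-biased scanpath over the items with occasional
#' revisits, truncated-lognormal fixation durations and 25-ms saccades that
#' exceed the detection thresholds; the true pupil is baseline + drift +
#' hippus + a per-condition load ramp + Erlang kernels injected at search
#' onset, target discoveries, target/distractor revisits and the terminating
#' button press; the recorded pupil adds the session's foreshortening plane,
#' then blinks. Behavioural outcomes follow the termination policy (press on
#' third-target discovery or on an exhausted array, otherwise 10-s timeout)
#' and the error rate. The ground truth logs every injected event, blink
#' span and fixation with its eligibility under the selection rules.
#'
#' @param config [sim_config()].
#' @param seed RNG seed.
#' @param subject_id,session_id Labels.
#' @param keep_true Keep bookkeeping traces (default FALSE).
#' @return A list with `series`, `events`, `trials`, `layouts`, `truth`.
#' @export
simulate_search_session <- function(config = sim_config(), seed = 1,
                                    subject_id = "s01", session_id = "a",
                                    keep_true = FALSE) {
  set.seed(seed)
  g <- config$geometry
  sc <- config$search
  bh <- config$behavior
  rs <- config$response
  p0 <- config$pfe$b0
  cx <- g$screen_width_px / 2; cy <- g$screen_height_px / 2

  conds <- sample(rep(sc$conditions, each = sc$trials_per_condition))
  n_trials <- length(conds)

  draw_fixdur <- function(k) {
    d <- round(rlnorm(k, bh$fixdur_meanlog, bh$fixdur_sdlog))
    pmax(d, bh$fixdur_min_ms)
  }

  trial_plan <- list()
  layouts <- NULL
  cursor <- 0
  for (ti in seq_len(n_trials)) {
    nt <- conds[ti]
    tid <- sprintf("%s_%s_t%03d", subject_id, session_id, ti)
    ly <- make_search_array(nt, config, trial_id = tid)
    layouts <- rbind(layouts, ly)

    onset <- cursor + sc$fixation_ms + sc$mask_ms
    # visit order: reading order perturbed by the (1 - bias) noise
    noise_sd <- (1 - bh$reading_bias) * 15
    visit_order <- order(ly$item_id + rnorm(nrow(ly), 0, noise_sd))
    visited <- integer(0)
    found_targets <- 0
    fx <- NULL
    t_cur <- onset
    press_t <- NA_real_
    self_term <- FALSE
    # initial fixation at screen centre carried over from the fixation period
    d0 <- draw_fixdur(1)
    fx <- rbind(fx, data.frame(onset_ms = t_cur, offset_ms = t_cur + d0,
                               x_px = cx, y_px = cy, item_id = NA_integer_))
    t_cur <- t_cur + d0
    qi <- 1L
    last_item <- NA_integer_
    while (TRUE) {
      revisit_pool <- setdiff(visited, last_item)
      do_revisit <- length(revisit_pool) > 0 && runif(1) < bh$revisit_rate
      if (do_revisit) {
        item <- revisit_pool[sample.int(length(revisit_pool), 1)]
      } else if (qi <= length(visit_order)) {
        item <- visit_order[qi]
        qi <- qi + 1L
      } else break
      dur <- draw_fixdur(1)
      on_t <- t_cur + bh$saccade_ms
      off_t <- on_t + dur
      if (off_t > onset + sc$max_search_ms) break
      last_item <- item
      pos <- c(ly$x_px[item], ly$y_px[item]) +
        rnorm(2, 0, bh$fix_jitter_deg * g$px_per_deg)
      fx <- rbind(fx, data.frame(onset_ms = on_t, offset_ms = off_t,
                                 x_px = pos[1], y_px = pos[2],
                                 item_id = ly$item_id[item]))
      t_cur <- off_t
      if (!do_revisit) {
        visited <- c(visited, item)
        if (ly$is_target[item]) found_targets <- found_targets + 1
        if (nt == 3 && found_targets == 3 &&
            runif(1) < bh$p_terminate_on_third) {
          press_t <- t_cur + bh$decision_delay_ms
          break
        }
        if (length(visited) == nrow(ly) &&
            runif(1) < bh$p_terminate_exhausted) {
          press_t <- t_cur + bh$decision_delay_ms
          break
        }
      }
    }
    if (!is.na(press_t) && press_t < onset + sc$max_search_ms) {
      offset <- press_t
      self_term <- TRUE
    } else {
      press_t <- NA_real_
      offset <- onset + sc$max_search_ms
    }
    resp <- nt
    if (runif(1) < bh$error_rate) {
      resp <- if (nt == 0) 1 else if (nt == 3) 2 else
        nt + sample(c(-1, 1), 1)
    }
    trial_plan[[ti]] <- list(
      tid = tid, nt = nt, onset = onset, offset = offset,
      press = press_t, self_term = self_term, resp = resp,
      fx = fx, ly = ly, t_end = offset + sc$post_mask_ms + sc$gap_ms)
    cursor <- trial_plan[[ti]]$t_end
  }

  n <- ceiling(cursor) + 1000
  t <- seq_len(n) - 1

  # gaze assembly: dwell spans filled, saccade gaps linearly interpolated
  gx <- rep(NA_real_, n); gy <- rep(NA_real_, n)
  gx[1] <- cx; gy[1] <- cy; gx[n] <- cx; gy[n] <- cy
  for (tp in trial_plan) {
    i0 <- round(tp$offset) + 26L
    gx[i0:min(round(tp$t_end), n)] <- cx
    gy[i0:min(round(tp$t_end), n)] <- cy
    pre <- round(tp$onset - sc$fixation_ms - sc$mask_ms) + 1L
    gx[pre:round(tp$fx$onset_ms[1])] <- cx
    gy[pre:round(tp$fx$onset_ms[1])] <- cy
    for (i in seq_len(nrow(tp$fx))) {
      idx <- (round(tp$fx$onset_ms[i]) + 1L):round(tp$fx$offset_ms[i])
      gx[idx] <- tp$fx$x_px[i]; gy[idx] <- tp$fx$y_px[i]
    }
    # hold last gaze position until the search display is replaced by the mask
    last <- nrow(tp$fx)
    idx <- (round(tp$fx$offset_ms[last]) + 1L):round(tp$offset)
    if (length(idx) && idx[1] <= idx[length(idx)]) {
      gx[idx] <- tp$fx$x_px[last]; gy[idx] <- tp$fx$y_px[last]
    }
  }
  fill <- function(v) approx(t[!is.na(v)], v[!is.na(v)], xout = t, rule = 2)$y
  gx <- fill(gx); gy <- fill(gy)
  gx <- gx + bl_noise(n, 1000, 5, bh$gaze_noise_deg * g$px_per_deg)
  gy <- gy + bl_noise(n, 1000, 5, bh$gaze_noise_deg * g$px_per_deg)

  # true pupil: baseline + drift + hippus + load ramps + kernels
  true_p <- p0 +
    bl_noise(n, 1000, config$noise$drift_hz, config$noise$drift_sd) +
    bl_noise(n, 1000, config$noise$hippus_hz, config$noise$hippus_sd) +
    rnorm(n, 0, config$noise$measurement_sd)
  k_target <- resp_kernel(rs$target_peak_ms, rs$kernel_shape)
  k_revisit <- resp_kernel(rs$revisit_peak_ms, rs$kernel_shape)
  k_drev <- resp_kernel(rs$distractor_revisit_peak_ms, rs$kernel_shape)
  k_press <- resp_kernel(rs$press_peak_ms, rs$kernel_shape)
  k_onset <- resp_kernel(rs$onset_peak_ms, rs$kernel_shape)

  injected <- NULL
  note <- function(kind, tid, at, amp) data.frame(
    kind = kind, trial_id = tid, t_ms = at, amplitude_pct = amp)
  fix_ledger <- NULL
  for (tp in trial_plan) {
    # per-trial contribution segment: kernels and ramps are accumulated in a
    # short local vector and spliced into the session trace once, so the
    # multi-million-sample trace is never copied per event
    s0 <- round(tp$onset - sc$fixation_ms - sc$mask_ms) + 1L
    s1 <- min(round(tp$t_end) + 8000L, n)
    contrib <- numeric(s1 - s0 + 1L)
    if (rs$onset_amp > 0) {
      contrib <- add_kernel(contrib, round(tp$onset) + 2L - s0, k_onset,
                            rs$onset_amp / 100 * p0)
      injected <- rbind(injected, note("onset", tp$tid, tp$onset, rs$onset_amp))
    }
    ramp_amp <- (rs$load_base_pct + rs$load_per_target_pct * tp$nt) / 100 * p0
    if (ramp_amp != 0) {
      i0 <- round(tp$onset) + 2L - s0; i1 <- round(tp$offset) + 2L - s0
      ramp <- seq(0, 1, length.out = i1 - i0 + 1L) * ramp_amp
      contrib[i0:i1] <- contrib[i0:i1] + ramp
      dec <- seq(1, 0, length.out = 1000) * ramp_amp
      idx <- i1 + seq_len(1000)
      ok <- idx <= length(contrib)
      contrib[idx[ok]] <- contrib[idx[ok]] + dec[ok]
    }
    # classify the realised scanpath for kernels and the eligibility ledger
    f <- tp$fx
    f$is_target <- FALSE
    f$item_class <- "none"
    has_item <- !is.na(f$item_id)
    f$is_target[has_item] <- tp$ly$is_target[match(f$item_id[has_item],
                                                   tp$ly$item_id)]
    f$item_class[has_item] <- ifelse(f$is_target[has_item],
                                     "target", "distractor")
    f$visit_type <- "unassigned"
    first_on <- list(); prev_item <- NA_integer_
    for (i in seq_len(nrow(f))) {
      it <- f$item_id[i]
      if (is.na(it)) { prev_item <- NA_integer_; next }
      key <- as.character(it)
      if (is.null(first_on[[key]])) {
        f$visit_type[i] <- "discovery"; first_on[[key]] <- f$onset_ms[i]
      } else if (!is.na(prev_item) && prev_item == it) {
        f$visit_type[i] <- "revisit_short"
      } else if (f$onset_ms[i] >= first_on[[key]] + 1000) {
        f$visit_type[i] <- "revisit"
      } else {
        f$visit_type[i] <- "revisit_short"
      }
      prev_item <- it
    }
    f$discovery_order <- NA_integer_
    disc <- which(f$visit_type == "discovery" & f$is_target)
    if (length(disc)) f$discovery_order[disc] <- seq_along(disc)
    for (i in seq_len(nrow(f))) {
      at <- round(f$onset_ms[i]) + 2L - s0
      if (f$is_target[i] && f$visit_type[i] == "discovery" && rs$target_amp > 0) {
        contrib <- add_kernel(contrib, at, k_target, rs$target_amp / 100 * p0)
        injected <- rbind(injected,
                          note("discovery", tp$tid, f$onset_ms[i], rs$target_amp))
      } else if (f$is_target[i] && f$visit_type[i] == "revisit" &&
                 rs$revisit_amp > 0) {
        contrib <- add_kernel(contrib, at, k_revisit, rs$revisit_amp / 100 * p0)
        injected <- rbind(injected,
                          note("revisit_target", tp$tid, f$onset_ms[i],
                               rs$revisit_amp))
      } else if (f$item_class[i] == "distractor" &&
                 f$visit_type[i] == "revisit" && rs$distractor_revisit_amp > 0) {
        contrib <- add_kernel(contrib, at, k_drev,
                              rs$distractor_revisit_amp / 100 * p0)
        injected <- rbind(injected,
                          note("revisit_distractor", tp$tid, f$onset_ms[i],
                               rs$distractor_revisit_amp))
      }
    }
    if (tp$self_term && rs$press_amp > 0) {
      contrib <- add_kernel(contrib, round(tp$press - rs$press_lead_ms) + 2L - s0,
                            k_press, rs$press_amp / 100 * p0)
      injected <- rbind(injected, note("press", tp$tid, tp$press, rs$press_amp))
    }
    true_p[s0:s1] <- true_p[s0:s1] + contrib
    f$trial_id <- tp$tid
    f$duration_ms <- f$offset_ms - f$onset_ms
    fix_ledger <- rbind(fix_ledger, f)
  }

  rec <- true_p + config$pfe$b1 * gx + config$pfe$b2 * gy
  withblinks <- insert_blinks(rec, config)
  series <- sample_series(t, gx, gy, withblinks$pupil, 1000)

  trials <- data.frame(
    trial_id = vapply(trial_plan, `[[`, character(1), "tid"),
    n_targets = vapply(trial_plan, `[[`, numeric(1), "nt"),
    search_onset_ms = vapply(trial_plan, `[[`, numeric(1), "onset"),
    search_offset_ms = vapply(trial_plan, `[[`, numeric(1), "offset"),
    self_terminated = vapply(trial_plan, `[[`, logical(1), "self_term"),
    press_time_ms = vapply(trial_plan, function(x)
      if (is.na(x$press)) NA_real_ else x$press, numeric(1)),
    response = vapply(trial_plan, `[[`, numeric(1), "resp"),
    stringsAsFactors = FALSE)
  trials$correct <- trials$response == trials$n_targets
  trials$session_id <- session_id
  trials$subject_id <- subject_id
  trials <- trial_records(trials)

  bl <- withblinks$blinks
  fix_ev <- fix_ledger
  events <- event_table(
    kind = c(rep("fixation", nrow(fix_ev)), rep("blink", nrow(bl)),
             rep("button_press", sum(trials$self_terminated))),
    onset_ms = c(fix_ev$onset_ms, bl$onset_ms,
                 trials$press_time_ms[trials$self_terminated]),
    offset_ms = c(fix_ev$offset_ms, bl$offset_ms,
                  trials$press_time_ms[trials$self_terminated]),
    x_px = c(fix_ev$x_px, rep(NA, nrow(bl)),
             rep(NA, sum(trials$self_terminated))),
    y_px = c(fix_ev$y_px, rep(NA, nrow(bl)),
             rep(NA, sum(trials$self_terminated))))

  fix_ledger <- ledger_eligibility(fix_ledger, trials)
  truth <- list(pfe = config$pfe, blinks = bl, injected = injected,
                fixations = fix_ledger,
                subject_id = subject_id, session_id = session_id)
  if (keep_true) {
    truth$true_pupil <- true_p
    truth$recorded_pre_blink <- rec
  }
  class(layouts) <- c("fp_layout", "data.frame")
  list(series = series, events = events, trials = trials,
       layouts = layouts, truth = truth)
}

# Apply the epoch-selection rules to the generator's own fixation list,
# recording per-rule pass flags and the resulting per-contrast eligibility.
# The duration cap is pooled over the session (mean + 3 SD of target
# fixations).
ledger_eligibility <- function(f, trials, params = selection_params()) {
  m <- match(f$trial_id, trials$trial_id)
  tdur <- f$duration_ms[f$item_class == "target" &
                        f$duration_ms >= params$min_duration_ms]
  cap <- if (length(tdur) > 1L) mean(tdur) + params$duration_sd_cap * sd(tdur)
         else Inf
  f$pass_duration <- f$duration_ms >= params$min_duration_ms &
    f$duration_ms <= cap
  f$pass_onset_window <- f$onset_ms >=
    trials$search_onset_ms[m] + params$onset_exclusion_ms
  st <- as.logical(trials$self_terminated[m])
  f$pass_press_window <- !st |
    f$onset_ms <= trials$press_time_ms[m] - params$press_exclusion_ms
  f$correct_trial <- as.logical(trials$correct[m])
  f$n_targets <- trials$n_targets[m]
  base <- f$pass_duration & f$pass_onset_window & f$pass_press_window &
    f$correct_trial & f$visit_type %in% c("discovery", "revisit")
  f$eligible_target_all <- base & f$item_class == "target" & f$n_targets >= 1
  f$eligible_distractor_all <- base & f$item_class == "distractor" &
    f$n_targets == 0
  f
}

#' Simulate a multi-subject study
#'
#' Each subject contributes `sessions_per_subject` sessions (two by default,
#' mirroring per-session fitting of the foreshortening model); each session
#' draws its own PFE plane around the reference coefficients and contains one
#' ellipse-tracking recording and one search recording sharing that plane.
#'
#' @param n_subjects Number of subjects.
#' @param config [sim_config()].
#' @param seed Master seed; per-session seeds are derived from it.
#' @param sessions_per_subject Default 2.
#' @return A list of class `fp_study`: `sessions` (each with `subject_id`,
#'   `session_id`, `ellipse`, `search`), `config`, `seed`.
#' @export
simulate_study <- function(n_subjects, config = sim_config(), seed = 1,
                           sessions_per_subject = 2) {
  sessions <- list()
  k <- 0L
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("s%02d", s)
    for (ss in seq_len(sessions_per_subject)) {
      k <- k + 1L
      sess_seed <- (seed * 7919L + s * 131L + ss) %% 2147483647L
      set.seed(sess_seed)
      cfg <- config
      cfg$pfe$b1 <- max(-1.2, min(-0.1,
        rnorm(1, config$pfe$b1, 0.276)))
      cfg$pfe$b2 <- rnorm(1, config$pfe$b2, 0.257)
      sess_id <- letters[ss]
      ell <- simulate_ellipse_session(cfg, seed = sess_seed + 1L,
                                      session_id = paste0(sid, "_", sess_id))
      srch <- simulate_search_session(cfg, seed = sess_seed + 2L,
                                      subject_id = sid, session_id = sess_id)
      sessions[[k]] <- list(subject_id = sid, session_id = sess_id,
                            pfe_truth = cfg$pfe, ellipse = ell, search = srch)
    }
  }
  structure(list(sessions = sessions, config = config, seed = seed),
            class = "fp_study")
}

#' Summarise a session's ground truth
#'
#' Machine-readable counts of injected response events per kind and targets
#' level, for acceptance checks against the pipeline's selections.
#'
#' @param truth The `truth` element of [simulate_search_session()].
#' @return A data.frame with `kind`, `n_targets`, `n_events`,
#'   `mean_amplitude_pct`.
#' @export
ground_truth_report <- function(truth) {
  inj <- truth$injected
  if (is.null(inj) || nrow(inj) == 0L)
    return(data.frame(kind = character(0), n_targets = numeric(0),
                      n_events = integer(0), mean_amplitude_pct = numeric(0)))
  nt <- truth$fixations$n_targets[match(inj$trial_id,
                                        truth$fixations$trial_id)]
  key <- split(seq_len(nrow(inj)), paste(inj$kind, nt))
  out <- do.call(rbind, lapply(key, function(ix) data.frame(
    kind = inj$kind[ix[1]], n_targets = nt[ix[1]],
    n_events = length(ix), mean_amplitude_pct = mean(inj$amplitude_pct[ix]))))
  rownames(out) <- NULL
  out[order(out$kind, out$n_targets), , drop = FALSE]
}
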