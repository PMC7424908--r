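#' Saccade-detection thresholds
#'
#' Thresholds of the standard video-tracker parsing scheme: a sample belongs
#' to a saccade if it exceeds the motion (deg), velocity (deg/s) or
#' acceleration (deg/s^2) threshold; everything else (outside blinks) is
#' fixation.
#'
#' @param motion_deg Displacement threshold over the running detection window.
#' @param velocity_deg_s Velocity threshold.
#' @param accel_deg_s2 Acceleration threshold.
#' @return A list of class `fp_detection_params`.
#' @export
detection_params <- function(motion_deg = 0.1, velocity_deg_s = 30,
                             accel_deg_s2 = 8000) {
  stopifnot(motion_deg > 0, velocity_deg_s > 0, accel_deg_s2 > 0)
  structure(list(motion_deg = motion_deg, velocity_deg_s = velocity_deg_s,
                 accel_deg_s2 = accel_deg_s2),
            class = "fp_detection_params")
}

#' Fixation selection thresholds
#'
#' All the thresholds of the fixation selection pipeline, with the reference
#' defaults: brief fixations (< 100 ms) are merged into a neighbour within
#' 1 degree or discarded; fixations are assigned to items within 1.25 deg;
#' epochs require duration >= 120 ms and below mean + 3 SD of all target
#' fixations; fixations within 1000 ms of search onset or 3000 ms of a
#' terminating button press are discarded; a revisit must start at least
#' 1000 ms after the initial fixation on the item.
#'
#' @param merge_below_ms,merge_within_deg Brief-fixation merge rule.
#' @param min_duration_ms Minimum epoch-eligible duration.
#' @param duration_sd_cap SD multiplier for the long-duration cap.
#' @param ia_radius_deg Interest-area radius.
#' @param onset_exclusion_ms,press_exclusion_ms Boundary exclusion windows.
#' @param revisit_min_gap_ms Minimum onset-to-onset gap for a true revisit.
#' @return A list of class `fp_selection_params`.
#' @export
selection_params <- function(merge_below_ms = 100, merge_within_deg = 1.0,
                             min_duration_ms = 120, duration_sd_cap = 3,
                             ia_radius_deg = 1.25, onset_exclusion_ms = 1000,
                             press_exclusion_ms = 3000,
                             revisit_min_gap_ms = 1000) {
  structure(list(merge_below_ms = merge_below_ms,
                 merge_within_deg = merge_within_deg,
                 min_duration_ms = min_duration_ms,
                 duration_sd_cap = duration_sd_cap,
                 ia_radius_deg = ia_radius_deg,
                 onset_exclusion_ms = onset_exclusion_ms,
                 press_exclusion_ms = press_exclusion_ms,
                 revisit_min_gap_ms = revisit_min_gap_ms),
            class = "fp_selection_params")
}

#' Detect fixations and saccades from raw gaze samples
#'
#' Velocity and acceleration are computed from Savitzky-Golay smoothed
#' differentials (quadratic, 9-sample window) of the gaze trace; the motion
#' test flags samples whose gaze displacement across the same window exceeds
#' the motion threshold. Samples exceeding any threshold are saccade samples;
#' maximal runs of non-saccade, non-blink samples become fixations with
#' mean-gaze centres. This detector makes the pipeline self-contained;
#' precomputed fixation events from the tracker's own parser take precedence
#' when present.
#'
#' @param series Native-rate [sample_series()].
#' @param params [detection_params()].
#' @param geometry [geometry()].
#' @param blinks Optional data.frame of blink spans to exclude; defaults to
#'   the series' interpolation mask.
#' @return An [event_table()] of `fixation` and `saccade` events.
#' @export
detect_fixations <- function(series, params = detection_params(),
                             geometry, blinks = NULL) {
  n <- length(series$t_ms)
  rate <- series$rate_hz
  ppd <- geometry$px_per_deg
  win <- 9L
  if (n <= win) stop_fixpupil("series too short for fixation detection")
  vx <-signal::sgolayfilt(series$gx_px, p = 2, n = win, m = 1) * rate
  vy <- signal::sgolayfilt(series$gy_px, p = 2, n = win, m = 1) * rate
  ax <- signal::sgolayfilt(series$gx_px, p = 2, n = win, m = 2) * rate^2
  ay <- signal::sgolayfilt(series$gy_px, p = 2, n = win, m = 2) * rate^2
  vel <- sqrt(vx^2 + vy^2) / ppd
  acc <- sqrt(ax^2 + ay^2) / ppd
  h <- win %/% 2L
  i0 <- pmax(seq_len(n) - h, 1L); i1 <- pmin(seq_len(n) + h, n)
  disp <- sqrt((series$gx_px[i1] - series$gx_px[i0])^2 +
               (series$gy_px[i1] - series$gy_px[i0])^2) / ppd
  sac <- vel > params$velocity_deg_s | acc > params$accel_deg_s2 |
    disp > params$motion_deg

  in_blink <- series$interp
  if (!is.null(blinks) && nrow(blinks)) {
    for (i in seq_len(nrow(blinks)))
      in_blink[series$t_ms >= blinks$onset_ms[i] &
               series$t_ms <= blinks$offset_ms[i]] <- TRUE
  }
  fix_flag <- !sac & !in_blink
  runs <- logical_runs(fix_flag)
  # drop degenerate single-sample runs at blink/saccade borders
  runs <- runs[runs$end > runs$start, , drop = FALSE]
  if (nrow(runs) == 0L)
    warning("no fixation samples detected; all-saccade or all-blink series")
  sruns <- logical_runs(sac & !in_blink)
  mk <- function(r, kind) {
    if (nrow(r) == 0L)
      return(event_table())
    event_table(
      kind = rep(kind, nrow(r)),
      onset_ms = series$t_ms[r$start], offset_ms = series$t_ms[r$end],
      x_px = vapply(seq_len(nrow(r)), function(i)
        mean(series$gx_px[r$start[i]:r$end[i]]), numeric(1)),
      y_px = vapply(seq_len(nrow(r)), function(i)
        mean(series$gy_px[r$start[i]:r$end[i]]), numeric(1)))
  }
  out <- rbind(mk(runs, "fixation"), mk(sruns, "saccade"))
  out <- out[order(out$onset_ms), , drop = FALSE]
  class(out) <- c("fp_events", "data.frame")
  out
}

#' Build a per-trial fixation table from parsed events
#'
#' Keeps fixations whose onset falls inside a trial's search window and
#' attaches the trial id plus empty classification columns.
#'
#' @param events An [event_table()] containing `fixation` rows.
#' @param trials An [trial_records()] data.frame.
#' @return A data.frame of fixation records.
#' @export
fixation_table <- function(events, trials) {
  fx <- events_of(events, "fixation")
  out <- lapply(seq_len(nrow(trials)), function(i) {
    tr <- trials[i, ]
    sub <- fx[fx$onset_ms >= tr$search_onset_ms &
              fx$onset_ms <= tr$search_offset_ms, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    data.frame(trial_id = tr$trial_id, onset_ms = sub$onset_ms,
               offset_ms = sub$offset_ms,
               duration_ms = sub$offset_ms - sub$onset_ms,
               x_px = sub$x_px, y_px = sub$y_px)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(trial_id = character(0), onset_ms = numeric(0),
                      offset_ms = numeric(0), duration_ms = numeric(0),
                      x_px = numeric(0), y_px = numeric(0))
  out$item_id <- NA_integer_
  out$item_class <- "none"
  out$visit_type <- "unassigned"
  out$discovery_order <- NA_integer_
  out[order(out$trial_id, out$onset_ms), , drop = FALSE]
}

#' Merge or discard brief fixations
#'
#' Iteratively takes the earliest fixation shorter than `merge_below_ms`,
#' merges it into the spatially nearest adjacent neighbour if that neighbour's
#' centre lies within `merge_within_deg` (the neighbour's span becomes the
#' union, its duration the new span length, its centre the duration-weighted
#' mean), and discards it otherwise. Iterates until no brief fixations remain.
#'
#' @param fix A fixation table from [fixation_table()].
#' @param params [selection_params()].
#' @param geometry [geometry()].
#' @return The merged fixation table.
#' @export
merge_or_discard_brief <- function(fix, params = selection_params(), geometry) {
  ppd <- geometry$px_per_deg
  out <- NULL
  for (tid in unique(fix$trial_id)) {
    f <- fix[fix$trial_id == tid, , drop = FALSE]
    f <- f[order(f$onset_ms), , drop = FALSE]
    repeat {
      brief <- which(f$duration_ms < params$merge_below_ms)
      if (!length(brief)) break
      i <- brief[1]
      cand <- c(i - 1L, i + 1L)
      cand <- cand[cand >= 1L & cand <= nrow(f)]
      if (length(cand)) {
        d <- sqrt((f$x_px[cand] - f$x_px[i])^2 +
                  (f$y_px[cand] - f$y_px[i])^2) / ppd
        j <- cand[which.min(d)]
      } else {
        j <- integer(0)
      }
      if (length(j) && min(d) < params$merge_within_deg) {
        w <- c(f$duration_ms[j], f$duration_ms[i])
        f$x_px[j] <- sum(w * c(f$x_px[j], f$x_px[i])) / sum(w)
        f$y_px[j] <- sum(w * c(f$y_px[j], f$y_px[i])) / sum(w)
        f$onset_ms[j] <- min(f$onset_ms[c(i, j)])
        f$offset_ms[j] <- max(f$offset_ms[c(i, j)])
        f$duration_ms[j] <- f$offset_ms[j] - f$onset_ms[j]
      }
      f <- f[-i, , drop = FALSE]
    }
    out <- rbind(out, f)
  }
  if (is.null(out)) fix else out
}

#' Assign fixations to display items
#'
#' A fixation is assigned to the item whose centre is nearest, provided that
#' distance is below the interest-area radius; ties go to the lowest item id.
#' Fixations farther than the radius from every item get class `"none"`.
#'
#' @param fix Fixation table.
#' @param layouts [item_layouts()] covering the fixations' trials.
#' @param params [selection_params()].
#' @param geometry [geometry()].
#' @return The fixation table with `item_id` and `item_class` filled in.
#' @export
assign_interest_areas <- function(fix, layouts, params = selection_params(),
                                  geometry) {
  ppd <- geometry$px_per_deg
  by_trial <- split(layouts[c("item_id", "x_px", "y_px", "is_target")],
                    layouts$trial_id)
  for (i in seq_len(nrow(fix))) {
    ly <- by_trial[[as.character(fix$trial_id[i])]]
    if (is.null(ly) || !nrow(ly)) next
    d <- sqrt((ly$x_px - fix$x_px[i])^2 + (ly$y_px - fix$y_px[i])^2) / ppd
    best <- which(d <= min(d) + 1e-12)
    j <- best[which.min(ly$item_id[best])]
    if (d[j] < params$ia_radius_deg) {
      fix$item_id[i] <- ly$item_id[j]
      fix$item_class[i] <- if (as.logical(ly$is_target[j])) "target" else "distractor"
    } else {
      fix$item_id[i] <- NA_integer_
      fix$item_class[i] <- "none"
    }
  }
  fix
}

#' Apply the duration filters
#'
#' Drops fixations shorter than `min_duration_ms`, then computes the mean and
#' SD of target-fixation durations pooled over the whole dataset and drops any
#' fixation (target or distractor) longer than `mean + duration_sd_cap * SD`.
#' With no target fixations in the dataset the SD cap is skipped with a
#' warning.
#'
#' @param fix Fixation table with interest areas assigned.
#' @param params [selection_params()].
#' @return The filtered table.
#' @export
filter_durations <- function(fix, params = selection_params()) {
  fix <- fix[fix$duration_ms >= params$min_duration_ms, , drop = FALSE]
  tdur <- fix$duration_ms[fix$item_class == "target"]
  if (length(tdur) == 0L) {
    warning("no target fixations in dataset; duration SD cap skipped")
    return(fix)
  }
  s <- if (length(tdur) > 1L) sd(tdur) else 0
  cap <- mean(tdur) + params$duration_sd_cap * s
  fix[fix$duration_ms <= cap, , drop = FALSE]
}

#' Exclude fixations near search onset and button press
#'
#' Drops fixations whose onset falls within `onset_exclusion_ms` of search
#' onset and, in self-terminated trials, within `press_exclusion_ms` before
#' the terminating press, so display changes and the motor act cannot
#' contaminate the epochs.
#'
#' @param fix Fixation table.
#' @param trials [trial_records()].
#' @param params [selection_params()].
#' @return The filtered table.
#' @export
exclude_boundary_fixations <- function(fix, trials,
                                       params = selection_params()) {
  m <- match(fix$trial_id, trials$trial_id)
  keep <- fix$onset_ms >= trials$search_onset_ms[m] + params$onset_exclusion_ms
  st <- as.logical(trials$self_terminated[m])
  press <- trials$press_time_ms[m]
  keep <- keep & !(st & fix$onset_ms > press - params$press_exclusion_ms)
  fix[keep & !is.na(keep), , drop = FALSE]
}

#' Classify visits and number target discoveries
#'
#' The first fixation on an item within a trial is its `discovery`. A later
#' fixation on the same item counts as a `revisit` only if at least one
#' intervening fixation landed on a different item (or none) - i.e. gaze left
#' the item - and its onset is at least `revisit_min_gap_ms` after the
#' discovery onset; otherwise it is `revisit_short` (excluded from every
#' selection). Target discoveries are numbered 1..3 within trial by onset.
#'
#' @param fix Fixation table with interest areas assigned, time-ordered.
#' @param params [selection_params()].
#' @return The table with `visit_type` and `discovery_order` filled in.
#' @export
classify_visits <- function(fix, params = selection_params()) {
  out <- NULL
  for (tid in unique(fix$trial_id)) {
    f <- fix[fix$trial_id == tid, , drop = FALSE]
    f <- f[order(f$onset_ms), , drop = FALSE]
    first_onset <- list()
    last_idx <- list()     # row index of previous fixation on the item
    prev_item <- NA_integer_
    for (i in seq_len(nrow(f))) {
      it <- f$item_id[i]
      if (is.na(it)) {
        f$visit_type[i] <- "unassigned"
        prev_item <- NA_integer_
        next
      }
      key <- as.character(it)
      if (is.null(first_onset[[key]])) {
        f$visit_type[i] <- "discovery"
        first_onset[[key]] <- f$onset_ms[i]
      } else if (!is.na(prev_item) && prev_item == it) {
        f$visit_type[i] <- "revisit_short"   # never left the item
      } else if (f$onset_ms[i] >= first_onset[[key]] + params$revisit_min_gap_ms) {
        f$visit_type[i] <- "revisit"
      } else {
        f$visit_type[i] <- "revisit_short"
      }
      prev_item <- it
    }
    disc <- which(f$visit_type == "discovery" & f$item_class == "target")
    if (length(disc))
      f$discovery_order[disc[order(f$onset_ms[disc])]] <- seq_along(disc)
    out <- rbind(out, f)
  }
  if (is.null(out)) fix else out
}

EPOCH_CONTRASTS <- c("target_all", "distractor_all",
                     "target_discovery", "target_revisit",
                     "distractor_discovery", "distractor_revisit",
                     "discovery_1", "discovery_2")

#' Select epoch-eligible fixation events for a named contrast
#'
#' Implements the named selections of the analysis: `target_all` (discoveries
#' and revisits on targets in 1-3-target trials), `distractor_all`
#' (discoveries and revisits on distractors in 0-target trials), the
#' `{target,distractor}_{discovery,revisit}` splits, and `discovery_1` /
#' `discovery_2` (first and second target discoveries in multi-target
#' trials). Every selection is restricted to trials answered correctly, and
#' `revisit_short` fixations never qualify.
#'
#' @param fix Classified fixation table.
#' @param trials [trial_records()].
#' @param contrast One of the names above.
#' @return The selected fixation rows with alignment time `t_align_ms` and
#'   trial metadata columns attached.
#' @export
select_epoch_events <- function(fix, trials, contrast) {
  if (!contrast %in% EPOCH_CONTRASTS)
    stop_fixpupil(sprintf("unknown contrast '%s'; valid: %s", contrast,
                          paste(EPOCH_CONTRASTS, collapse = ", ")))
  m <- match(fix$trial_id, trials$trial_id)
  fx <- cbind(fix,
              n_targets = trials$n_targets[m],
              correct = as.logical(trials$correct[m]),
              subject_id = trials$subject_id[m],
              session_id = trials$session_id[m])
  fx <- fx[fx$correct & !is.na(fx$correct), , drop = FALSE]
  real_visit <- fx$visit_type %in% c("discovery", "revisit")
  sel <- switch(contrast,
    target_all = fx$item_class == "target" & real_visit & fx$n_targets >= 1,
    distractor_all = fx$item_class == "distractor" & real_visit &
      fx$n_targets == 0,
    target_discovery = fx$item_class == "target" &
      fx$visit_type == "discovery" & fx$n_targets >= 1,
    target_revisit = fx$item_class == "target" &
      fx$visit_type == "revisit" & fx$n_targets >= 1,
    distractor_discovery = fx$item_class == "distractor" &
      fx$visit_type == "discovery" & fx$n_targets == 0,
    distractor_revisit = fx$item_class == "distractor" &
      fx$visit_type == "revisit" & fx$n_targets == 0,
    discovery_1 = fx$item_class == "target" & fx$visit_type == "discovery" &
      !is.na(fx$discovery_order) & fx$discovery_order == 1 & fx$n_targets >= 2,
    discovery_2 = fx$item_class == "target" & fx$visit_type == "discovery" &
      !is.na(fx$discovery_order) & fx$discovery_order == 2 & fx$n_targets >= 2)
  out <- fx[sel, , drop = FALSE]
  out$t_align_ms <- out$onset_ms
  out$contrast <- rep(contrast, nrow(out))
  rownames(out) <- NULL
  out
}

#' Full fixation selection pipeline
#'
#' merge -> assign interest areas -> classify visits -> duration filter ->
#' boundary exclusion, in that order. Visits are classified on the full
#' merged sequence, before any eligibility filtering, so that a refixation
#' keeps its `revisit` status even when the initial fixation on the item is
#' itself ineligible (too early, too short, or too close to the press).
#' Deterministic: rerunning yields the same table.
#'
#' @param events An [event_table()] with fixation rows (e.g. the tracker's or
#'   [detect_fixations()]' output).
#' @param trials [trial_records()].
#' @param layouts [item_layouts()].
#' @param params [selection_params()].
#' @param geometry [geometry()].
#' @return A classified, filtered fixation table.
#' @export
fixation_pipeline <- function(events, trials, layouts,
                              params = selection_params(), geometry) {
  fix <- fixation_table(events, trials)
  fix <- merge_or_discard_brief(fix, params, geometry)
  fix <- assign_interest_areas(fix, layouts, params, geometry)
  fix <- classify_visits(fix, params)
  fix <- filter_durations(fix, params)
  exclude_boundary_fixations(fix, trials, params)
}
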