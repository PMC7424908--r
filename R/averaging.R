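#' Epoch window parameters
#'
#' Fixation-aligned epochs span `window_ms` around the alignment event and are
#' expressed as %-change from the mean pupil size over `baseline_ms` (a window
#' ending at the event). Both bounds must be multiples of the sample period.
#'
#' @param window_ms Length-2 vector, default `c(-500, 2000)`.
#' @param baseline_ms Length-2 vector, default `c(-500, 0)`; the baseline is
#'   the half-open interval `[baseline_ms[1], baseline_ms[2])`.
#' @return A list of class `fp_epoch_params`.
#' @export
epoch_params <- function(window_ms = c(-500, 2000), baseline_ms = c(-500, 0)) {
  stopifnot(length(window_ms) == 2L, length(baseline_ms) == 2L,
            window_ms[1] < window_ms[2], baseline_ms[1] < baseline_ms[2],
            baseline_ms[1] >= window_ms[1], baseline_ms[2] <= window_ms[2])
  structure(list(window_ms = window_ms, baseline_ms = baseline_ms),
            class = "fp_epoch_params")
}

epoch_grid <- function(params, rate_hz) {
  period <- 1000 / rate_hz
  seq(params$window_ms[1], params$window_ms[2], by = period)
}

#' Extract one baseline-normalised epoch
#'
#' Aligns the window to the sample nearest `t0_ms` and expresses pupil size as
#' `100 * (p - B) / B`, with `B` the mean pupil over the baseline window. The
#' epoch is rejected (with a stated reason) if the window does not fit inside
#' the recording or the baseline mean is not positive.
#'
#' @param series Preprocessed [sample_series()] (50 Hz, blinks repaired,
#'   optionally PFE-corrected).
#' @param t0_ms Alignment time in ms.
#' @param params [epoch_params()].
#' @return A list with `rel_time_ms`, `values` (%-change), `baseline_mean`,
#'   `interp_fraction`; or, when the epoch is rejected, an
#'   `fp_epoch_rejected` object with `values = NULL` and a `reason`.
#' @export
extract_epoch <- function(series, t0_ms, params = epoch_params()) {
  period <- 1000 / series$rate_hz
  i0 <- series_index_at(series, t0_ms)
  rel <- epoch_grid(params, series$rate_hz)
  idx <- i0 + as.integer(round(rel / period))
  reject <- function(why) structure(list(values = NULL, reason = why),
                                    class = "fp_epoch_rejected")
  if (is.na(i0) || idx[1] < 1L || idx[length(idx)] > length(series$t_ms))
    return(reject("window outside recording"))
  bsel <- rel >= params$baseline_ms[1] & rel < params$baseline_ms[2]
  B <- mean(series$pupil[idx[bsel]])
  if (!is.finite(B) || B <= 0)
    return(reject("non-positive baseline"))
  list(rel_time_ms = rel,
       values = 100 * (series$pupil[idx] - B) / B,
       baseline_mean = B,
       interp_fraction = mean(series$interp[idx]))
}

#' Extract a set of epochs for selected events
#'
#' @param series Preprocessed [sample_series()].
#' @param events Data.frame of selected fixation events (from
#'   [select_epoch_events()]) with `t_align_ms` and metadata columns.
#' @param params [epoch_params()].
#' @return A list of class `fp_epochs`: `values` (epochs x time matrix),
#'   `rel_time_ms`, `meta` (metadata rows of accepted epochs), `rejected`
#'   (rows and reasons of rejected epochs).
#' @export
extract_epochs <- function(series, events, params = epoch_params()) {
  rel <- epoch_grid(params, series$rate_hz)
  vals <- matrix(NA_real_, nrow = nrow(events), ncol = length(rel))
  ok <- logical(nrow(events))
  reason <- character(nrow(events))
  base <- numeric(nrow(events))
  for (i in seq_len(nrow(events))) {
    ep <- extract_epoch(series, events$t_align_ms[i], params)
    if (is.null(ep$values)) {
      reason[i] <- ep$reason %||% "rejected"
    } else {
      vals[i, ] <- ep$values
      base[i] <- ep$baseline_mean
      ok[i] <- TRUE
    }
  }
  structure(list(values = vals[ok, , drop = FALSE], rel_time_ms = rel,
                 meta = cbind(events[ok, , drop = FALSE],
                              baseline_mean = base[ok]),
                 rejected = cbind(events[!ok, , drop = FALSE],
                                  reason = reason[!ok])),
            class = "fp_epochs")
}

#' @export
print.fp_epochs <- function(x, ...) {
  cat(sprintf("<fp_epochs> %d epochs x %d samples (%g..%g ms), %d rejected\n",
              nrow(x$values), length(x$rel_time_ms), min(x$rel_time_ms),
              max(x$rel_time_ms), nrow(x$rejected)))
  invisible(x)
}

#' Grand-average a set of traces
#'
#' With `unit = "subject"` the epochs are first averaged within subject and
#' the grand mean taken across subjects (the group-level replication used for
#' all between-participant figures); with `unit = "epoch"` all epochs are
#' pooled. The per-unit traces are returned so a bootstrap SEM can be
#' computed on the same units.
#'
#' @param epochs An `fp_epochs` object, or a plain matrix (units x time).
#' @param unit `"subject"` or `"epoch"`.
#' @param subject Subject ids per epoch row (taken from `meta$subject_id` for
#'   `fp_epochs` input).
#' @return A list of class `fp_average`: `grid`, `mean`, `n_units`, `unit`,
#'   `per_unit` (units x time matrix).
#' @export
grand_average <- function(epochs, unit = c("subject", "epoch"),
                          subject = NULL) {
  unit <- match.arg(unit)
  if (inherits(epochs, "fp_epochs")) {
    mat <- epochs$values
    grid <- epochs$rel_time_ms
    subject <- subject %||% epochs$meta$subject_id
  } else {
    mat <- as.matrix(epochs)
    grid <- seq_len(ncol(mat))
  }
  if (nrow(mat) == 0L) stop_fixpupil("no epochs to average")
  if (unit == "subject") {
    if (is.null(subject)) stop_fixpupil("subject ids required for unit='subject'")
    per_unit <- do.call(rbind, lapply(split(seq_len(nrow(mat)), subject),
                                      function(ix) colMeans(mat[ix, , drop = FALSE])))
  } else {
    per_unit <- mat
  }
  structure(list(grid = grid, mean = colMeans(per_unit),
                 n_units = nrow(per_unit), unit = unit, per_unit = per_unit),
            class = "fp_average")
}

#' Bootstrap standard error of a mean trace
#'
#' Per time point, the SD of the means of `n_boot` resamples (with
#' replacement) of the units (subjects or epochs). Seeded and reproducible.
#'
#' @param per_unit Units x time matrix (e.g. `fp_average$per_unit`).
#' @param n_boot Number of bootstrap iterations (default 5000).
#' @param seed RNG seed.
#' @return Numeric SEM trace.
#' @export
bootstrap_sem <- function(per_unit, n_boot = 5000, seed = 1) {
  per_unit <- as.matrix(per_unit)
  n <- nrow(per_unit)
  if (n < 2L) stop_fixpupil("need at least 2 units for a bootstrap SEM")
  set.seed(seed)
  draws <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
  boots <- matrix(NA_real_, n_boot, ncol(per_unit))
  for (b in seq_len(n_boot))
    boots[b, ] <- colMeans(per_unit[draws[b, ], , drop = FALSE])
  apply(boots, 2, sd)
}

#' Whole-trial pupil traces in %-change
#'
#' Returns onset-locked, search-phase and offset-locked segments of one
#' trial, all normalised by a single baseline: the mean pupil over the
#' 1000 ms before search onset. A trial whose baseline window is more than
#' half interpolated is flagged.
#'
#' @param series Preprocessed [sample_series()].
#' @param trial One row of [trial_records()].
#' @param pre_ms,post_ms Extent of the onset/offset-locked windows (default
#'   3000 ms each side).
#' @param baseline_ms Baseline length before onset (default 1000).
#' @return A list with `onset_locked`, `search_phase`, `offset_locked` (each
#'   `list(rel_time_ms, values)`), `baseline_mean` and `flagged`.
#' @export
whole_trial_traces <- function(series, trial, pre_ms = 3000, post_ms = 3000,
                               baseline_ms = 1000) {
  period <- 1000 / series$rate_hz
  seg <- function(t_from, t_to, anchor) {
    i0 <- series_index_at(series, t_from)
    i1 <- series_index_at(series, t_to)
    if (is.na(i0) || is.na(i1)) return(NULL)
    idx <- i0:i1
    list(rel_time_ms = series$t_ms[idx] - anchor, idx = idx)
  }
  on <- trial$search_onset_ms
  off <- trial$search_offset_ms
  bidx <- which(series$t_ms >= on - baseline_ms & series$t_ms < on)
  if (!length(bidx)) stop_fixpupil("baseline window outside recording")
  B <- mean(series$pupil[bidx])
  if (!is.finite(B) || B <= 0) stop_fixpupil("non-positive whole-trial baseline")
  flagged <- mean(series$interp[bidx]) > 0.5
  pc <- function(s) {
    if (is.null(s)) return(NULL)
    list(rel_time_ms = s$rel_time_ms,
         values = 100 * (series$pupil[s$idx] - B) / B)
  }
  list(onset_locked = pc(seg(on - pre_ms, on + post_ms, on)),
       search_phase = pc(seg(on, off, on)),
       offset_locked = pc(seg(off - pre_ms, off + post_ms, off)),
       baseline_mean = B, flagged = flagged)
}

#' Resample a search-phase trace onto a normalised-phase grid
#'
#' Linear interpolation onto `n_points` equally spaced points of normalised
#' phase `[0, 1]`, so searches of different length can be averaged at
#' equivalent stages of processing. Endpoints are preserved exactly.
#'
#' @param values Numeric trace (>= 2 samples).
#' @param n_points Grid size (default 101).
#' @return A list with `phase` and `values`.
#' @export
time_normalize <- function(values, n_points = 101) {
  n <- length(values)
  if (n < 2L) stop_fixpupil("cannot time-normalise a single-sample trace")
  phase <- seq(0, 1, length.out = n_points)
  list(phase = phase,
       values = approx(seq(0, 1, length.out = n), values, xout = phase)$y)
}

#' Condition averages of whole-trial traces
#'
#' Groups trials by `n_targets` or by self-termination, averages within
#' subject first and then across subjects, and returns bootstrap SEMs over
#' subjects. Also returns each subject's mean search-phase modulation (the
#' scalar summary per group). Subjects with an empty cell are dropped from
#' that grouping (recorded in `dropped_subjects`).
#'
#' @param series Preprocessed [sample_series()] covering the trials.
#' @param trials [trial_records()].
#' @param group_by `"n_targets"` or `"self_terminated"`.
#' @param pre_ms,post_ms,baseline_ms Passed to [whole_trial_traces()].
#' @param n_points Normalised-phase grid size.
#' @param n_boot,seed Bootstrap SEM settings.
#' @param correct_only Keep only correct trials (default TRUE).
#' @return A list of class `fp_condition_averages`: per group, `fp_average`
#'   objects (+`sem`) for the three segments and the per-subject scalar
#'   modulation table.
#' @export
condition_averages <- function(series, trials,
                               group_by = c("n_targets", "self_terminated"),
                               pre_ms = 3000, post_ms = 3000,
                               baseline_ms = 1000, n_points = 101,
                               n_boot = 1000, seed = 1, correct_only = TRUE) {
  group_by <- match.arg(group_by)
  if (correct_only) trials <- trials[as.logical(trials$correct), , drop = FALSE]
  if (!nrow(trials)) stop_fixpupil("no trials to average")
  grp <- if (group_by == "n_targets") trials$n_targets
         else as.logical(trials$self_terminated)

  onset_grid <- seq(-pre_ms, post_ms, by = 1000 / series$rate_hz)
  per_trial <- lapply(seq_len(nrow(trials)), function(i) {
    wt <- whole_trial_traces(series, trials[i, ], pre_ms, post_ms, baseline_ms)
    list(onset = wt$onset_locked$values, offset = wt$offset_locked$values,
         phase = time_normalize(wt$search_phase$values, n_points)$values,
         flagged = wt$flagged)
  })
  keep <- !vapply(per_trial, `[[`, logical(1), "flagged")
  groups <- sort(unique(grp))
  out <- list()
  modulation <- NULL
  subj_all <- unique(trials$subject_id)
  for (g in groups) {
    sel <- which(grp == g & keep)
    bysub <- split(sel, trials$subject_id[sel])
    bysub <- bysub[vapply(bysub, length, integer(1)) > 0]
    segavg <- function(field) {
      per_sub <- do.call(rbind, lapply(bysub, function(ix)
        colMeans(do.call(rbind, lapply(per_trial[ix], `[[`, field)))))
      av <- grand_average(per_sub, unit = "epoch")
      av$unit <- "subject"
      av$sem <- if (nrow(per_sub) > 1L)
        bootstrap_sem(per_sub, n_boot = n_boot, seed = seed) else
        rep(0, ncol(per_sub))
      av
    }
    onset <- segavg("onset"); onset$grid <- onset_grid
    offset <- segavg("offset"); offset$grid <- onset_grid
    phase <- segavg("phase"); phase$grid <- seq(0, 1, length.out = n_points)
    out[[as.character(g)]] <- list(onset_locked = onset,
                                   offset_locked = offset,
                                   search_phase = phase)
    modulation <- rbind(modulation, data.frame(
      group = g, subject_id = names(bysub),
      mean_modulation = rowMeans(phase$per_unit),
      n_trials = vapply(bysub, length, integer(1))))
  }
  dropped <- setdiff(subj_all,
                     Reduce(intersect, split(modulation$subject_id,
                                             modulation$group)))
  structure(list(groups = out, group_by = group_by, modulation = modulation,
                 dropped_subjects = dropped),
            class = "fp_condition_averages")
}
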