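#' Uniformly sampled eye-tracker trace
#'
#' Holds one continuous recording: timestamps (ms from session start), gaze
#' coordinates (px, origin top-left, x rightward, y downward), pupil size
#' (arbitrary recorded units, e.g. EyeLink area units) and a per-sample
#' interpolation mask that is `TRUE` wherever the pupil value was
#' reconstructed rather than measured.
#'
#' @param t_ms Strictly increasing, uniformly spaced timestamps in ms.
#' @param gx_px,gy_px Gaze coordinates in px.
#' @param pupil Pupil size in recorded units; must be non-negative where not
#'   masked. `NA` is allowed only where `interp` is `TRUE` (pending repair) or
#'   inside known blink spans prior to repair.
#' @param rate_hz Sampling rate in Hz; spacing must equal `1000/rate_hz`.
#' @param interp Logical mask, `TRUE` = reconstructed sample.
#' @return An object of class `fp_series`.
#' @export
sample_series <- function(t_ms, gx_px, gy_px, pupil, rate_hz,
                          interp = logical(length(t_ms))) {
  n <- length(t_ms)
  if (n < 2L) stop_fixpupil("a sample series needs at least 2 samples")
  if (length(gx_px) != n || length(gy_px) != n || length(pupil) != n ||
      length(interp) != n)
    stop_fixpupil("all sample columns must have equal length")
  dt <- diff(t_ms)
  if (any(dt <= 0))
    stop_fixpupil(sprintf("timestamps not strictly increasing at row %d",
                          which(dt <= 0)[1] + 1L))
  period <- 1000 / rate_hz
  if (any(abs(dt - period) > 1e-6 * period + 1e-9))
    stop_fixpupil(sprintf("timestamp spacing does not match rate %g Hz at row %d",
                          rate_hz, which(abs(dt - period) > 1e-6 * period)[1] + 1L))
  bad <- !interp & !is.na(pupil) & pupil < 0
  if (any(bad))
    stop_fixpupil(sprintf("negative pupil outside mask at row %d", which(bad)[1]))
  structure(
    list(t_ms = as.numeric(t_ms), gx_px = as.numeric(gx_px),
         gy_px = as.numeric(gy_px), pupil = as.numeric(pupil),
         rate_hz = rate_hz, interp = as.logical(interp)),
    class = "fp_series"
  )
}

#' @export
print.fp_series <- function(x, ...) {
  cat(sprintf(
    "<fp_series> %d samples @ %g Hz (%.1f s), %.2f%% interpolated\n",
    length(x$t_ms), x$rate_hz, diff(range(x$t_ms)) / 1000,
    100 * mean(x$interp)))
  invisible(x)
}

#' @export
length.fp_series <- function(x) length(x$t_ms)

series_index_at <- function(series, t_ms) {
  # nearest-sample index; t relative to the series' own clock
  period <- 1000 / series$rate_hz
  i <- round((t_ms - series$t_ms[1]) / period) + 1
  i[i < 1 | i > length(series$t_ms)] <- NA_integer_
  as.integer(i)
}

# first index with t >= t_ms (NA if past the end); timestamps are uniform so
# this is O(1) arithmetic, not a scan
series_index_ge <- function(series, t_ms) {
  period <- 1000 / series$rate_hz
  i <- as.integer(ceiling((t_ms - series$t_ms[1]) / period - 1e-9)) + 1L
  if (i < 1L) i <- 1L
  if (i > length(series$t_ms)) return(NA_integer_)
  i
}

# last index with t <= t_ms (NA if before the start)
series_index_le <- function(series, t_ms) {
  period <- 1000 / series$rate_hz
  i <- as.integer(floor((t_ms - series$t_ms[1]) / period + 1e-9)) + 1L
  if (i > length(series$t_ms)) i <- length(series$t_ms)
  if (i < 1L) return(NA_integer_)
  i
}

EVENT_KINDS <- c("blink", "fixation", "saccade", "message", "button_press")

#' Eye-tracker event table
#'
#' Parsed events in the style of a video eye tracker's event stream: blinks,
#' fixations, saccades, messages (onset only) and button presses. Events of a
#' single kind must not overlap in time.
#'
#' @param kind Character vector, each in
#'   `c("blink", "fixation", "saccade", "message", "button_press")`.
#' @param onset_ms,offset_ms Event span in ms (messages and button presses may
#'   have `offset_ms = onset_ms`).
#' @param x_px,y_px Event position payload (fixations: mean gaze), `NA` otherwise.
#' @param payload Free-text payload (messages), `NA` otherwise.
#' @return A `data.frame` of class `fp_events`.
#' @export
event_table <- function(kind = character(), onset_ms = numeric(),
                        offset_ms = onset_ms,
                        x_px = rep(NA_real_, length(kind)),
                        y_px = rep(NA_real_, length(kind)),
                        payload = rep(NA_character_, length(kind))) {
  ev <- data.frame(kind = as.character(kind), onset_ms = as.numeric(onset_ms),
                   offset_ms = as.numeric(offset_ms), x_px = as.numeric(x_px),
                   y_px = as.numeric(y_px), payload = as.character(payload),
                   stringsAsFactors = FALSE)
  validate_events(ev)
  class(ev) <- c("fp_events", "data.frame")
  ev
}

validate_events <- function(ev, file = NULL) {
  where <- if (is.null(file)) "" else paste0(" in ", file)
  bad <- !ev$kind %in% EVENT_KINDS
  if (any(bad))
    stop_fixpupil(sprintf("unknown event kind '%s'%s at row %d",
                          ev$kind[bad][1], where, which(bad)[1]))
  bad <- ev$offset_ms < ev$onset_ms
  if (any(bad))
    stop_fixpupil(sprintf("event offset before onset%s at row %d",
                          where, which(bad)[1]))
  for (k in unique(ev$kind)) {
    if (k %in% c("message", "button_press")) next
    sub <- ev[ev$kind == k, , drop = FALSE]
    o <- order(sub$onset_ms)
    son <- sub$onset_ms[o]; soff <- sub$offset_ms[o]
    if (length(son) > 1L) {
      ovl <- which(son[-1] < soff[-length(soff)])
      if (length(ovl))
        stop_fixpupil(sprintf("overlapping %s events%s (rows %d, %d)",
                              k, where,
                              which(ev$kind == k)[o][ovl[1]],
                              which(ev$kind == k)[o][ovl[1] + 1L]))
    }
  }
  invisible(ev)
}

events_of <- function(ev, kind) {
  out <- ev[ev$kind == kind, , drop = FALSE]
  out[order(out$onset_ms), , drop = FALSE]
}

#' Per-trial behavioural records
#'
#' One row per search trial. `search_offset_ms - search_onset_ms` can be at
#' most 10000 ms (the display limit); self-terminated trials must carry a
#' press time no later than search offset, and `correct` must equal
#' `response == n_targets`.
#'
#' @param df A data.frame with columns `trial_id`, `n_targets` (0-3),
#'   `search_onset_ms`, `search_offset_ms`, `self_terminated`, `press_time_ms`
#'   (`NA` unless self-terminated), `response`, `correct`, `session_id`,
#'   `subject_id`.
#' @return The validated data.frame with class `fp_trials`.
#' @export
trial_records <- function(df) {
  validate_trials(df)
  class(df) <- c("fp_trials", "data.frame")
  df
}

validate_trials <- function(df, file = NULL) {
  where <- if (is.null(file)) "" else paste0(" in ", file)
  need <- c("trial_id", "n_targets", "search_onset_ms", "search_offset_ms",
            "self_terminated", "press_time_ms", "response", "correct",
            "session_id", "subject_id")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_fixpupil(sprintf("trial table%s missing column(s): %s", where,
                          paste(miss, collapse = ", ")))
  bad <- !df$n_targets %in% 0:3
  if (any(bad))
    stop_fixpupil(sprintf("n_targets outside 0..3%s at row %d", where, which(bad)[1]))
  dur <- df$search_offset_ms - df$search_onset_ms
  bad <- dur < 0 | dur > 10000 + 1e-6
  if (any(bad))
    stop_fixpupil(sprintf("search duration outside [0, 10000] ms%s at row %d",
                          where, which(bad)[1]))
  st <- as.logical(df$self_terminated)
  bad <- st & (is.na(df$press_time_ms) | df$press_time_ms > df$search_offset_ms + 1e-6)
  if (any(bad))
    stop_fixpupil(sprintf(
      "self-terminated trial without valid press time%s at row %d",
      where, which(bad)[1]))
  bad <- as.logical(df$correct) != (df$response == df$n_targets)
  if (any(bad))
    stop_fixpupil(sprintf("`correct` inconsistent with response%s at row %d",
                          where, which(bad)[1]))
  if (anyDuplicated(df$trial_id))
    stop_fixpupil(sprintf("duplicated trial_id%s", where))
  invisible(df)
}

#' Search-array item layouts
#'
#' Thirty display items per trial with pixel coordinates and a target flag.
#' The number of targets in a trial's layout must equal the trial's
#' `n_targets`, which is checked when the layout is paired with trial records
#' in [read_recording()].
#'
#' @param df A data.frame with columns `trial_id`, `item_id`, `x_px`, `y_px`,
#'   `is_target`.
#' @param set_size Required number of items per trial (default 30).
#' @return The validated data.frame with class `fp_layout`.
#' @export
item_layouts <- function(df, set_size = 30L) {
  validate_layouts(df, set_size = set_size)
  class(df) <- c("fp_layout", "data.frame")
  df
}

validate_layouts <- function(df, file = NULL, set_size = 30L, trials = NULL) {
  where <- if (is.null(file)) "" else paste0(" in ", file)
  need <- c("trial_id", "item_id", "x_px", "y_px", "is_target")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_fixpupil(sprintf("layout table%s missing column(s): %s", where,
                          paste(miss, collapse = ", ")))
  cnt <- table(df$trial_id)
  bad <- cnt != set_size
  if (any(bad))
    stop_fixpupil(sprintf("trial %s has %d layout items%s (expected %d)",
                          names(cnt)[bad][1], cnt[bad][1], where, set_size))
  if (!is.null(trials)) {
    ntg <- tapply(as.logical(df$is_target), df$trial_id, sum)
    m <- match(trials$trial_id, names(ntg))
    bad <- which(!is.na(m) & ntg[m] != trials$n_targets)
    if (length(bad))
      stop_fixpupil(sprintf(
        "layout target count disagrees with n_targets for trial %s%s",
        trials$trial_id[bad[1]], where))
  }
  invisible(df)
}
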