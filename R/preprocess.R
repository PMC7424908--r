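#' Blink-repair parameters
#'
#' Controls the derivative-based extension of parsed blink endpoints and the
#' linear reconstruction of the masked span. After a parsed blink ends, the
#' recovery artifact often persists; the endpoint is pushed to the first
#' sample at which the windowed mean of the absolute z-scored pupil derivative
#' falls below `z_fraction` of its whole-recording mean, up to `max_extend_ms`
#' past the parsed offset.
#'
#' @param window_ms Moving-window length in ms (default 100).
#' @param z_fraction Fraction of the recording-mean derivative activity below
#'   which the signal counts as recovered (default 0.10).
#' @param max_extend_ms Cap on the extension past the parsed offset
#'   (default 1000).
#' @param window_align Window alignment for the moving mean. `"forward"`
#'   (default) asks that the `window_ms` of signal *from* a candidate sample
#'   onward is quiet, which locates the artifact end without the systematic
#'   lag a trailing window would add; `"trailing"` and `"centered"` are
#'   available for comparison.
#' @return A list of class `fp_blink_params`.
#' @export
blink_params <- function(window_ms = 100, z_fraction = 0.10,
                         max_extend_ms = 1000,
                         window_align = c("forward", "trailing", "centered")) {
  window_align <- match.arg(window_align)
  stopifnot(window_ms > 0, max_extend_ms > 0,
            z_fraction > 0, z_fraction < 1)
  structure(list(window_ms = window_ms, z_fraction = z_fraction,
                 max_extend_ms = max_extend_ms, window_align = window_align),
            class = "fp_blink_params")
}

#' Low-pass filter parameters
#'
#' @param target_rate_hz Rate the trace is downsampled to before smoothing
#'   (default 50 Hz).
#' @param butter_order Butterworth order (default 3).
#' @param cutoff_hz Low-pass cutoff in Hz (default 4); must be below the
#'   Nyquist frequency of the target rate.
#' @return A list of class `fp_filter_params`.
#' @export
filter_params <- function(target_rate_hz = 50, butter_order = 3, cutoff_hz = 4) {
  stopifnot(target_rate_hz > 0, butter_order >= 1,
            cutoff_hz > 0, cutoff_hz < target_rate_hz / 2)
  structure(list(target_rate_hz = target_rate_hz, butter_order = butter_order,
                 cutoff_hz = cutoff_hz), class = "fp_filter_params")
}

# Derivative-activity profile used by the endpoint-extension rule.
# Returns list(q = windowed mean |z| per sample, threshold).
# z-scoring statistics and the recording mean exclude samples inside the
# parsed blink spans, whose pupil values are tracker garbage.
blink_activity <- function(series, blinks, params) {
  n <- length(series$t_ms)
  d <- c(0, diff(series$pupil))
  in_blink <- rep(FALSE, n)
  if (nrow(blinks)) {
    for (i in seq_len(nrow(blinks))) {
      i0 <- series_index_ge(series, blinks$onset_ms[i])
      i1 <- series_index_le(series, blinks$offset_ms[i])
      if (!is.na(i0) && !is.na(i1) && i0 <= i1) in_blink[i0:i1] <- TRUE
    }
  }
  # a first difference that touches a blink sample is not signal: drop it
  # from the statistics and from the activity profile
  contaminated <- in_blink | c(FALSE, in_blink[-n])
  ok <- !contaminated & !is.na(d)
  m <- mean(d[ok]); s <- sd(d[ok])
  if (!is.finite(s) || s == 0) s <- 1
  a <- abs((d - m) / s)
  a[is.na(a) | contaminated] <- 0
  k <- max(1L, round(params$window_ms * series$rate_hz / 1000))
  q <- moving_mean(a, k, align = params$window_align)
  list(q = q, threshold = params$z_fraction * mean(q[ok]), in_blink = in_blink)
}

#' Extend a parsed blink endpoint past its recovery artifact
#'
#' Returns the first post-blink time at which the moving-window mean of the
#' absolute z-scored pupil derivative falls below `z_fraction` times its
#' whole-recording mean, capped at `offset + max_extend_ms` and never earlier
#' than the parsed offset. A blink with no post-blink samples returns the
#' original offset with attribute `warning = TRUE`.
#'
#' @param series An [sample_series()] at native rate (pre-repair).
#' @param blink A list or one-row data.frame with `onset_ms`, `offset_ms`.
#' @param params [blink_params()].
#' @param activity Optional precomputed [blink_activity] profile (internal
#'   reuse across blinks of one recording).
#' @return Extended offset time in ms.
#' @export
extend_blink_end <- function(series, blink, params = blink_params(),
                             activity = NULL) {
  if (is.null(activity)) {
    bl <- data.frame(onset_ms = blink$onset_ms, offset_ms = blink$offset_ms)
    activity <- blink_activity(series, bl, params)
  }
  t <- series$t_ms
  i_from <- series_index_ge(series, blink$offset_ms)
  if (is.na(i_from)) {
    out <- blink$offset_ms
    attr(out, "warning") <- TRUE
    return(out)
  }
  cap_t <- blink$offset_ms + params$max_extend_ms
  i_cap <- series_index_le(series, cap_t)
  cand <- if (!is.na(i_cap) && i_from <= i_cap) i_from:i_cap else integer(0)
  hit <- cand[activity$q[cand] <= activity$threshold]
  if (length(hit)) t[hit[1]] else min(cap_t, t[length(t)])
}

#' Reconstruct blink spans by linear interpolation
#'
#' Each parsed blink is first extended with [extend_blink_end()]; overlapping
#' or touching extended spans are merged; pupil samples inside each span are
#' replaced by linear interpolation between the nearest valid samples outside
#' it, and the interpolation mask is set there. A span touching the recording
#' start (end) is back-filled (forward-filled) with the nearest valid value.
#' Gaze samples are left untouched.
#'
#' @param series An [sample_series()] at native rate.
#' @param blinks A data.frame of blink events (`onset_ms`, `offset_ms`), e.g.
#'   the `blink` rows of an [event_table()].
#' @param params [blink_params()].
#' @return The repaired series; attribute `"blink_log"` holds one row per
#'   parsed blink with its extended offset and cap flag.
#' @export
repair_blinks <- function(series, blinks, params = blink_params()) {
  if (is.null(blinks) || nrow(blinks) == 0L) {
    attr(series, "blink_log") <- data.frame(onset_ms = numeric(0),
                                            offset_ms = numeric(0),
                                            extended_offset_ms = numeric(0),
                                            capped = logical(0))
    return(series)
  }
  blinks <- blinks[order(blinks$onset_ms), , drop = FALSE]
  act <- blink_activity(series, blinks, params)
  ext <- vapply(seq_len(nrow(blinks)), function(i)
    as.numeric(extend_blink_end(series, blinks[i, ], params, activity = act)),
    numeric(1))
  capped <- ext >= blinks$offset_ms + params$max_extend_ms - 1e-9
  log <- data.frame(onset_ms = blinks$onset_ms, offset_ms = blinks$offset_ms,
                    extended_offset_ms = ext, capped = capped)
  spans <- merge_intervals(blinks$onset_ms, ext)

  t <- series$t_ms; p <- series$pupil; mask <- series$interp
  n <- length(t)
  for (i in seq_len(nrow(spans))) {
    i0 <- series_index_ge(series, spans$start[i])
    i1 <- series_index_le(series, spans$end[i])
    if (is.na(i0) || is.na(i1) || i0 > i1) next
    idx <- i0:i1
    lo <- idx[1] - 1L; hi <- idx[length(idx)] + 1L
    if (lo >= 1L && hi <= n) {
      p[idx] <- p[lo] + (p[hi] - p[lo]) * (t[idx] - t[lo]) / (t[hi] - t[lo])
    } else if (lo < 1L && hi <= n) {
      p[idx] <- p[hi]          # blink spans recording start: back-fill
    } else if (lo >= 1L) {
      p[idx] <- p[lo]          # spans recording end: forward-fill
    }
    mask[idx] <- TRUE
  }
  out <- sample_series(t, series$gx_px, series$gy_px, p, series$rate_hz, mask)
  attr(out, "blink_log") <- log
  out
}

#' Fraction of interpolated samples in an interval
#'
#' @param series An [sample_series()].
#' @param t0,t1 Interval bounds in ms (inclusive); must contain at least one
#'   sample.
#' @return Fraction in `[0, 1]`.
#' @export
interpolated_fraction <- function(series, t0, t1) {
  idx <- which(series$t_ms >= t0 & series$t_ms <= t1)
  if (!length(idx)) stop_fixpupil("interval contains no samples")
  mean(series$interp[idx])
}

#' Downsample by non-overlapping bin averaging
#'
#' Each output sample is the mean of its input bin (pupil and gaze alike);
#' the bin average provides anti-aliasing before the low-pass filter. The
#' output mask is `TRUE` if any bin member was interpolated. Output
#' timestamps are the bin centres.
#'
#' @param series An [sample_series()].
#' @param target_rate_hz Target rate; the native rate must be an integer
#'   multiple.
#' @return A new [sample_series()] at `target_rate_hz`.
#' @export
downsample <- function(series, target_rate_hz = 50) {
  f <- series$rate_hz / target_rate_hz
  if (abs(f - round(f)) > 1e-9)
    stop_fixpupil(sprintf("native rate %g Hz is not divisible by target %g Hz",
                          series$rate_hz, target_rate_hz))
  f <- as.integer(round(f))
  if (f == 1L) return(series)
  n_out <- length(series$t_ms) %/% f
  if (n_out < 2L) stop_fixpupil("series too short to downsample")
  keep <- seq_len(n_out * f)
  binmean <- function(x) colMeans(matrix(x[keep], nrow = f))
  sample_series(binmean(series$t_ms), binmean(series$gx_px),
                binmean(series$gy_px), binmean(series$pupil),
                target_rate_hz,
                interp = colSums(matrix(series$interp[keep], nrow = f)) > 0)
}

# Zero-phase Butterworth low-pass with odd-reflection edge padding, so that
# edge transients do not leak into the data (DC gain 1 to ~1e-12).
zero_phase_lowpass <- function(x, rate_hz, cutoff_hz, order) {
  bf <- signal::butter(order, cutoff_hz / (rate_hz / 2), type = "low")
  pad <- min(length(x) - 1L, 3L * order * ceiling(rate_hz / cutoff_hz))
  front <- 2 * x[1] - x[seq(pad + 1L, 2L)]
  back <- 2 * x[length(x)] - x[seq(length(x) - 1L, length(x) - pad)]
  y <- signal::filtfilt(bf, c(front, x, back))
  y[seq(pad + 1L, pad + length(x))]
}

#' Zero-phase Butterworth smoothing of the pupil trace
#'
#' Forward-backward filtering preserves event latencies (no group delay),
#' which matters for peak-latency claims; the effective amplitude response is
#' the squared single-pass Butterworth magnitude. Gaze channels are left
#' unfiltered. The series must already be blink-repaired (no missing pupil).
#'
#' @param series An [sample_series()] at the filter's design rate.
#' @param params [filter_params()].
#' @return The smoothed series.
#' @export
smooth_pupil <- function(series, params = filter_params()) {
  if (abs(series$rate_hz - params$target_rate_hz) > 1e-9)
    stop_fixpupil("series rate does not match filter design rate; downsample first")
  if (anyNA(series$pupil))
    stop_fixpupil("pupil contains missing values; repair blinks first")
  warmup <- 3 * params$butter_order * params$target_rate_hz / params$cutoff_hz
  if (length(series$t_ms) < warmup)
    stop_fixpupil(sprintf("series shorter than filter warm-up (%d samples)",
                          ceiling(warmup)))
  p <- zero_phase_lowpass(series$pupil, params$target_rate_hz,
                          params$cutoff_hz, params$butter_order)
  out <- series
  out$pupil <- p
  out
}

#' Standard preprocessing chain
#'
#' Repairs blinks at the native rate, downsamples by bin averaging, then
#' applies the zero-phase low-pass. On blink-free data this equals
#' downsample + smooth alone. Event timestamps are untouched throughout.
#'
#' @param series Native-rate [sample_series()].
#' @param events An [event_table()] whose `blink` rows drive the repair, or a
#'   plain data.frame of blinks.
#' @param blink [blink_params()].
#' @param filter [filter_params()].
#' @return Preprocessed series at the target rate, with the `"blink_log"`
#'   attribute from [repair_blinks()].
#' @export
preprocess <- function(series, events, blink = blink_params(),
                       filter = filter_params()) {
  blinks <- if (inherits(events, "fp_events") ||
                (is.data.frame(events) && "kind" %in% names(events)))
    events_of(events, "blink") else events
  rep <- repair_blinks(series, blinks, blink)
  out <- smooth_pupil(downsample(rep, filter$target_rate_hz), filter)
  attr(out, "blink_log") <- attr(rep, "blink_log")
  out
}
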