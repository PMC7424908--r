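#' Write a recording to the four standard CSV tables
#'
#' `samples.csv` has columns `t_ms,gx_px,gy_px,pupil,interp`; missing pupil
#' (pre-repair blink samples) is written as an empty field. `events.csv` has
#' `kind,onset_ms,offset_ms,x_px,y_px,payload`; `trials.csv` and `layout.csv`
#' follow [trial_records()] and [item_layouts()]. All files are UTF-8 with
#' mandatory headers.
#'
#' @param series An [sample_series()] object.
#' @param events An [event_table()].
#' @param trials An [trial_records()] data.frame (optional for ellipse-task
#'   recordings).
#' @param layouts An [item_layouts()] data.frame (optional).
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_recording <- function(series, events, trials = NULL, layouts = NULL, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  samples <- data.frame(t_ms = series$t_ms, gx_px = series$gx_px,
                        gy_px = series$gy_px, pupil = series$pupil,
                        interp = as.integer(series$interp))
  data.table::fwrite(samples, file.path(dir, "samples.csv"), na = "")
  data.table::fwrite(as.data.frame(events), file.path(dir, "events.csv"), na = "")
  if (!is.null(trials))
    data.table::fwrite(as.data.frame(trials), file.path(dir, "trials.csv"), na = "")
  if (!is.null(layouts))
    data.table::fwrite(as.data.frame(layouts), file.path(dir, "layout.csv"), na = "")
  invisible(dir)
}

read_table_checked <- function(path, need) {
  if (!file.exists(path)) stop_fixpupil(sprintf("file not found: %s", path))
  df <- as.data.frame(data.table::fread(path, na.strings = c("NA", "")))
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_fixpupil(sprintf("%s missing column(s): %s", path,
                          paste(miss, collapse = ", ")))
  df
}

#' Read and validate a recording from CSV tables
#'
#' Inverse of [write_recording()]; all container invariants are checked and
#' violations are reported with file and row. The trials and layout tables are
#' optional (an ellipse-tracking recording has neither).
#'
#' @param dir Directory holding `samples.csv`, `events.csv` and optionally
#'   `trials.csv` / `layout.csv`.
#' @param rate_hz Sampling rate of the samples table.
#' @return A list with elements `series`, `events`, `trials`, `layouts`.
#' @export
read_recording <- function(dir, rate_hz = 1000) {
  sp <- file.path(dir, "samples.csv")
  s <- read_table_checked(sp, c("t_ms", "gx_px", "gy_px", "pupil", "interp"))
  dup <- which(duplicated(s$t_ms))
  if (length(dup))
    stop_fixpupil(sprintf("%s: duplicated timestamp at row %d", sp, dup[1]))
  series <- tryCatch(
    sample_series(s$t_ms, s$gx_px, s$gy_px, s$pupil, rate_hz,
                  interp = s$interp != 0),
    error = function(e) stop_fixpupil(sprintf("%s: %s", sp, conditionMessage(e))))

  ep <- file.path(dir, "events.csv")
  e <- read_table_checked(ep, c("kind", "onset_ms", "offset_ms",
                                "x_px", "y_px", "payload"))
  e$payload <- as.character(e$payload)
  validate_events(e, file = ep)
  class(e) <- c("fp_events", "data.frame")

  trials <- layouts <- NULL
  tp <- file.path(dir, "trials.csv")
  if (file.exists(tp)) {
    tr <- read_table_checked(tp, character())
    validate_trials(tr, file = tp)
    trials <- tr
    class(trials) <- c("fp_trials", "data.frame")
  }
  lp <- file.path(dir, "layout.csv")
  if (file.exists(lp)) {
    ly <- read_table_checked(lp, character())
    validate_layouts(ly, file = lp, trials = trials)
    layouts <- ly
    class(layouts) <- c("fp_layout", "data.frame")
  }
  list(series = series, events = e, trials = trials, layouts = layouts)
}

#' Per-condition behavioural summary
#'
#' Mean accuracy, mean search time and the proportion of self-terminated
#' trials for each level of `n_targets` (0-3). An empty condition yields `NA`
#' values rather than an error.
#'
#' @param trials An [trial_records()] data.frame.
#' @return A data.frame with one row per targets level.
#' @export
summarize_behavior <- function(trials) {
  out <- do.call(rbind, lapply(0:3, function(k) {
    sub <- trials[trials$n_targets == k, , drop = FALSE]
    if (nrow(sub) == 0L)
      return(data.frame(n_targets = k, n_trials = 0L, accuracy = NA_real_,
                        mean_search_time_ms = NA_real_,
                        prop_self_terminated = NA_real_))
    data.frame(
      n_targets = k, n_trials = nrow(sub),
      accuracy = mean(as.logical(sub$correct)),
      mean_search_time_ms = mean(sub$search_offset_ms - sub$search_onset_ms),
      prop_self_terminated = mean(as.logical(sub$self_terminated)))
  }))
  rownames(out) <- NULL
  out
}
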