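#' Fit the pupil foreshortening error model
#'
#' Ordinary least squares of recorded pupil size on horizontal and vertical
#' gaze position, `P' = b0 + b1*X + b2*Y + e`, fitted per recording session on
#' ellipse-tracking data. Interpolated samples are excluded from the fit. An
#' optional leading trim drops the start of the recording, where the
#' trial-initiating button press can transiently dilate the pupil and degrade
#' the regression.
#'
#' @param series A preprocessed (blink-repaired) [sample_series()].
#' @param trim_ms Leading portion to drop before fitting, in ms (default 1000).
#' @param session_id Identifier stored with the model.
#' @return An object of class `fp_pfe` with fields `b0`, `b1`, `b2`, `r2`,
#'   `coef_p_values`, `n_samples`, `session_id`.
#' @export
fit_pfe <- function(series, trim_ms = 1000, session_id = NA_character_) {
  keep <- !series$interp & series$t_ms >= series$t_ms[1] + trim_ms
  x <- series$gx_px[keep]; y <- series$gy_px[keep]; p <- series$pupil[keep]
  if (length(p) < 100L)
    stop_fixpupil("need at least 100 unmasked samples to fit the PFE model")
  if (diff(range(x)) <= 1)
    stop_fixpupil("gaze covers <= 1 px on the horizontal axis; design is degenerate")
  if (diff(range(y)) <= 1)
    stop_fixpupil("gaze covers <= 1 px on the vertical axis; design is degenerate")
  fit <- lm(p ~ x + y)
  sm <- summary(fit)
  cf <- coef(fit)
  if (any(!is.finite(cf)))
    stop_fixpupil("rank-deficient gaze design; cannot fit PFE model")
  structure(
    list(b0 = unname(cf[1]), b1 = unname(cf[2]), b2 = unname(cf[3]),
         r2 = sm$r.squared,
         coef_p_values = unname(sm$coefficients[, 4]),
         n_samples = length(p), session_id = session_id),
    class = "fp_pfe")
}

#' @export
print.fp_pfe <- function(x, ...) {
  cat(sprintf(
    "<fp_pfe> session %s: b0 = %.2f, b1 = %.4f, b2 = %.4f, R2 = %.3f (n = %d)\n",
    x$session_id, x$b0, x$b1, x$b2, x$r2, x$n_samples))
  invisible(x)
}

#' Correct a pupil trace for the foreshortening error
#'
#' Applies `Pc = P - b1*X - b2*Y` samplewise with the coefficients of a model
#' fitted on the same session's ellipse-tracking data; gaze and mask are
#' unchanged. The same-session requirement exists because the correction is
#' only valid while the recording geometry (eye level, camera and screen
#' distances) is unchanged between tasks.
#'
#' @param series An [sample_series()].
#' @param model An `fp_pfe` model from [fit_pfe()].
#' @return The corrected series.
#' @export
apply_pfe_correction <- function(series, model) {
  stopifnot(inherits(model, "fp_pfe"))
  out <- series
  out$pupil <- series$pupil - model$b1 * series$gx_px - model$b2 * series$gy_px
  out
}

#' Aggregate PFE models across sessions
#'
#' Descriptive summary (mean, SD, min, max) of `r2`, `b1` and `b2` over a set
#' of per-session models.
#'
#' @param models A list of `fp_pfe` objects.
#' @return A data.frame with one row per statistic.
#' @export
pfe_summary <- function(models) {
  if (!length(models)) stop_fixpupil("need at least one model")
  grab <- function(f) vapply(models, `[[`, numeric(1), f)
  stats_row <- function(name, v) {
    data.frame(quantity = name, mean = mean(v),
               sd = if (length(v) > 1L) sd(v) else 0,
               min = min(v), max = max(v), n_sessions = length(v))
  }
  out <- rbind(stats_row("r2", grab("r2")),
               stats_row("b1", grab("b1")),
               stats_row("b2", grab("b2")))
  rownames(out) <- NULL
  out
}
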