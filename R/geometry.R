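#' Screen and viewing geometry
#'
#' Bundles the display parameters needed to convert between pixels and degrees
#' of visual angle. All angular thresholds used by the pipeline (interest-area
#' radius, saccade-detection thresholds, merge distances) are specified in
#' degrees and converted through a single scalar `px_per_deg`, i.e. an
#' isotropic small-angle approximation.
#'
#' The default `px_per_deg` is derived from the reference setup: a 1024 x 768
#' display viewed at 40 cm, with the stimulus field spanning roughly 20 x 20
#' degrees. It is fully configurable because the physical pixel pitch of any
#' given rig must be measured, not assumed.
#'
#' @param screen_width_px,screen_height_px Display resolution in pixels.
#' @param viewing_distance_cm Eye-to-screen distance in cm.
#' @param px_per_deg Pixels per degree of visual angle (scalar).
#' @return An object of class `fp_geometry`.
#' @examples
#' g <- geometry()
#' deg_to_px(1.25, g)
#' @export
geometry <- function(screen_width_px = 1024, screen_height_px = 768,
                     viewing_distance_cm = 40, px_per_deg = 14.7) {
  for (nm in c("screen_width_px", "screen_height_px", "viewing_distance_cm",
               "px_per_deg")) {
    v <- get(nm)
    assert_finite_scalar(v, nm)
    if (v <= 0) stop_fixpupil(sprintf("`%s` must be positive", nm))
  }
  structure(
    list(screen_width_px = screen_width_px,
         screen_height_px = screen_height_px,
         viewing_distance_cm = viewing_distance_cm,
         px_per_deg = px_per_deg),
    class = "fp_geometry"
  )
}

#' @export
print.fp_geometry <- function(x, ...) {
  cat(sprintf("<fp_geometry> %d x %d px, %.1f cm viewing distance, %.2f px/deg\n",
              x$screen_width_px, x$screen_height_px,
              x$viewing_distance_cm, x$px_per_deg))
  invisible(x)
}

#' Convert degrees of visual angle to pixels (and back)
#'
#' Linear conversion through `geometry$px_per_deg`. `px_to_deg()` is the exact
#' inverse.
#'
#' @param angle_deg Angle(s) in degrees of visual angle.
#' @param px Length(s) in pixels.
#' @param geometry An [geometry()] object.
#' @return Numeric vector of the same length as the input.
#' @export
deg_to_px <- function(angle_deg, geometry) {
  stopifnot(inherits(geometry, "fp_geometry"))
  if (!is.numeric(angle_deg) || any(!is.finite(angle_deg)))
    stop_fixpupil("`angle_deg` must be finite numeric")
  angle_deg * geometry$px_per_deg
}

#' @rdname deg_to_px
#' @export
px_to_deg <- function(px, geometry) {
  stopifnot(inherits(geometry, "fp_geometry"))
  if (!is.numeric(px) || any(!is.finite(px)))
    stop_fixpupil("`px` must be finite numeric")
  px / geometry$px_per_deg
}
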